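test_that("zero rates produce profiles with no features", {
  spec <- em_scene_spec(
    n_profiles_per_condition = 5L, conditions = "no_stim",
    structure_rates = list(no_stim = c(pit = 0)), seed = 2L)
  sim <- simulate_em_dataset(spec)
  expect_length(sim$profiles, 5L)
  expect_true(all(vapply(sim$profiles, function(p) length(p$features),
                         integer(1)) == 0L))
  expect_true(all(as.matrix(sim$truth$counts[, -(1:2)]) == 0L))
})

test_that("empirical pit rate matches the Poisson rate within 3 SE", {
  spec <- em_scene_spec(
    n_profiles_per_condition = 1000L, conditions = "100ms",
    structure_rates = list(`100ms` = c(pit = 0.3)), seed = 4L)
  sim <- simulate_em_dataset(spec)
  m <- mean(sim$truth$counts$pit)
  se <- sqrt(0.3 / 1000)
  expect_lt(abs(m - 0.3), 3 * se)
})

test_that("simulation is deterministic and truth cardinalities are exact", {
  spec <- em_scene_spec(n_profiles_per_condition = 30L, seed = 9L)
  a <- simulate_em_dataset(spec)
  b <- simulate_em_dataset(spec)
  expect_equal(a$truth, b$truth)
  expect_equal(length(a$profiles), length(b$profiles))
  # counts table covers every profile exactly once
  expect_equal(nrow(a$truth$counts), 30L * 3L)
  expect_setequal(a$truth$counts$profile_id,
                  vapply(a$profiles, `[[`, character(1), "profile_id"))
  # one pit-distance row per generated uncoated pit
  expect_equal(nrow(a$truth$pit_distances), sum(a$truth$counts$pit))
})

test_that("annotations round-trip through the JSON schema", {
  spec <- em_scene_spec(n_profiles_per_condition = 8L, seed = 5L)
  sim <- simulate_em_dataset(spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_em_annotations(sim$profiles, path)
  back <- parse_annotations(path)
  expect_length(back, length(sim$profiles))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$profile_id, sim$profiles[[i]]$profile_id)
    expect_equal(back[[i]]$membrane, unname(sim$profiles[[i]]$membrane),
                 ignore_attr = TRUE, tolerance = 1e-9)
    expect_equal(length(back[[i]]$features), length(sim$profiles[[i]]$features))
    kinds <- vapply(back[[i]]$features, `[[`, character(1), "kind")
    expect_equal(kinds, vapply(sim$profiles[[i]]$features, `[[`,
                               character(1), "kind"))
  }
  # and quantification is identical on the round-tripped annotations
  expect_equal(count_structures(back), count_structures(sim$profiles))
})

test_that("schema validation rejects off-membrane pit edges and bad kinds", {
  expect_error(
    make_straight_profile(features = list(
      em_feature("pit", list(type = "segment",
                             edges = rbind(c(150, 5), c(190, 0)))))),
    "off the membrane")
  expect_error(em_feature("mystery", list(type = "point", at = c(0, 0))),
               "unknown feature kind")
  expect_error(em_feature("vesicle", list(type = "circle", center = c(0, 0),
                                          diameter_nm = -5)),
               "positive")
})

test_that("generated diameters respect category windows", {
  spec <- em_scene_spec(
    n_profiles_per_condition = 200L, conditions = "1s",
    structure_rates = list(`1s` = c(vesicle = 0.5, large_vesicle = 0.5,
                                    endosome = 0.5)),
    seed = 12L)
  sim <- simulate_em_dataset(spec)
  for (p in sim$profiles) for (f in p$features) {
    d <- f$geometry$diameter_nm
    switch(f$kind,
           vesicle = expect_lte(d, 60),
           large_vesicle = { expect_gt(d, 60); expect_lt(d, 100) },
           endosome = expect_gte(d, 100))
  }
})
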