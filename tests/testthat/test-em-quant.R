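test_that("diameter thresholds classify exactly at the boundaries", {
  expect_equal(classify_structure(circle_feature(60.0)), "vesicle")
  expect_equal(classify_structure(circle_feature(60.1)), "large_vesicle")
  expect_equal(classify_structure(circle_feature(99.9)), "large_vesicle")
  expect_equal(classify_structure(circle_feature(100.0)), "endosome")
  # ferritin flag promotes the larger categories
  expect_equal(classify_structure(circle_feature(75, ferritin = TRUE)),
               "ferritin_large_vesicle")
  expect_equal(classify_structure(circle_feature(130, ferritin = TRUE)),
               "ferritin_endosome")
  # pits pass through regardless of geometry details
  expect_equal(classify_structure(pit_at(150, 190)), "pit")
  expect_equal(classify_structure(pit_at(150, 190, "coated_pit")), "coated_pit")
  # vesicular feature without a usable diameter
  expect_error(classify_structure(
    em_feature("vesicle", list(type = "point", at = c(0, 0)))), "diameter")
})

test_that("pit distance is the arc length to the nearest active-zone end", {
  # membrane along x, active zone covering arc [0, 100]
  p <- make_straight_profile(az_segment = c(1L, 2L),
                             features = list(pit_at(146.23, 186.23)))
  expect_equal(pit_az_distance(p$features[[1]], p), 46.23, tolerance = 1e-9)

  # contact and overlap give zero
  p2 <- make_straight_profile(features = list(pit_at(100, 140)))
  expect_equal(pit_az_distance(p2$features[[1]], p2), 0)
  p3 <- make_straight_profile(features = list(pit_at(80, 120)))
  expect_equal(pit_az_distance(p3$features[[1]], p3), 0)
})

test_that("pit distance is invariant under rigid motions and bounds Euclid", {
  bend <- cbind(c(0, 100, 200, 250, 300, 400),
                c(0, 0, 40, 90, 140, 160)) # bent membrane
  pit <- em_feature("pit", list(type = "segment",
                                edges = rbind(bend[5, ], bend[6, ])))
  prof <- profile_annotation("b1", "100ms", bend, c(1L, 2L), list(pit))
  d0 <- pit_az_distance(pit, prof)

  theta <- 0.83; R <- matrix(c(cos(theta), sin(theta),
                               -sin(theta), cos(theta)), 2, 2)
  bend2 <- t(R %*% t(bend)) + rep(c(333, -77), each = nrow(bend))
  pit2 <- em_feature("pit", list(type = "segment",
                                 edges = rbind(bend2[5, ], bend2[6, ])))
  prof2 <- profile_annotation("b2", "100ms", bend2, c(1L, 2L), list(pit2))
  expect_equal(pit_az_distance(pit2, prof2), d0, tolerance = 1e-9)

  # arc length dominates the straight-line distance
  d_euc <- pit_az_distance(pit, prof, mode = "euclidean")
  expect_gte(d0, d_euc)
})

test_that("structure counting matches hand counts and the generator truth", {
  p <- make_straight_profile(features = list(
    pit_at(150, 190), pit_at(300, 340), circle_feature(120)))
  counts <- count_structures(list(p))
  expect_equal(counts$pit, 2L)
  expect_equal(counts$endosome, 1L)
  expect_equal(counts$vesicle, 0L)

  expect_equal(nrow(count_structures(list())), 0L)

  sim <- simulate_em_dataset(em_scene_spec(n_profiles_per_condition = 60L,
                                           seed = 14L))
  got <- count_structures(sim$profiles)
  expect_equal(got, sim$truth$counts) # exact ground-truth agreement

  # excluded profiles are dropped from counts
  sim$profiles[[1]]$excluded <- TRUE
  expect_equal(nrow(count_structures(sim$profiles)), nrow(got) - 1L)
})

test_that("timepoint summaries report mean, SEM and group sizes", {
  counts <- data.frame(profile_id = sprintf("p%d", 1:4),
                       condition = "100ms",
                       pit = c(0L, 0L, 1L, 1L), coated_pit = 0L,
                       vesicle = 0L)
  s <- summarize_timepoints(counts)
  row <- s[s$category == "pit", ]
  expect_equal(row$mean, 0.5)
  expect_equal(row$sem, 0.288675, tolerance = 1e-5)
  expect_equal(row$n_profiles, 4L)
  zero <- s[s$category == "coated_pit", ]
  expect_equal(zero$mean, 0)
  expect_equal(zero$sem, 0)
  # single-profile condition: SEM undefined
  s1 <- summarize_timepoints(counts[1, ])
  expect_true(is.na(s1$sem[1]))
  expect_error(summarize_timepoints(counts, conditions = "1s"),
               "unknown condition")
})

test_that("blinding is a deterministic, invertible permutation", {
  ids <- sprintf("micrograph_%02d", 1:10)
  m1 <- randomize_blind(ids, seed = 7L)
  m2 <- randomize_blind(ids, seed = 7L)
  expect_identical(m1$key, m2$key)
  expect_equal(length(unique(m1$key$code)), 10L)
  expect_identical(unblind(m1, blind_code(m1, ids)), ids)
  # different seeds permute differently (n = 100)
  big <- sprintf("m%03d", 1:100)
  expect_false(identical(randomize_blind(big, 1L)$key$code,
                         randomize_blind(big, 2L)$key$code))
  expect_error(randomize_blind(c("a", "a"), 1L), "unique")
})

test_that("blinding never alters quantification", {
  sim <- simulate_em_dataset(em_scene_spec(n_profiles_per_condition = 25L,
                                           seed = 16L))
  ids <- vapply(sim$profiles, `[[`, character(1), "profile_id")
  map <- randomize_blind(ids, seed = 3L)
  blinded <- lapply(sim$profiles, function(p) {
    p$profile_id <- blind_code(map, p$profile_id)
    p
  })
  a <- summarize_timepoints(count_structures(sim$profiles))
  b <- summarize_timepoints(count_structures(blinded))
  expect_equal(a, b)
  expect_equal(sort(pit_distances(sim$profiles)$distance_nm),
               sort(pit_distances(blinded)$distance_nm))
})

test_that("simulated pit distances are recovered exactly from annotations", {
  sim <- simulate_em_dataset(em_scene_spec(
    n_profiles_per_condition = 200L, conditions = "100ms",
    structure_rates = list(`100ms` = c(pit = 0.5)), seed = 18L))
  got <- pit_distances(sim$profiles)
  expect_equal(nrow(got), nrow(sim$truth$pit_distances))
  expect_equal(sort(got$distance_nm), sort(sim$truth$pit_distances$distance_nm),
               tolerance = 1e-6)
})
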