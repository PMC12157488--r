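# azdist

Quantification of endocytic protein localization relative to the synaptic
active zone, in two complementary data types:

* **STED super-resolution images** of presynapses: where do puncta of an
  endocytic protein (e.g. the dynamin splice variant Dyn1xA) sit relative
  to the active-zone boundary defined by the Bassoon scaffold signal, in
  excitatory (PSD-95⁺) versus inhibitory (gephyrin⁺) synapses?
* **Zap-and-freeze electron micrographs**: how many endocytic structures
  (uncoated pits, coated pits, large endocytic vesicles, endosomes) does a
  synaptic profile carry at each timepoint after a single stimulus, and how
  far from the active zone do pits form?

The package is aimed at synapse biologists running these analyses on their
own images/annotations, and ships a synthetic-data generator with known
ground truth so the whole measurement chain is testable without any raw
data.

## The measurement

For a punctum at position $p$ and the active-zone boundary $\partial A$ —
the closed iso-contour of the (normalized, pre-filtered, twice blind
Richardson–Lucy-deconvolved) Bassoon channel at half the intensity of its
local maximum — the reported quantity is the signed minimum distance

$$ d(p) = s \cdot \min_{q \in \partial A} \lVert p - q \rVert \cdot
   \Delta_{\text{px}}, \qquad s = \begin{cases} -1 & p \in A \\ +1 &
   p \notin A \end{cases} $$

in nm ($\Delta_{\text{px}}$ = 20 nm/px by default). Distances are measured
in top-view synapses only. Distributions are summarized by the median with
a percentile-bootstrap 95% CI, the fraction inside the periactive band
(−50 to +50 nm, closed), cumulative curves, and two-sample
Kolmogorov–Smirnov tests. EM structures are classified by diameter —
synaptic vesicle ≤ 60 nm, large endocytic vesicle (LEV) > 60 nm,
endosome ≥ 100 nm — counted per profile (mean ± SEM per timepoint), and
pit-to-active-zone distances are arc lengths along the annotated membrane
from the pit's nearest edge to the nearest active-zone end.

## Worked example

```r
library(azdist)

# twenty synthetic excitatory synapses, one punctum each at a known offset
scenes <- lapply(1:20, function(i) {
  set.seed(i)
  spec <- sted_scene_spec(
    puncta = data.frame(offset_nm = runif(1, -40, 60),
                        azimuth = runif(1, 0, 2 * pi), peak = 400),
    noise = TRUE, seed = i)
  render_sted_scene(spec, sprintf("scene%02d", i))$image
})
res <- run_sted_pipeline(scenes, run_config(seed = 1), gaussian_psf(fwhm_px = 4.4))
head(res$records, 3)
#>        synapse_id synapse_class view x_px y_px signed_distance_nm
#> 1 scene01_x42_y49    excitatory  top   21   24         -12.688030
#> 2 scene02_x48_y41    excitatory  top   18   20          -7.596539
#> 3 scene03_x49_y43    excitatory  top   21   19         -27.143130
res$summaries$excitatory
#> n = 20, median = 5.75 nm (95% CI -12.77 to 25.43), 90.0% in [-50, 50] nm band
```

One record per detected punctum: negative distances lie inside the
active-zone contour, positive outside; the summary says this cohort sits
at the boundary (median ~6 nm) with 90% of puncta in the periactive band —
as expected, since the generator drew offsets from U(−40, 60) nm.

```r
sim <- simulate_em_dataset(em_scene_spec(n_profiles_per_condition = 200L, seed = 1L))
em <- run_em_pipeline(sim$profiles, run_config(seed = 1))
subset(em$timepoint_summary, category == "pit")
#>    condition category  mean         sem n_profiles
#> 1    no_stim      pit 0.015 0.008616625        200
#> 9      100ms      pit 0.315 0.041684083        200
#> 17        1s      pit 0.070 0.018086892        200
em$pit_distance_summaries[["100ms"]]
#> n = 63, median = 29.54 nm (95% CI 24.51 to 41.80), 66.7% in [-50, 50] nm band
```

Pit counts per synaptic profile peak 100 ms after the stimulus (the
generator's rates: 0.02 / 0.30 / 0.08) and pits form a few tens of nm from
the active zone.

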