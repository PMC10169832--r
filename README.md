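# octacov

Spatio-temporal perfusion variability in the macular microvasculature,
quantified from sequences of co-located en-face OCT angiography (OCTA)
frames.

Blood flow through retinal capillaries is not steady: capillaries
"blink" in and out of the perfused pool over minutes, while the major
radial arterioles and venules fluctuate far less. Given `T` repeated
angiograms of the same 3×3 mm macular field (nominally 20 frames of
304×304 px), `octacov` measures this with the pixel-wise **coefficient
of variation**

&nbsp;&nbsp;&nbsp;&nbsp;CoV = SD(I(t)) / mean(I(t)) × 100%,

computed over time after upscaling (×2, bilinear) and spatial alignment
(rigid + smooth non-linear registration) of the frames. Single-pixel
vessel centrelines are extracted (multi-scale vesselness, hysteresis
threshold, topological thinning) and decomposed into **vessel
segments** — maximal centreline paths between junctions/endpoints — each
carrying the mean CoV of its pixels. Segments are summarized within
seven histology-informed ROI categories:

| Category | Content |
|---|---|
| Arteriole / Venule | major radial vessels ("a1", …, "v1", …; masks are inputs) |
| Arteriole-net / Venule-net | capillary influence zone of each vessel (generalized Voronoi partition by exact Euclidean distance) |
| FAZ-net | capillary territory of the foveal avascular zone |
| FAZ-cp | pure-capillary band hugging the FAZ boundary |
| Quadrant | four quadrants through the foveola, minus vessels and FAZ |

Per ROI, the **median** of segment mean CoV measures temporal variation
and the **IQR** spatial variation. Across subjects, the per-category
medians (and IQRs) are compared with a one-way repeated-measures ANOVA —
Mauchly's sphericity test, Huynh–Feldt ε correction, generalized η² —
and Bonferroni-corrected post-hoc paired t-tests with adjusted
confidence intervals.

Because patient OCTA data cannot be redistributed, the package includes
a first-class synthetic phantom generator (`generate_phantom()`,
`simulate_sequence()`): radial vessel trees around an avascular FAZ
disc, a capillary mesh, class-specific temporal modulation (sinusoidal
for large vessels, two-state "blinking" telegraph for capillaries,
calibrated analytically to target CoV levels), sensor noise, and
optional inter-frame motion with ground truth — so every stage of the
pipeline is testable end to end.

## Worked example

```r
library(octacov)

ph  <- generate_phantom(shape = c(160, 160), n_arterioles = 4,
                        n_venules = 4, faz_radius = 18, seed = 1)
sim <- simulate_sequence(ph, temporal_model(n_frames = 20, rng_seed = 11))
cm  <- compute_cov_map(sim$frames, require_aligned = FALSE)  # motion-free
sk  <- segment_centrelines(sim$frames)
segs <- segment_mean_cov(cm, decompose_segments(sk))
segs
#> <vessel_segments> 267 segments, median length 4 px, median mean CoV 29.57%

asg <- assign_segments(segs, ph$roi_truth)
head(summarize_roi(asg)[, 1:5], 4)
#>    category roi n_segments median_mean_cov iqr_mean_cov
#> 1 Arteriole  a1         13        16.69827    0.4196729
#> 2 Arteriole  a2          4        16.62696    0.1714799
#> 3 Arteriole  a3         10        16.52436    4.5111637
#> 4 Arteriole  a4          8        17.81738    2.9318821
```

Arteriole ROIs sit near 16–18% CoV while the capillary categories sit
near 30–33% — the temporal-variation contrast between large vessels and
capillaries that the method is built to expose. A multi-subject run
(here three small phantoms) adds the statistical layer:

```r
cfgs <- lapply(1:3, function(i) analysis_config(
  phantom_shape = c(128, 128), n_arterioles = 3, n_venules = 3,
  faz_radius = 15, phantom_seed = i, seed = 200 + i,
  registration = "none", upscale_factor = 2L,
  model = temporal_model(n_frames = 20, rng_seed = 1), fcp_width = 5))
run_cohort(cfgs)
#> <cohort_result> 3 subjects
#>
#> Medians (temporal variation):
#> One-way repeated-measures ANOVA (3 subjects x 7 categories, measure = median)
#>   Huynh-Feldt epsilon = 1.00 (Greenhouse-Geisser 0.31)
#>   F(6.00, 12.00) = 1721.98, p = 6.81e-17, generalized eta^2 = 1.00
#>
#> IQRs (spatial variation):
#> One-way repeated-measures ANOVA (3 subjects x 7 categories, measure = IQR)
#>   Huynh-Feldt epsilon = 0.44 (Greenhouse-Geisser 0.22)
#>   F(6.00, 12.00) = 21.55, p = 9.03e-06, generalized eta^2 = 0.91
```

The category difference is overwhelming by design: the phantom's
generative CoV levels separate the two vessel classes. `pairwise_matrix
(run_cohort(...)$posthoc_medians)` prints the Bonferroni-adjusted
p-values in the lower-triangular layout used for reporting.

`render_centreline_map()` produces the clamped blue→red centreline heat
maps (global 50% cap, or per-category percentile clamping), and
`render_boxplots()` the comparative box plots with per-box sample sizes,
exporting the underlying statistics as CSV. A thin CLI over these
functions lives at `inst/cli/octacov.R` (verbs `simulate`, `run-all`,
`stats`).

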