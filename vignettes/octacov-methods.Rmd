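---
title: "Quantifying spatio-temporal perfusion variability in macular OCTA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatio-temporal perfusion variability in macular OCTA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A sequence of co-located en-face OCT angiograms records how the
decorrelation signal of each retinal vessel fluctuates over minutes.
Capillaries "blink" — they drop in and out of the perfused pool — while
major radial arterioles and venules fluctuate far less. `octacov`
quantifies this with the pixel-wise **coefficient of variation** (CoV):
the sample standard deviation of a pixel's intensity over the aligned
frames divided by its temporal mean, expressed in percent. The CoV is
zero for a constant series, independent of frame ordering, and invariant
under linear intensity scaling — which makes it robust to bias fields and
comparable across retinal locations, eyes, and subjects.

The analysis proceeds in five stages, each exposed as ordinary functions
and orchestrated by `run_subject()` / `run_cohort()`:

1. **Upscaling** — every frame is upscaled by an integer factor (default
   2) with bilinear interpolation. This is not cosmetic: capillaries are
   about one pixel wide at acquisition resolution, and both centreline
   detection and subpixel resampling behave much better at twice the
   sampling density (see *Numerical choices*).
2. **Alignment** — rigid registration (NCC objective, phase-correlation
   initialization, Nelder-Mead refinement over `(dx, dy, theta)`)
   followed by an optional non-linear stage: a diffusion-regularized,
   demons-style iteration whose displacement field is smoothed with a
   Gaussian schedule `g, g/2, g/4` (`grid_spacing = 8` px by default).
   The non-linear stage never degrades the global NCC; if it would, the
   zero field is returned. Pixels resampled from outside the field of
   view become `NA` and are excluded from all temporal statistics rather
   than zero-filled, which avoids manufacturing variance at the borders.
3. **CoV map** — sample (n−1) SD over time divided by temporal mean, at
   pixels where all `T` samples are valid and the mean exceeds
   `mean_floor` (default 1% of the global mean intensity, guarding
   against division blow-ups in empty background).
4. **Centrelines and segments** — multi-scale Hessian (Frangi-style)
   vesselness of the temporal-mean image, hysteresis thresholding, small
   component removal, and Zhang–Suen thinning to a single-pixel skeleton.
   Skeleton pixels are classified by 8-neighbour count (1 endpoint, 2
   interior, ≥3 junction); junction pixels terminate paths and belong to
   no segment, so the maximal paths between terminals partition the
   remaining skeleton unambiguously. A **vessel segment** carries the
   arithmetic mean of per-pixel CoV over its valid pixels.
5. **ROI summaries and statistics** — segments are assigned to the seven
   histology-informed ROI categories; per-ROI medians measure temporal
   variation and IQRs spatial variation; per-subject category medians and
   IQRs feed the repeated-measures ANOVA battery.

## The seven ROI categories

Major radial arteriole ("a1", "a2", …) and venule ("v1", …) masks, and
the FAZ mask, are inputs (drawn interactively in practice; ground truth
for phantoms). From them the package derives:

- **"-net" influence zones** — the generalized Voronoi partition of the
  capillary domain: each pixel outside the major vessels and FAZ is
  assigned to the nearest seed by exact Euclidean distance (squared
  distances compared as integers; ties broken toward the lowest seed
  index, making the partition deterministic across platforms).
  "a1-net" is the capillary territory of arteriole a1, "F-net" that of
  the FAZ.
- **"F-cp"** — the pure-capillary band: either a user-drawn mask or an
  annulus of configurable width (default 6 px at acquisition resolution)
  outward from the FAZ boundary.
- **Quadrants Q1–Q4** — axis-aligned quadrants through the foveola
  centre, minus the major-vessel and FAZ masks; together with the
  exclusions they partition the field exactly. The split axes are a
  design choice; the paper-level analyses are insensitive to their
  orientation.

A segment joins at most one ROI per category by the majority-of-pixels
rule (at least half of its pixels inside the category; ties broken
toward the ROI containing the segment midpoint, then the lowest ROI
index).

## The statistical battery

For `n` subjects and the `k = 7` categories, the subjects × categories
table of pooled medians (or IQRs) is analysed with a one-way
within-subject ANOVA: `SS_total = SS_subjects + SS_effect + SS_error`,
`F = MS_effect / MS_error` on `(k−1, (n−1)(k−1))` degrees of freedom,
and generalized effect size `η²_g = SS_effect / (SS_effect +
SS_subjects + SS_error)`. Mauchly's W is computed from the covariance of
`k−1` orthonormalized Helmert contrasts with Box's chi-square
approximation including the second-order term (matching base R's
`mauchly.test` to machine precision). When Mauchly rejects sphericity at
0.05, degrees of freedom are scaled by the Huynh–Feldt epsilon — the
`(n(k−1)ε̂ − 2) / ((k−1)(n − 1 − (k−1)ε̂))` correction of the
Greenhouse–Geisser estimate, capped at 1, the convention of the
mainstream repeated-measures implementations (`car`, and the tools built
on it, against which the package is cross-checked in its tests). Both
corrected and uncorrected results are always reported.

Post-hoc comparisons are all `k(k−1)/2 = 21` paired t-tests with
Bonferroni adjustment `p_adj = min(1, 21p)` and confidence intervals at
the per-comparison level `1 − 0.05/21`, so interval coverage and the
decision rule are consistent. Whether a pooled or per-pair error term is
used is genuinely open in this design; per-pair paired t-tests are
implemented, the default of the post-hoc tooling this field uses.

## What the phantom generator emulates — and what it does not

`generate_phantom()` builds a macular field with alternating radial
arteriole/venule trees (2–3 branch generations, widths 5 px tapering to
2 px), an avascular FAZ disc bounded by a terminal capillary ring, and a
capillary mesh of k-nearest-neighbour edges between blue-noise
(jittered-grid, ~7 px spacing) points. A Delaunay triangulation of
Poisson-disc points would be marginally more regular; no triangulation
library is available in the supported dependency set and the
k-nearest-neighbour mesh serves the same statistical role.

`temporal_model()` drives each vessel with a class-specific modulation
shared along the vessel segment: a low-amplitude sinusoid for major
vessels and a symmetric two-state random telegraph ("blinking",
per-frame switch probability 0.3) for capillaries, plus independent
additive Gaussian sensor noise (SD 5 on baselines of 150–200, floored at
0). Amplitudes are calibrated analytically, not empirically: a sinusoid
of relative amplitude `a` sampled over whole periods has population CoV
`a/√2`, a symmetric telegraph has population CoV `a`. The defaults
target 16% (major vessels) and 33% (capillaries), the pooled levels
reported for healthy maculae; `simulate_sequence()` returns the
ground-truth population CoV map alongside the frames.

The phantom does **not** model OCTA physics: no speckle, no
decorrelation statistics, no projection artifacts, no flow-dependent
signal saturation, no eye-tracking residuals. Temporal autocorrelation
of real OCTA intensities is uncharacterized in the source material; the
sinusoid/telegraph forms are stand-ins, not physiological claims.
Passing tests therefore demonstrate that the *pipeline* recovers known
generative structure — not that real capillaries blink like telegraph
processes.

## Numerical choices

- **Quartiles** everywhere (IQR, QCD, box plots, clamp ranges) use
  linear interpolation between order statistics (R type 7), stated once
  and used consistently.
- **Sample (n−1) SD** for the CoV: `T = 20` frames is small, and the
  phantom oracles use the same convention (tests accept the
  `√(T/(T−1))` gap from population values as `O(1/T)` sampling error).
- **Upscale-then-align order matters.** Registering at acquisition
  resolution and computing CoV on pixel-thin capillaries inflates CoV by
  ~3 pp through interpolation alone; upscaling ×2 first keeps the
  motion-induced CoV error at ~1.5 pp median — inside the 2 pp
  tolerance the validation demands. This reproduces the rationale for
  upscaling before alignment.
- **Vesselness** responses are max-normalized per scale before taking
  the across-scale maximum; otherwise thin-capillary responses on the
  bilinearly interpolated grid fall below any threshold calibrated on
  major vessels. Hysteresis thresholds (2% / 10% of the maximum
  response), scales (0.6/1.25/2.5 px at acquisition resolution, scaled
  by the upscale factor), and the minimum component size are all config
  values.
- **Thinning** is Zhang–Suen plus a final pass that removes a pixel of
  any residual 2×2 block when its neighbours remain 8-connected
  (union-find simplicity test) — the skeleton is guaranteed free of 2×2
  blocks.
- **Junction pixels belong to no segment.** This keeps segments simple
  paths and the partition property exact: every non-junction skeleton
  pixel lies in exactly one segment. Closed loops without junctions
  (e.g. the terminal ring) become single segments with a deterministic
  start.
- **Degenerate inputs** are first-class: constant frames are rejected by
  rigid registration; all-invalid CoV maps warn; ROIs with no segments
  report `n = 0` with undefined statistics; zero-variance post-hoc pairs
  are flagged rather than tested; `Q1 + Q3 = 0` makes the QCD undefined,
  flagged.

## Validation sizes

The test-suite and acceptance computations run on scaled-down fields
chosen to exercise every code path with comfortable margins: phantoms of
160×160 px with 4 arterioles, 4 venules and an 18 px FAZ (the full-size
default is 304×304 with 8+8 and 30 px), sequences of `T = 20` frames,
and validation cohorts of 10 subjects. Registration oracles use known
rigid motions up to 5 px / 3° and smooth warps up to 2 px. The
statistical layer is validated on the exact reported scale
(10 subjects × 7 categories).

## Known limitations

- Artery/vein identity, vessel order, and the FAZ outline are inputs,
  not inferences; the package does not classify vessels from image
  content.
- The centreline operator and its thresholds are a declared design (the
  upstream description names no operator); on very low-contrast data the
  hysteresis fractions will need adjustment.
- The demons-style non-linear stage assumes smooth, small
  (few-pixel) residual deformation; it is not a diffeomorphic framework
  and will not recover large or discontinuous motion.
- Per-pixel QCD on strongly bimodal ("blinking") series is heavily
  quantized; dispersion comparisons should be made at the
  vessel-segment level, where means smooth the quantization.
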