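---
title: "Uncertainty-guided space-time segmentation of perfusion MRI: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-guided space-time segmentation of perfusion MRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

First-pass perfusion cardiac MRI acquires a short-axis slice repeatedly while
a contrast bolus transits the heart: the right-ventricular bloodpool enhances
first, then the left-ventricular (LV) bloodpool, then the LV myocardium.
Automatic per-pixel delineation of the myocardial ring in these dynamic
(2D+time) series is the prerequisite for objective ischemia assessment, but
networks trained on data from one scanner and pulse sequence degrade on
*shifted* data — another vendor, another sequence, another patient mix — and
the degradation is silent: a single trained network reports no measure of its
own reliability on a new case.

`perfuseg` implements a patch-level analysis framework that addresses both
issues at once:

1. **Patch-level segmentation.** A series is decomposed into overlapping
   space-time patches by a spatially sliding window; each patch (all time
   frames stacked as channels) is segmented independently by a 2D+time
   U-Net into background / LV myocardium / bloodpool softmax maps, and the
   maps are averaged back into a full-frame solution.
2. **Uncertainty as a byproduct.** Because a pixel belongs to several
   overlapping patches, the same model classifies it several times under
   different spatial contexts. The per-pixel **U-map** is the population
   standard deviation of the myocardium probabilities across the covering
   patches; the scalar **Upp** is the squared Frobenius norm of the U-map
   divided by the number of predicted myocardial pixels,
   $U_{pp} = \lVert U\rVert_F^2 / N_{myo}$.
3. **Data-adaptive model selection.** A pool of identically configured
   networks is trained (several seeded runs, several gated checkpoints per
   run). At analysis time *every* member segments the test case and the
   solution with the smallest Upp is kept. The comparator ("established"
   selection) fixes the single member with the best validation Dice and uses
   it for every case.

Since each probability lies in $[0,1]$, the U-map is bounded by $0.5$, with
the bound attained exactly by a two-patch $\{0,1\}$ disagreement. U-map
displays therefore use a fixed $[0, 0.5]$ color scale.

## Why the receptive field matters

The uncertainty signal exists only if a pixel's prediction depends on its
patch context. An early one-level variant of our U-Net (receptive field
around 14 px) made interior pixels effectively context-independent: overlapping
patches agreed everywhere except near patch borders, and oversmoothed,
weakly trained members — whose low-amplitude probability fields disagree the
least — systematically won minimum-Upp selection, inverting the method. The
shipped network is a three-level encoder/decoder whose receptive field
exceeds the patch size, so every prediction is a function of the whole
patch; with that property restored, weak members betray themselves through
patch-level inconsistency and selection behaves as intended. The framework
itself is architecture-agnostic; any patch-level segmenter with a
patch-scale receptive field can be plugged in through `segment_series()`.

## Strides

Two strides govern the sliding window:

* **training stride = patch/2** — the spacing used to harvest training
  patches;
* **inference stride = patch/4** (default 16 px for 64-px patches) — the
  dense overlap that gives interior pixels high coverage for the U-map.
  A dense stride is essential: with it, an interior pixel is covered by up
  to 25 patches, and the sliding window naturally samples the image center
  (where the heart sits) more densely than the edges. The stride is a
  config knob (`train_config(infer_stride = ...)`) for users who want the
  sparser three-quarter-overlap reading.

Edge handling clamps the final window flush with the image border rather
than padding, so no intensities are fabricated and every pixel is covered
at least once.

## The synthetic phantom

Real multi-center perfusion data cannot ship with a package, so the study
conditions are emulated by a generator with exact ground truth
(`make_phantom()`, `phantom_sampler()`, `make_dataset()`):

* **Geometry.** A bloodpool disk (LV cavity) inside a myocardial ring,
  plus an RV crescent labelled bloodpool; center jittered a few pixels.
* **Temporal structure.** Each tissue follows a gamma-variate enhancement
  curve on top of a small baseline; onset/shape/rate/amplitude defaults are
  ordered so the RV pool peaks before the LV pool, which peaks before the
  myocardium — the three wash-in stages the method assumes.
* **Perfusion defects.** An angular sector whose whole myocardial signal is
  scaled by a multiplier in $[0,1)$ — a one-parameter severity knob whose
  mean-peak ratio inside/outside the sector equals the multiplier exactly
  (convenient for verification).
* **Coil shading.** A multiplicative field of 2–4 broad Gaussian bumps,
  constant over time.
* **Noise.** Additive Gaussian. At the signal-to-noise ratios of magnitude
  perfusion images the difference from Rician noise is immaterial for
  segmentation-level testing.
* **Dataset shift.** The `"shifted"` sampler raises noise (σ 0.04–0.08 vs
  0.01–0.03) and shading (0.2–0.4 vs 0.05–0.2), enlarges the cavity and
  thins the ring, and offsets the myocardial peak amplitude by −0.08 —
  emulating a pulse-sequence/vendor change relative to the `"internal"`
  training distribution.
* **Motion-correction errors.** `inject_motion_error()` translates a random
  subset of frames rigidly (bilinear, edge-replicated). Real residual
  motion-correction errors are nonrigid; rigid per-frame translation is a
  stated stand-in that suffices to provoke patch-level disagreement while
  remaining exactly verifiable (a frame's centroid moves by the commanded
  shift).

What the phantom does **not** emulate: dark-rim artifacts, through-plane
motion, arrhythmia-driven temporal irregularity, anatomical variability
beyond ring geometry, k-space/acquisition physics, and physiologically
calibrated signal amplitudes. Passing the package's tests therefore shows
the *mechanism* works under controlled shift and corruption — it does not
certify clinical performance.

## Preprocessing and augmentation

Every series is standardized to the analysis grid (`preprocess_series()`):
cubic-spline spatial upsampling (nearest-neighbor for labels), a half-open
square crop centered on a *provided* heart center (phantoms carry theirs;
real-data users must supply one — automatic heart detection is out of
scope), shape-preserving piecewise-cubic (PCHIP) resampling onto a uniform
time grid spanning the input's time range, then min-max normalization of
the whole 2D+time volume to $[0,1]$ (per series, never per frame, so
relative enhancement across frames is preserved). Coordinates are 1-based
pixel centers (R convention) throughout. A constant series is a
normalization error, not a silent division by zero.

Training augmentation (`augment_policy()`) has two families, applied on the
fly each epoch so different pool runs see different streams:

* *segmentation-variant*: one affine map (rotation ±15°, shear ±8°,
  translation ±8 px, scale 0.9–1.1) applied identically to all frames
  (bilinear) and the mask (nearest); out-of-frame regions are intensity 0 /
  label 0;
* *segmentation-invariant*: additive Gaussian noise (σ up to 0.05),
  gamma-style contrast change (γ 0.7–1.4), and a smooth multiplicative
  modulation field (±30%) mimicking coil-sensitivity weighting; the mask is
  untouched by contract.

The magnitudes are implementation defaults chosen to be label-preserving at
the 128-px scale; they are not taken from any external protocol.

## Training the pool

All members share one architecture and hyperparameter set
(`train_config()`); runs differ only in their weight-initialization seed.
Optimization is Adam on the categorical cross-entropy, with gradients
verified against finite differences in the test suite. At the end of every
epoch the candidate weights are scored by full-image validation Dice
(myocardium class, through the inference path — pool gating and reporting
both operate at image level, not patch level). Epochs reaching the
`dice_gate` (default 0.87) are snapshotted; up to `checkpoints_per_run`
snapshots, evenly spaced over the qualifying epochs with the earliest and
latest included, enter the pool. Even spacing maximizes intra-run diversity
among the kept checkpoints, which is what makes per-case selection useful.
The reference profile is 5 runs × 10 checkpoints = 50 members; the desk
profile used by the tests is 2 × 3 = 6. If no epoch passes the gate the run
fails loudly with the best Dice achieved — the gate is relative to task
difficulty, and the phantom task is designed to be learnable well above it.

## Numerical choices and degenerate inputs

* **Population (divisor-N) standard deviation** in the U-map. The printed
  $[0, 0.5]$ bound forces this reading: the sample (N−1) standard deviation
  of $\{0,1\}$ is $\approx 0.707$.
* **U-map uses the myocardium probability only**, matching the definition
  of the patch-level scores as myocardium likelihoods.
* **$N_{myo} = 0 \Rightarrow U_{pp} = +\infty$.** An empty segmentation has
  zero uncertainty energy by vacuity; the sentinel prevents it from winning
  selection. If *every* member returns an empty myocardium the analysis
  aborts with a diagnostic naming the series.
* **Upp is computed per series (one slice) over the full crop**; no
  heart-proximity windowing is applied. Multi-slice aggregation, when
  needed, is the mean of slice values.
* **Ties** in selection are broken by pool manifest order; argmax ties in
  `prob_to_mask()` go to the lower class code; established-selection ties
  go to the earlier (run, epoch).
* **Total energy** ($\lVert U\rVert_F^2$, no normalization) is available as
  an alternative selection metric behind `selection_metric =
  "total_energy"`; Upp remains the default and is always reported.
* **HD95** is the *undirected* 95th-percentile Hausdorff distance, taken as
  the maximum of the two directed 95th-percentile boundary-to-boundary
  distances (quantile type 7), scaled to mm by the pixel spacing. An empty
  class on either side yields `Inf` with a warning and is counted as a
  failure downstream, excluded from mean-distance summaries.
* **Failed segmentations** are operationalized topologically rather than by
  AHA-segment bookkeeping: after dropping myocardial components smaller
  than 5 pixels, criterion (ii) (noncontiguous) fires when the myocardium
  is not a single 8-connected component enclosing at least one cavity;
  criterion (i) (bloodpool inclusion) fires when bloodpool pixels occupy an
  enclosed region other than the single largest cavity. Enclosed regions
  are 4-connected complement components not touching the image border.
  Every ground-truth phantom mask passes both criteria.
* **PCHIP** temporal interpolation is a vectorized Fritsch–Carlson
  implementation over the shared time grid (one slope computation for all
  pixels), verified against `signal::interp1(..., "pchip")`.

## Problem sizes

The package's own experiments use the desk profile: 72-px native phantoms
cropped to 64 × 64 × 16, 32-px patches (training stride 16, inference
stride 8), a width-8 three-level U-Net (~30k parameters), 10 training and 5
validation series, 30 epochs per run, a 2 × 3 pool, and 30-series test arms.
These sizes were chosen so a complete train-and-evaluate cycle is a
desk-scale computation while leaving every structural ratio of the
full-scale profile (patch/image ratio, stride ratios, gate) intact.
`full_preset()` carries the full-scale configuration (128 × 128 × 30 grid,
64-px patches, 5 × 10 pool) for users with the time to run it.

## What the package's experiments show

With fixed seeds, the desk-profile end-to-end run reproduces the framework's
qualitative claims: on internal-style test phantoms the adaptive and
established selections are statistically indistinguishable; on shifted test
phantoms adaptive selection attains at least the established mean Dice with
at most its failure rate; and median Upp increases monotonically with the
magnitude of injected frame misregistration. The test suite
(`tests/testthat/test-acceptance.R`) computes these checks, alongside exact
oracle equivalences for the U-map, argmax, selection and distance
primitives. Directions, not magnitudes, are the claim at phantom scale:
clinical effect sizes are a property of clinical data.

```{r example}
library(perfuseg)
res <- run_end_to_end(desk_preset(seed = 1), out_dir = "perfuseg-out")
res$comparison$summary
autoplot(res$comparison)
```

## Known limitations

* The phantom's simplicity means segmentation Dice saturates near 0.99 on
  internal-style data; contrasts between selection regimes are therefore
  compressed relative to clinical data.
* The pool's smallest gated checkpoints can sit just above the Dice gate;
  on clean data the established member is often best, and the benefit of
  adaptive selection appears under shift — as designed, but worth
  remembering when interpreting per-dataset tables.
* Rigid translation under-represents the deformation structure of real
  motion-correction failures; the motion sweep tests direction of the
  Upp response only.
* Blood-flow quantification, arterial input functions, multi-slice
  bookkeeping and DICOM ingestion are out of scope.
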