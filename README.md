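# perfuseg

Uncertainty-guided space-time segmentation of dynamic (2D+time) first-pass
myocardial perfusion MRI.

Deep networks that segment the left-ventricular myocardium in perfusion CMR
series degrade silently on *shifted* data — a different scanner vendor,
pulse sequence or patient mix than they were trained on. `perfuseg`
implements a patch-level analysis framework that turns the segmentation
process itself into an uncertainty estimator and uses it for per-case model
selection:

* A series is decomposed into overlapping space-time patches by a spatially
  sliding window; a 2D+time U-Net (time frames stacked as input channels)
  segments each patch into background / LV myocardium / bloodpool, and the
  per-patch softmax maps are averaged back into a full-frame solution.
* Because each pixel lies in several overlapping patches, the same model
  classifies it several times under different contexts. The **U-map** is
  the per-pixel population standard deviation of the myocardium
  probabilities over the covering patches,

  $$U(x,y) = \mathrm{std}\,\{\,p_i(x,y) : i \in \Gamma(x,y)\,\},$$

  bounded in $[0, 0.5]$; the scalar **Upp** is its mean per-pixel energy,
  $U_{pp} = \lVert U \rVert_F^2 / N_{myo}$, where $N_{myo}$ counts the
  predicted myocardial pixels.
* A **pool** of identically configured networks (several seeded training
  runs × several validation-gated checkpoints per run) all segment each
  test case; the solution with the smallest Upp is kept (*adaptive*
  selection). The comparator (*established* selection) fixes the single
  member with the best validation Dice for all cases.

Because clinical multi-center data cannot ship with a package, `perfuseg`
includes a first-pass perfusion phantom with exact ground truth — ordered
gamma-variate wash-in curves (RV pool → LV pool → myocardium), perfusion
defect sectors, coil shading, noise, frame-level misregistration, and a
"shifted" sampler emulating a vendor/sequence change — so the full
pipeline trains, runs and is verified end to end at desk scale.

## Worked example

```r
library(perfuseg)

# one phantom series with ground truth
ph <- make_phantom(phantom_config(image_size = 72, n_frames = 20,
                                  cavity_radius = 10, ring_thickness = 6,
                                  seed = 3))
ph$series
#> <perfusion_series 'phantom-seed3'> 72 x 72 pixels, 20 frames, spacing 1.80 x 1.80 mm
#>   heart center (row, col): 36.5, 36.5; t in [0.0, 19.0] s

# full desk-scale experiment: generate data, train a 2x3 pool, compare
# adaptive vs established selection on internal and shifted test sets
# (~2 minutes on one CPU)
res <- run_end_to_end(desk_preset(seed = 1))
res$comparison
#> <method_comparison>
#> # A tibble: 4 × 8
#>   dataset  method          n mean_dice sd_dice mean_hd95 sd_hd95 failure_rate
#>   <chr>    <chr>       <int>     <dbl>   <dbl>     <dbl>   <dbl>        <dbl>
#> 1 internal adaptive       30     0.992 0.00678     0.799   0.915       0
#> 2 internal established    30     0.984 0.0250      1.13    1.91        0.0667
#> 3 shifted  adaptive       30     0.943 0.0473      2.12    0.995       0.0667
#> 4 shifted  established    30     0.865 0.0896      3.35    1.81        0.2
#> # A tibble: 2 × 3
#>   dataset    p_dice p_failures
#>   <chr>       <dbl>      <dbl>
#> 1 internal 0.118         0.492
#> 2 shifted  0.000138      0.254
```

Reading the table: on internal-style phantoms the two selection regimes are
statistically indistinguishable (Dice 0.992 vs 0.984, p = 0.12); on shifted
phantoms adaptive selection is markedly better on mean Dice (0.943 vs
0.865, p < 0.001), boundary distance, and failure rate (6.7% vs 20%) —
the behavior the framework is designed for.

The uncertainty metric also tracks the severity of injected
motion-correction errors:

```r
member <- select_best_validation(res$pool)
grid <- build_grid(c(64, 64), patch_size = 32, stride = 8)
ds <- preprocess_dataset(make_dataset(30, phantom_sampler("internal"), 777),
                         preprocess_spec(64, 16, 1))
motion_error_sweep(member, ds, levels = c(0, 2, 4, 8), grid = grid, seed = 11)
#> <motion_sweep> median Upp by displacement level:
#> # A tibble: 4 × 3
#>   level median_upp     n
#>   <dbl>      <dbl> <int>
#> 1     0    0.00510    30
#> 2     2    0.00577    30
#> 3     4    0.00661    30
#> 4     8    0.0101     30
#> Spearman(level, median Upp) = 1.000
```

`plot_umap()`, `plot_frame()` and `autoplot()` methods visualize U-maps
(fixed `[0, 0.5]` scale), series frames with contours, and comparison /
sweep results. `write_series_nifti()` / `write_solution()` persist series,
masks, U-maps and selection logs as NIfTI + JSON/CSV. A thin CLI wrapper
lives at `inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --preset desk --seed 1 --out out/`).

The methods vignette
(`vignettes/uncertainty-guided-segmentation.Rmd`) documents the model, the
phantom's assumptions, numerical choices, and limitations.

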