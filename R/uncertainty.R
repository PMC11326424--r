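#' Per-pixel uncertainty map from overlapping-patch disagreement
#'
#' For each pixel, the U-map value is the population standard deviation
#' (divisor N) of the myocardium probabilities assigned to that pixel by
#' the same model across all patches covering it:
#' \deqn{U(x, y) = \mathrm{std}\{p_i(x, y) : i \in \Gamma(x, y)\}.}
#' Pixels covered by a single patch get 0. Because each probability lies in
#' `[0, 1]`, the value is bounded by 0.5, attained exactly by a two-patch
#' `{0, 1}` disagreement.
#'
#' @param stack a `patch_prob_stack` from [recombine_patches()].
#' @return `H x W` numeric matrix of uncertainty values in `[0, 0.5]`.
#' @export
compute_umap <- function(stack) {
  if (!inherits(stack, "patch_prob_stack"))
    stop("contract error: `stack` must be a patch_prob_stack")
  d <- dim(stack$probs)
  if (is.null(d) || prod(d) == 0) stop("contract error: empty stack")
  if (any(stack$coverage < 1))
    stop("contract error: every pixel must be covered by at least one patch")
  m <- matrix(stack$probs, d[1] * d[2], d[3])
  m1 <- rowMeans(m, na.rm = TRUE)
  m2 <- rowMeans(m * m, na.rm = TRUE)
  v <- pmax(m2 - m1^2, 0)
  matrix(sqrt(v), d[1], d[2])
}

#' Mean per-pixel uncertainty energy (Upp)
#'
#' The squared Frobenius norm of the U-map divided by the number of
#' myocardium-labelled pixels in the segmentation solution:
#' \deqn{U_{pp} = \lVert U \rVert_F^2 / N_{myo}.}
#' An empty myocardium (`N_myo = 0`) returns `+Inf`: a solution that
#' segments no myocardium at all is maximally distrusted rather than
#' vacuously certain.
#'
#' @param umap uncertainty map from [compute_umap()].
#' @param mask the solution's label mask (code 1 = myocardium).
#' @return A non-negative scalar (possibly `Inf`).
#' @export
compute_upp <- function(umap, mask) {
  if (!identical(dim(umap), dim(mask))) stop("shape mismatch")
  if (any(umap < 0)) stop("contract error: negative uncertainty values")
  n_myo <- sum(mask == 1L)
  if (n_myo == 0) return(Inf)
  sum(umap^2) / n_myo
}

#' Total uncertainty energy (alternative selection metric)
#'
#' The un-normalized sum of squared U-map values,
#' `total_energy = Upp * N_myo` whenever the myocardium is non-empty.
#' Exposed as an alternative per-case selection criterion.
#'
#' @param umap uncertainty map from [compute_umap()].
#' @return A non-negative scalar.
#' @export
total_energy_metric <- function(umap) {
  if (any(umap < 0)) stop("contract error: negative uncertainty values")
  sum(umap^2)
}

#' Data-adaptive uncertainty-guided model selection
#'
#' Runs every pool member on the series through the full inference path,
#' computes each member's U-map and uncertainty metric, and returns the
#' solution with the minimal metric (ties broken by pool manifest order).
#' This lets the test case itself pick the model that it induces the least
#' patch-level disagreement in, instead of committing to the single model
#' that looked best on validation data.
#'
#' @param pool a `model_pool`.
#' @param series a preprocessed `perfusion_series`.
#' @param grid the inference [build_grid()].
#' @param metric `"upp"` (mean per-pixel energy, default) or
#'   `"total_energy"`.
#' @param truth optional ground-truth mask; when given, per-member Dice is
#'   added to the selection log.
#' @return An object of class `segmentation_solution`: fields `mask`,
#'   `probs`, `umap`, `upp`, `total_energy`, `n_myo`, `member_id`,
#'   `series_id`, and `log`, a tibble with one row per pool member
#'   (member_id, upp, total_energy, n_myo, selected, and dice if `truth`
#'   was supplied).
#' @export
select_min_uncertainty <- function(pool, series, grid,
                                   metric = c("upp", "total_energy"),
                                   truth = NULL) {
  stopifnot(inherits(pool, "model_pool"))
  metric <- match.arg(metric)
  if (length(pool$members) == 0) stop("contract error: empty pool")
  sols <- lapply(pool$members, function(m) {
    seg <- segment_series(m, series, grid)
    umap <- compute_umap(seg$stack)
    list(seg = seg, umap = umap,
         upp = compute_upp(umap, seg$mask),
         total_energy = total_energy_metric(umap),
         n_myo = sum(seg$mask == 1L))
  })
  n_myo <- vapply(sols, `[[`, numeric(1), "n_myo")
  if (all(n_myo == 0))
    stop(sprintf("all-empty error: every pool member segmented no myocardium on series '%s'",
                 series$series_id))
  vals <- vapply(sols, `[[`, numeric(1), metric)
  best <- which.min(vals)
  log <- tibble::tibble(
    series_id = series$series_id,
    member_id = pool$manifest$member_id,
    upp = vapply(sols, `[[`, numeric(1), "upp"),
    total_energy = vapply(sols, `[[`, numeric(1), "total_energy"),
    n_myo = as.integer(n_myo),
    selected = seq_along(sols) == best)
  if (!is.null(truth))
    log$dice <- vapply(sols, function(s) dice_score(s$seg$mask, truth, 1L),
                       numeric(1))
  s <- sols[[best]]
  structure(list(mask = s$seg$mask, probs = s$seg$probs, umap = s$umap,
                 upp = s$upp, total_energy = s$total_energy,
                 n_myo = as.integer(s$n_myo),
                 member_id = pool$manifest$member_id[best],
                 series_id = series$series_id, metric = metric, log = log),
            class = "segmentation_solution")
}

#' @export
print.segmentation_solution <- function(x, ...) {
  cat(sprintf("<segmentation_solution> series '%s', member %s, Upp = %.4g, N_myo = %d\n",
              x$series_id, x$member_id, x$upp, x$n_myo))
  invisible(x)
}

#' Sweep motion-correction error levels and track Upp
#'
#' For each displacement level, injects frame-level misregistration into
#' every series of a clean phantom set, segments it (with a single member,
#' or with per-case uncertainty-guided selection when a pool is given),
#' and records Upp. The summary reports the median Upp per level and the
#' Spearman rank correlation between level and median Upp — a positive
#' value means the uncertainty metric tracks the severity of the
#' corruption.
#'
#' @param model a pool member / model (or a `model_pool`).
#' @param dataset list of preprocessed `list(series, mask)` entries.
#' @param levels numeric vector of at least 2 displacement magnitudes in
#'   pixels, typically including 0 as the control condition.
#' @param n_bad_frames number of displaced frames per series; defaults to
#'   one fifth of the frames (at least 3).
#' @param grid the inference [build_grid()].
#' @param seed integer seed controlling the injected displacements.
#' @return An object of class `motion_sweep`: `per_series` (tibble: level,
#'   series_id, upp), `summary` (tibble: level, median_upp, n) and
#'   `spearman`.
#' @export
motion_error_sweep <- function(model, dataset, levels, grid,
                               n_bad_frames = NULL, seed = 1L) {
  if (length(levels) < 2)
    stop("parameter error: need at least 2 displacement levels")
  T <- dim(dataset[[1]]$series$intensities)[3]
  if (is.null(n_bad_frames)) n_bad_frames <- max(3L, round(T / 5))
  is_pool <- inherits(model, "model_pool")
  seeds <- derive_seeds(seed, length(levels) * length(dataset))
  rows <- list()
  k <- 0L
  for (li in seq_along(levels)) {
    for (si in seq_along(dataset)) {
      k <- k + 1L
      el <- dataset[[si]]
      ser <- if (levels[li] > 0)
        inject_motion_error(el$series, n_bad_frames, levels[li], seed = seeds[k])
      else el$series
      upp <- if (is_pool) {
        select_min_uncertainty(model, ser, grid)$upp
      } else {
        seg <- segment_series(model, ser, grid)
        compute_upp(compute_umap(seg$stack), seg$mask)
      }
      rows[[k]] <- tibble::tibble(level = levels[li],
                                  series_id = el$series$series_id, upp = upp)
    }
  }
  per_series <- dplyr::bind_rows(rows)
  summary <- per_series |>
    dplyr::group_by(level) |>
    dplyr::summarise(median_upp = stats::median(upp), n = dplyr::n(),
                     .groups = "drop")
  rho <- stats::cor(summary$level, summary$median_upp, method = "spearman")
  structure(list(per_series = per_series, summary = summary, spearman = rho),
            class = "motion_sweep")
}

#' @export
print.motion_sweep <- function(x, ...) {
  cat("<motion_sweep> median Upp by displacement level:\n")
  print(x$summary)
  cat(sprintf("Spearman(level, median Upp) = %.3f\n", x$spearman))
  invisible(x)
}
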