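#' Dice overlap coefficient for one class
#'
#' `2|A∩B| / (|A|+|B|)` over the pixel sets of `class_code` in the two
#' masks. Defined as 1 when both sets are empty and 0 when exactly one is.
#'
#' @param pred,truth label masks of identical shape.
#' @param class_code class to score (0 background, 1 myocardium,
#'   2 bloodpool).
#' @return A value in `[0, 1]`.
#' @export
dice_score <- function(pred, truth, class_code = 1L) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (!class_code %in% 0:2) stop("parameter error: unknown class code")
  a <- pred == class_code
  b <- truth == class_code
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  2 * sum(a & b) / (na + nb)
}

# Boundary pixels of a class: class pixels with a 4-neighbor outside the
# class (pixels on the image border count as boundary).
boundary_coords <- function(mask, class_code) {
  inside <- mask == class_code
  if (!any(inside)) return(matrix(numeric(0), 0, 2))
  H <- nrow(inside); W <- ncol(inside)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- inside
  core <- pad[2:(H + 1), 2:(W + 1)] &
    pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(inside & !core, arr.ind = TRUE)
}

directed_hd95 <- function(from, to, spacing) {
  # for each boundary point in `from`, distance (mm) to nearest point of `to`
  dy <- outer(from[, 1], to[, 1], "-") * spacing[1]
  dx <- outer(from[, 2], to[, 2], "-") * spacing[2]
  mins <- apply(sqrt(dy^2 + dx^2), 1, min)
  stats::quantile(mins, 0.95, names = FALSE, type = 7)
}

#' Undirected 95th-percentile Hausdorff distance
#'
#' The maximum of the two directed 95th-percentile boundary-to-boundary
#' nearest-neighbor distances between the class boundaries of `pred` and
#' `truth`, in millimetres. Boundaries are 4-connectivity class borders;
#' distances are scaled by the pixel spacing. If either side has no pixels
#' of the class, `Inf` is returned with a warning (counted as a failure
#' downstream).
#'
#' @inheritParams dice_score
#' @param spacing_mm pixel spacing `(dy, dx)` in mm.
#' @return Distance in mm (possibly `Inf`).
#' @export
hd95 <- function(pred, truth, class_code = 1L, spacing_mm = c(1, 1)) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (!class_code %in% 0:2) stop("parameter error: unknown class code")
  a <- boundary_coords(pred, class_code)
  b <- boundary_coords(truth, class_code)
  if (nrow(a) == 0 || nrow(b) == 0) {
    warning("empty class on one side; returning Inf")
    return(Inf)
  }
  max(directed_hd95(a, b, spacing_mm), directed_hd95(b, a, spacing_mm))
}

#' Detect failed segmentations
#'
#' Operationalizes the two visual failure criteria for a predicted mask:
#' (i) *bloodpool inside the myocardial contour* — some bloodpool-labelled
#' pixel lies in a region enclosed by the myocardium other than its single
#' largest enclosed cavity; (ii) *noncontiguous myocardium* — after
#' removing components smaller than `min_component` pixels, the myocardium
#' is not a single 8-connected component, or encloses no cavity at all
#' (e.g. a ring with a gap). Enclosed regions are 4-connected components
#' of the non-myocardium complement that do not touch the image border;
#' enclosed pockets beyond the largest cavity count against criterion (i),
#' not (ii).
#'
#' @param pred predicted label mask.
#' @param min_component minimum myocardial component size kept (pixels).
#' @return `list(failure_bloodpool, failure_noncontiguous)`, both logical;
#'   for an empty prediction both are `TRUE` with attribute `"note"`.
#' @export
detect_failure <- function(pred, min_component = 5L) {
  pred <- validate_mask(pred)
  myo <- pred == 1L
  if (!any(myo)) {
    out <- list(failure_bloodpool = TRUE, failure_noncontiguous = TRUE)
    attr(out, "note") <- "empty prediction"
    return(out)
  }
  comp <- cpp_label_components(myo, 8L)
  sizes <- tabulate(comp[comp > 0])
  keep <- which(sizes >= min_component)
  myo_kept <- matrix(comp %in% keep, nrow(pred), ncol(pred))
  if (!any(myo_kept)) {
    out <- list(failure_bloodpool = TRUE, failure_noncontiguous = TRUE)
    attr(out, "note") <- "no myocardial component above the size threshold"
    return(out)
  }
  n_myo_comp <- length(keep)

  # 4-connected components of the complement; those touching the border are
  # "outside", the rest are cavities enclosed by the myocardium.
  comp_bg <- cpp_label_components(!myo_kept, 4L)
  border_ids <- unique(c(comp_bg[1, ], comp_bg[nrow(comp_bg), ],
                         comp_bg[, 1], comp_bg[, ncol(comp_bg)]))
  border_ids <- border_ids[border_ids > 0]
  all_ids <- setdiff(unique(as.vector(comp_bg)), 0L)
  enclosed_ids <- setdiff(all_ids, border_ids)
  n_enclosed <- length(enclosed_ids)

  failure_noncontiguous <- (n_myo_comp != 1L) || (n_enclosed < 1L)

  failure_bloodpool <- FALSE
  if (n_enclosed > 0) {
    enc_sizes <- vapply(enclosed_ids, function(id) sum(comp_bg == id), integer(1))
    cavity <- enclosed_ids[which.max(enc_sizes)]
    pocket_ids <- setdiff(enclosed_ids, cavity)
    if (length(pocket_ids) > 0)
      failure_bloodpool <- any(pred == 2L & matrix(comp_bg %in% pocket_ids,
                                                   nrow(pred), ncol(pred)))
  }
  list(failure_bloodpool = failure_bloodpool,
       failure_noncontiguous = failure_noncontiguous)
}

evaluate_solution <- function(mask, truth, spacing_mm, series_id, method,
                              upp = NA_real_, member_id = NA_character_) {
  fl <- detect_failure(mask)
  hd <- suppressWarnings(hd95(mask, truth, 1L, spacing_mm))
  tibble::tibble(series_id = series_id, method = method,
                 dice_myo = dice_score(mask, truth, 1L),
                 hd95_mm = hd,
                 failure_bloodpool = fl$failure_bloodpool,
                 failure_noncontiguous = fl$failure_noncontiguous,
                 failed = fl$failure_bloodpool | fl$failure_noncontiguous,
                 upp = upp, member_id = member_id)
}

#' Compare adaptive and established model selection on test sets
#'
#' For every series of every test set, segments with (a) per-case
#' uncertainty-guided selection over the pool ("adaptive") and (b) the
#' single best-validation member ("established"), then scores myocardium
#' Dice, HD95, and the two failure criteria. Per-dataset summaries include
#' mean ± sd of both metrics, failure rates, an unpaired two-tailed t-test
#' on Dice and Fisher's exact test on failure counts.
#'
#' @param pool a trained `model_pool`.
#' @param test_sets named list of test datasets, each a list of
#'   preprocessed `list(series, mask)` entries.
#' @param grid the inference [build_grid()].
#' @param metric selection metric passed to [select_min_uncertainty()].
#' @param out_dir optional directory; when given, per-series results and
#'   the selection log are written as CSV.
#' @return An object of class `method_comparison`: `per_series` (tibble),
#'   `summary` (tibble), `tests` (tibble of p-values per dataset) and
#'   `selection_log`.
#' @export
compare_methods <- function(pool, test_sets, grid,
                            metric = c("upp", "total_energy"), out_dir = NULL) {
  metric <- match.arg(metric)
  established <- select_best_validation(pool)
  rows <- list(); logs <- list()
  for (ds in names(test_sets)) {
    for (el in test_sets[[ds]]) {
      sp <- el$series$pixel_spacing_mm
      ad <- select_min_uncertainty(pool, el$series, grid, metric = metric,
                                   truth = el$mask)
      logs[[length(logs) + 1L]] <- dplyr::mutate(ad$log, dataset = ds)
      est_seg <- segment_series(established, el$series, grid)
      est_umap <- compute_umap(est_seg$stack)
      rows[[length(rows) + 1L]] <- dplyr::bind_rows(
        evaluate_solution(ad$mask, el$mask, sp, el$series$series_id,
                          "adaptive", ad$upp, ad$member_id),
        evaluate_solution(est_seg$mask, el$mask, sp, el$series$series_id,
                          "established", compute_upp(est_umap, est_seg$mask),
                          established$member_id)) |>
        dplyr::mutate(dataset = ds)
    }
  }
  per_series <- dplyr::bind_rows(rows) |>
    dplyr::relocate(dataset)
  summary <- per_series |>
    dplyr::group_by(dataset, method) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_dice = mean(dice_myo), sd_dice = stats::sd(dice_myo),
      mean_hd95 = mean(hd95_mm[is.finite(hd95_mm)]),
      sd_hd95 = stats::sd(hd95_mm[is.finite(hd95_mm)]),
      failure_rate = mean(failed), .groups = "drop")
  tests <- per_series |>
    dplyr::group_by(dataset) |>
    dplyr::summarise(
      p_dice = tryCatch(
        stats::t.test(dice_myo[method == "adaptive"],
                      dice_myo[method == "established"])$p.value,
        error = function(e) NA_real_),
      p_failures = stats::fisher.test(table(
        factor(method, c("adaptive", "established")),
        factor(failed, c(FALSE, TRUE))))$p.value,
      .groups = "drop")
  selection_log <- dplyr::bind_rows(logs)
  out <- structure(list(per_series = per_series, summary = summary,
                        tests = tests, selection_log = selection_log,
                        metric = metric),
                   class = "method_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_series, file.path(out_dir, "per_series.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(selection_log, file.path(out_dir, "selection_log.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print(x$summary)
  print(x$tests)
  invisible(x)
}
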