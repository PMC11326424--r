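#' Construct a perfusion series object
#'
#' A `perfusion_series` holds one short-axis slice's dynamic (2D+time)
#' intensity volume together with its geometric and temporal metadata. It is
#' the unit of analysis throughout the package.
#'
#' @param intensities numeric H x W x T array of pixel intensities; all
#'   values must be finite.
#' @param pixel_spacing_mm numeric length-2 vector `(dy, dx)` in mm.
#' @param frame_times_s numeric length-T vector of frame acquisition times
#'   in seconds, strictly increasing.
#' @param heart_center numeric length-2 vector `(row, col)` of the heart
#'   location in 1-based pixel coordinates.
#' @param series_id character scalar identifier.
#'
#' @return An object of class `perfusion_series`.
#' @export
perfusion_series <- function(intensities, pixel_spacing_mm = c(1, 1),
                             frame_times_s = NULL,
                             heart_center = NULL, series_id = "series") {
  d <- dim(intensities)
  if (length(d) != 3L) stop("`intensities` must be an H x W x T array")
  if (d[3] < 2L) stop("a perfusion series needs at least 2 frames")
  if (!all(is.finite(intensities))) stop("`intensities` must be finite")
  if (is.null(frame_times_s)) frame_times_s <- seq_len(d[3]) - 1
  if (length(frame_times_s) != d[3] || any(diff(frame_times_s) <= 0))
    stop("`frame_times_s` must be strictly increasing with one entry per frame")
  if (is.null(heart_center)) heart_center <- (d[1:2] + 1) / 2
  structure(
    list(intensities = intensities,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         frame_times_s = as.numeric(frame_times_s),
         heart_center = as.numeric(heart_center),
         series_id = as.character(series_id)),
    class = "perfusion_series")
}

#' @export
print.perfusion_series <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<perfusion_series '%s'> %d x %d pixels, %d frames, spacing %.2f x %.2f mm\n",
    x$series_id, d[1], d[2], d[3], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  cat(sprintf("  heart center (row, col): %.1f, %.1f; t in [%.1f, %.1f] s\n",
              x$heart_center[1], x$heart_center[2],
              min(x$frame_times_s), max(x$frame_times_s)))
  invisible(x)
}

#' @export
dim.perfusion_series <- function(x) dim(x$intensities)

# Label codes: 0 background, 1 LV myocardium, 2 bloodpool.
#' Validate a label mask
#'
#' Checks that `mask` is an integer-valued matrix with values in
#' `{0, 1, 2}` (background / LV myocardium / bloodpool), optionally matched
#' against the spatial dimensions of a series.
#'
#' @param mask integer matrix of per-pixel class codes.
#' @param series optional `perfusion_series` whose H x W must match.
#' @return The mask, invisibly, as an integer-storage matrix.
#' @export
validate_mask <- function(mask, series = NULL) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  v <- as.vector(mask)
  if (anyNA(v) || !all(v %in% 0:2))
    stop("mask values must be in {0 (background), 1 (myocardium), 2 (bloodpool)}")
  if (!is.null(series) && !identical(dim(mask), dim(series$intensities)[1:2]))
    stop("mask dimensions do not match the series")
  storage.mode(mask) <- "integer"
  invisible(mask)
}
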