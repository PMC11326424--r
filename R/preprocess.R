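#' Preprocessing specification
#'
#' Defines the fixed analysis grid every series is standardized to before
#' training or inference: spatial upsampling, a square crop centered on the
#' heart, piecewise-cubic temporal resampling to a fixed number of frames,
#' and per-series min-max normalization to `[0, 1]`.
#'
#' @param target_matrix side of the square output crop in pixels.
#' @param target_frames number of output time frames (at least 2).
#' @param upsample_factor spatial upsampling ratio applied before cropping.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(target_matrix = 128, target_frames = 30,
                            upsample_factor = 2) {
  if (target_frames < 2) stop("`target_frames` must be >= 2")
  if (upsample_factor <= 0) stop("`upsample_factor` must be positive")
  structure(list(target_matrix = as.integer(target_matrix),
                 target_frames = as.integer(target_frames),
                 upsample_factor = upsample_factor),
            class = "preprocess_spec")
}

#' Standardize a series (and optional mask) to the analysis grid
#'
#' Applies, in order: cubic-spline spatial upsampling (nearest-neighbor for
#' the mask, so label codes are preserved), a half-open square crop of
#' `target_matrix` pixels centered on the series' `heart_center`,
#' shape-preserving piecewise-cubic (PCHIP) temporal resampling onto a
#' uniform grid of `target_frames` points spanning the input time range,
#' and min-max normalization of the whole 2D+time volume to `[0, 1]`
#' (one global min/max per series, not per frame).
#'
#' @param raw a `perfusion_series` carrying a `heart_center`.
#' @param mask optional label mask aligned with `raw`.
#' @param spec a [preprocess_spec()].
#' @return `list(series, mask)`; `mask` is `NULL` when none was given.
#' @export
preprocess_series <- function(raw, mask = NULL, spec = preprocess_spec()) {
  stopifnot(inherits(raw, "perfusion_series"), inherits(spec, "preprocess_spec"))
  d <- dim(raw$intensities)
  H <- d[1]; W <- d[2]; T <- d[3]
  f <- spec$upsample_factor
  if (!is.null(mask)) mask <- validate_mask(mask, raw)

  uH <- round(H * f); uW <- round(W * f)
  n <- spec$target_matrix
  ctr <- raw$heart_center * f - (f - 1) / 2  # pixel-center mapping of the heart
  r0 <- round(ctr[1]) - n %/% 2 + 1L
  c0 <- round(ctr[2]) - n %/% 2 + 1L
  if (r0 < 1 || c0 < 1 || r0 + n - 1 > uH || c0 + n - 1 > uW)
    stop(sprintf("geometry error: crop [%d..%d] x [%d..%d] exceeds the %d x %d upsampled frame",
                 r0, r0 + n - 1, c0, c0 + n - 1, uH, uW))
  rows <- r0:(r0 + n - 1L); cols <- c0:(c0 + n - 1L)

  cropped <- array(0, c(n, n, T))
  for (t in seq_len(T)) {
    frame <- raw$intensities[, , t]
    up <- if (f == 1) frame else resize_cubic(frame, uH, uW)
    cropped[, , t] <- up[rows, cols]
  }
  if (!is.null(mask)) {
    up_mask <- if (f == 1) mask else resize_nearest(mask, uH, uW)
    mask <- up_mask[rows, cols]
  }

  t_in <- raw$frame_times_s
  t_out <- seq(t_in[1], t_in[T], length.out = spec$target_frames)
  flat <- matrix(cropped, n * n, T)
  flat <- pchip_resample(flat, t_in, t_out)
  out <- array(flat, c(n, n, spec$target_frames))

  rng <- range(out)
  if (rng[1] == rng[2])
    stop("normalization error: series is constant (max equals min), cannot min-max scale")
  out <- (out - rng[1]) / (rng[2] - rng[1])

  series <- perfusion_series(
    out,
    pixel_spacing_mm = raw$pixel_spacing_mm / f,
    frame_times_s = t_out,
    heart_center = c((n + 1) / 2, (n + 1) / 2),
    series_id = raw$series_id)
  list(series = series,
       mask = if (is.null(mask)) NULL else validate_mask(mask, series))
}

# Preprocess every element of a phantom dataset (list of series/mask pairs).
#' @rdname preprocess_series
#' @param dataset a list of `list(series, mask, ...)` entries, as produced
#'   by [make_dataset()].
#' @export
preprocess_dataset <- function(dataset, spec = preprocess_spec()) {
  lapply(dataset, function(el) {
    pp <- preprocess_series(el$series, el$mask, spec)
    list(series = pp$series, mask = pp$mask, config = el$config)
  })
}
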