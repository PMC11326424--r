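#' Gamma-variate contrast enhancement curve
#'
#' Standard bolus-passage model for first-pass contrast enhancement. The
#' curve is zero up to the onset time `t0`, rises to a single peak of height
#' `A` at `t0 + alpha * beta`, and decays exponentially:
#' \deqn{f(t) = A \left(\frac{t - t_0}{\alpha\beta}\right)^{\alpha}
#'   \exp\!\left(\alpha - \frac{t - t_0}{\beta}\right), \quad t > t_0.}
#'
#' @param t numeric vector of times (seconds).
#' @param t0 onset time (seconds).
#' @param alpha shape parameter, must be positive.
#' @param beta rate parameter (seconds), must be positive.
#' @param A peak amplitude, must be non-negative.
#' @return Numeric vector of intensities, `0` for `t <= t0`.
#' @examples
#' t <- seq(0, 30, by = 0.5)
#' plot(t, gamma_variate_curve(t, t0 = 5, alpha = 3, beta = 1.8, A = 1), type = "l")
#' @export
gamma_variate_curve <- function(t, t0, alpha, beta, A) {
  if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be positive")
  if (A < 0) stop("`A` must be non-negative")
  out <- numeric(length(t))
  up <- t > t0
  tu <- (t[up] - t0)
  out[up] <- A * (tu / (alpha * beta))^alpha * exp(alpha - tu / beta)
  out
}

#' Phantom configuration
#'
#' Parameters of the synthetic short-axis first-pass perfusion phantom:
#' concentric left-ventricular geometry (bloodpool disk surrounded by a
#' myocardial ring, optional right-ventricular crescent), per-tissue
#' gamma-variate wash-in curves ordered RV pool, then LV pool, then
#' myocardium, an optional hypoperfused angular sector, a smooth
#' multiplicative coil-shading field, and additive Gaussian noise.
#'
#' @param image_size square image side in pixels.
#' @param n_frames number of time frames.
#' @param dt_s frame spacing in seconds.
#' @param cavity_radius LV bloodpool radius in pixels.
#' @param ring_thickness myocardial ring thickness in pixels.
#' @param rv_crescent logical; add a right-ventricular crescent (labelled
#'   bloodpool) left of the LV.
#' @param curve_params named list with elements `rv`, `lv`, `myo`, each a
#'   numeric vector `c(t0, alpha, beta, A)` of gamma-variate parameters.
#' @param baselines named numeric vector of pre-contrast intensities for
#'   `background`, `myo`, `blood`.
#' @param defect_spec `NULL`, or `list(theta_start, theta_end, multiplier)`:
#'   an angular sector (radians, half-open, measured anticlockwise from the
#'   +x image axis) whose full myocardial signal is scaled by `multiplier`
#'   in `[0, 1)`.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param shading_strength amplitude of the multiplicative bias field
#'   (`0` disables shading).
#' @param heart_center optional `(row, col)`; defaults to the image center.
#' @param seed integer RNG seed; the phantom is deterministic given the
#'   configuration.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128, n_frames = 30, dt_s = 1,
                           cavity_radius = 18, ring_thickness = 10,
                           rv_crescent = TRUE,
                           curve_params = list(
                             rv = c(t0 = 2, alpha = 3, beta = 1.5, A = 0.9),
                             lv = c(t0 = 5, alpha = 3, beta = 1.8, A = 1.0),
                             myo = c(t0 = 8, alpha = 3.5, beta = 2.5, A = 0.35)),
                           baselines = c(background = 0.08, myo = 0.12, blood = 0.10),
                           defect_spec = NULL,
                           noise_sigma = 0.02, shading_strength = 0.15,
                           heart_center = NULL, seed = 1L) {
  if (cavity_radius + ring_thickness >= image_size / 2)
    stop("geometry error: cavity_radius + ring_thickness must be < image_size/2")
  if (n_frames < 2) stop("need at least 2 frames")
  amps <- vapply(curve_params, function(p) p[[4]], numeric(1))
  if (any(amps < 0) || any(baselines < 0)) stop("all amplitudes must be >= 0")
  if (!is.null(defect_spec)) {
    m <- defect_spec$multiplier
    if (is.null(m) || m < 0 || m >= 1)
      stop("defect multiplier must be in [0, 1)")
  }
  if (is.null(heart_center)) heart_center <- rep((image_size + 1) / 2, 2)
  structure(
    list(image_size = as.integer(image_size), n_frames = as.integer(n_frames),
         dt_s = dt_s, cavity_radius = cavity_radius,
         ring_thickness = ring_thickness, rv_crescent = isTRUE(rv_crescent),
         curve_params = curve_params, baselines = baselines,
         defect_spec = defect_spec, noise_sigma = noise_sigma,
         shading_strength = shading_strength,
         heart_center = as.numeric(heart_center), seed = as.integer(seed)),
    class = "phantom_config")
}

# Smooth multiplicative bias field: 1 + strength * g, where g is a sum of
# 2-4 broad Gaussian bumps rescaled to peak absolute value 1.
shading_field <- function(H, W, strength) {
  if (strength == 0) return(matrix(1, H, W))
  n_bumps <- sample(2:4, 1)
  g <- matrix(0, H, W)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(n_bumps)) {
    rc <- runif(1, 1, H); cc0 <- runif(1, 1, W)
    sig <- runif(1, 0.3, 0.7) * max(H, W)
    sgn <- sample(c(-1, 1), 1)
    g <- g + sgn * exp(-((rr - rc)^2 + (cc - cc0)^2) / (2 * sig^2))
  }
  g <- g / max(abs(g))
  1 + strength * g
}

#' Generate a synthetic perfusion series with exact ground truth
#'
#' Renders the phantom described by a [phantom_config()]: each tissue
#' follows its gamma-variate wash-in curve (RV pool peaks before the LV
#' pool, which peaks before the myocardium), the optional defect sector has
#' its myocardial signal scaled down, a smooth multiplicative shading field
#' and additive Gaussian noise are applied. The label mask describes the
#' noise-free geometry: 0 background, 1 LV myocardium, 2 bloodpool (LV
#' cavity and RV crescent).
#'
#' @param config a [phantom_config()].
#' @return A list with elements `series` (a `perfusion_series`), `mask`
#'   (integer label matrix) and `config`.
#' @examples
#' ph <- make_phantom(phantom_config(image_size = 64, n_frames = 10,
#'                                   cavity_radius = 10, ring_thickness = 6))
#' table(ph$mask)
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  H <- W <- config$image_size
  T <- config$n_frames
  ctr <- config$heart_center
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
  r_in <- config$cavity_radius
  r_out <- r_in + config$ring_thickness

  # tissue index: 0 background, 1 myocardium, 2 LV pool, 3 RV pool
  tissue <- matrix(0L, H, W)
  tissue[d <= r_out] <- 1L
  tissue[d <= r_in] <- 2L
  if (config$rv_crescent) {
    rv_radius <- 1.1 * r_in
    rv_ctr <- c(ctr[1], ctr[2] - (r_out + 0.6 * rv_radius))
    d2 <- sqrt((rr - rv_ctr[1])^2 + (cc - rv_ctr[2])^2)
    tissue[d2 <= rv_radius & d > r_out + 1] <- 3L
  }

  mask <- matrix(0L, H, W)
  mask[tissue == 1L] <- 1L
  mask[tissue >= 2L] <- 2L

  tt <- (seq_len(T) - 1) * config$dt_s
  cp <- config$curve_params
  bl <- config$baselines
  curves <- rbind(
    background = rep(bl[["background"]], T),
    myo   = bl[["myo"]]   + gamma_variate_curve(tt, cp$myo[[1]], cp$myo[[2]], cp$myo[[3]], cp$myo[[4]]),
    lv    = bl[["blood"]] + gamma_variate_curve(tt, cp$lv[[1]],  cp$lv[[2]],  cp$lv[[3]],  cp$lv[[4]]),
    rv    = bl[["blood"]] + gamma_variate_curve(tt, cp$rv[[1]],  cp$rv[[2]],  cp$rv[[3]],  cp$rv[[4]]))

  defmult <- matrix(1, H, W)
  if (!is.null(config$defect_spec)) {
    ds <- config$defect_spec
    theta <- atan2(rr - ctr[1], cc - ctr[2]) %% (2 * pi)
    span <- (theta - ds$theta_start) %% (2 * pi)
    width <- (ds$theta_end - ds$theta_start) %% (2 * pi)
    in_sector <- span < width
    defmult[tissue == 1L & in_sector] <- ds$multiplier
  }

  intensities <- with_seed(config$seed, {
    bias <- shading_field(H, W, config$shading_strength)
    arr <- array(0, c(H, W, T))
    for (t in seq_len(T)) {
      frame <- matrix(curves[tissue + 1L, t], H, W) * defmult * bias
      arr[, , t] <- frame
    }
    if (config$noise_sigma > 0)
      arr <- arr + array(rnorm(H * W * T, sd = config$noise_sigma), c(H, W, T))
    arr
  })

  series <- perfusion_series(
    intensities, pixel_spacing_mm = c(1.8, 1.8), frame_times_s = tt,
    heart_center = ctr,
    series_id = sprintf("phantom-seed%d", config$seed))
  list(series = series, mask = validate_mask(mask, series), config = config)
}

#' Inject frame-level misregistration into a series
#'
#' Emulates residual motion-correction errors by translating a random
#' subset of frames rigidly in-plane (random direction, fixed magnitude,
#' bilinear resampling with edge replication). The label mask is untouched:
#' it describes the reference geometry the corrupted frames should have.
#'
#' @param series a `perfusion_series`.
#' @param n_bad_frames number of frames to displace, `0..T`.
#' @param shift_px displacement magnitude in pixels (non-negative, at most
#'   a quarter of the image size).
#' @param seed integer seed controlling which frames move and where.
#' @return A `perfusion_series` with the selected frames displaced.
#' @export
inject_motion_error <- function(series, n_bad_frames, shift_px, seed = 1L) {
  stopifnot(inherits(series, "perfusion_series"))
  d <- dim(series$intensities)
  T <- d[3]
  if (n_bad_frames < 0 || n_bad_frames > T)
    stop("`n_bad_frames` must be between 0 and the number of frames")
  if (shift_px < 0) stop("`shift_px` must be non-negative")
  if (shift_px > min(d[1], d[2]) / 4)
    stop("parameter error: shift larger than image_size/4")
  if (n_bad_frames == 0 || shift_px == 0) return(series)
  out <- series
  with_seed(seed, {
    frames <- sample.int(T, n_bad_frames)
    for (f in frames) {
      phi <- runif(1, 0, 2 * pi)
      out$intensities[, , f] <- shift_frame(series$intensities[, , f],
                                            dy = shift_px * sin(phi),
                                            dx = shift_px * cos(phi))
    }
  })
  out
}

#' Phantom configuration samplers
#'
#' Returns a function `f(seed)` drawing a randomized [phantom_config()].
#' The `"internal"` style represents the training distribution; the
#' `"shifted"` style emulates a dataset shift: higher noise, stronger coil
#' shading, a larger cavity with a thinner ring, and a systematic offset of
#' the myocardial peak enhancement amplitude.
#'
#' @param style `"internal"` or `"shifted"`.
#' @param image_size native phantom size in pixels (cropped later by
#'   preprocessing).
#' @param n_frames native number of frames.
#' @param myo_peak_offset additive offset on the myocardial curve amplitude;
#'   defaults to `0` for `"internal"` and `-0.08` for `"shifted"`.
#' @return A function mapping an integer seed to a `phantom_config`, with
#'   attribute `"style"`.
#' @export
phantom_sampler <- function(style = c("internal", "shifted"),
                            image_size = 72, n_frames = 20,
                            myo_peak_offset = NULL) {
  style <- match.arg(style)
  shifted <- style == "shifted"
  if (is.null(myo_peak_offset)) myo_peak_offset <- if (shifted) -0.08 else 0
  f <- function(seed) {
    with_seed(seed, {
      jit <- function(x) x * runif(1, 0.9, 1.1)
      cavity <- if (shifted) runif(1, 11, 15) else runif(1, 9, 12)
      ring <- if (shifted) runif(1, 4, 6) else runif(1, 5, 7)
      ctr <- (image_size + 1) / 2 + runif(2, -3, 3)
      cp <- list(
        rv  = c(t0 = jit(2), alpha = jit(3),   beta = jit(1.5), A = jit(0.9)),
        lv  = c(t0 = jit(5), alpha = jit(3),   beta = jit(1.8), A = jit(1.0)),
        myo = c(t0 = jit(8), alpha = jit(3.5), beta = jit(2.5),
                A = max(0.02, 0.35 * runif(1, 0.9, 1.1) + myo_peak_offset)))
      defect <- NULL
      if (runif(1) < if (shifted) 0.5 else 0.4) {
        th0 <- runif(1, 0, 2 * pi)
        defect <- list(theta_start = th0,
                       theta_end = th0 + runif(1, pi / 6, pi / 2),
                       multiplier = runif(1, 0.3, 0.8))
      }
      phantom_config(
        image_size = image_size, n_frames = n_frames,
        cavity_radius = cavity, ring_thickness = ring,
        curve_params = cp, defect_spec = defect,
        noise_sigma = if (shifted) runif(1, 0.04, 0.08) else runif(1, 0.01, 0.03),
        shading_strength = if (shifted) runif(1, 0.2, 0.4) else runif(1, 0.05, 0.2),
        heart_center = ctr, seed = seed)
    })
  }
  attr(f, "style") <- style
  f
}

#' Generate a reproducible set of phantom series
#'
#' @param n_series number of series to generate (at least 1).
#' @param sampler a configuration sampler from [phantom_sampler()] (or any
#'   function mapping a seed to a `phantom_config`).
#' @param seed integer seed; each series receives a distinct derived seed.
#' @return A list of length `n_series`; each element is the
#'   `list(series, mask, config)` returned by [make_phantom()], with the
#'   sampler style recorded in `series$series_id`.
#' @export
make_dataset <- function(n_series, sampler, seed = 1L) {
  if (n_series < 1) stop("`n_series` must be >= 1")
  style <- attr(sampler, "style") %||% "custom"
  seeds <- derive_seeds(seed, n_series)
  lapply(seq_len(n_series), function(i) {
    ph <- make_phantom(sampler(seeds[i]))
    ph$series$series_id <- sprintf("%s-%03d", style, i)
    ph
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
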