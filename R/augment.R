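#' Training augmentation policy
#'
#' Two augmentation families are used during training: segmentation-variant
#' spatial transforms (one affine map — rotation, shear, translation,
#' scale — applied identically to every frame and to the label mask) and
#' segmentation-invariant intensity transforms (additive Gaussian noise,
#' gamma-style contrast change, and a smooth multiplicative spatial
#' modulation emulating coil-sensitivity weighting) that leave the ground
#' truth untouched.
#'
#' Ranges are symmetric around the identity and chosen to be
#' label-preserving at the default analysis scale.
#'
#' @param rotation_deg rotation range (degrees), sampled uniformly in
#'   `[-rotation_deg, rotation_deg]` (or a length-2 vector giving the range).
#' @param shear_deg shear angle range (degrees).
#' @param translation_px translation range (pixels, per axis).
#' @param scale_range multiplicative scale range; must lie inside (0.5, 2).
#' @param noise_sigma_range additive noise standard deviation range.
#' @param contrast_gamma_range gamma range for contrast change.
#' @param modulation_n_bumps range of Gaussian bumps in the modulation field.
#' @param modulation_amplitude_range relative amplitude range of the field.
#' @param modulation_width_range bump width range, as a fraction of the
#'   image side.
#' @param p_affine,p_noise,p_gamma,p_modulation per-transform application
#'   probabilities, each in `[0, 1]`.
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(rotation_deg = 15, shear_deg = 8, translation_px = 8,
                           scale_range = c(0.9, 1.1),
                           noise_sigma_range = c(0, 0.05),
                           contrast_gamma_range = c(0.7, 1.4),
                           modulation_n_bumps = c(2, 4),
                           modulation_amplitude_range = c(-0.3, 0.3),
                           modulation_width_range = c(0.3, 0.8),
                           p_affine = 0.8, p_noise = 0.5, p_gamma = 0.5,
                           p_modulation = 0.5) {
  as_range <- function(x) if (length(x) == 1) c(-x, x) else sort(as.numeric(x))
  if (min(scale_range) <= 0.5 || max(scale_range) >= 2.0)
    stop("`scale_range` must lie within (0.5, 2.0)")
  p <- c(p_affine, p_noise, p_gamma, p_modulation)
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  structure(list(
    rotation_deg = as_range(rotation_deg), shear_deg = as_range(shear_deg),
    translation_px = as_range(translation_px), scale_range = sort(scale_range),
    noise_sigma_range = sort(noise_sigma_range),
    contrast_gamma_range = sort(contrast_gamma_range),
    modulation_n_bumps = round(range(modulation_n_bumps)),
    modulation_amplitude_range = sort(modulation_amplitude_range),
    modulation_width_range = sort(modulation_width_range),
    p_affine = p_affine, p_noise = p_noise, p_gamma = p_gamma,
    p_modulation = p_modulation), class = "augment_policy")
}

#' A policy whose every transform is the identity (useful for testing and
#' for disabling augmentation).
#' @rdname augment_policy
#' @export
identity_policy <- function() {
  augment_policy(rotation_deg = 0, shear_deg = 0, translation_px = 0,
                 scale_range = c(1, 1), noise_sigma_range = c(0, 0),
                 contrast_gamma_range = c(1, 1),
                 modulation_amplitude_range = c(0, 0),
                 p_affine = 0, p_noise = 0, p_gamma = 0, p_modulation = 0)
}

# Build the inverse map of the sampled forward affine (about the image
# center, plus translation), for use with warp_affine_2d.
sample_affine_inverse <- function(policy, H, W) {
  th <- runif(1, policy$rotation_deg[1], policy$rotation_deg[2]) * pi / 180
  sh <- tan(runif(1, policy$shear_deg[1], policy$shear_deg[2]) * pi / 180)
  s <- runif(1, policy$scale_range[1], policy$scale_range[2])
  tr <- runif(2, policy$translation_px[1], policy$translation_px[2])
  # forward linear part: scale %*% shear %*% rotation (row, col coords)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, 0, sh, 1), 2, 2)
  A <- s * (Sh %*% R)
  if (abs(det(A)) < 1e-6) return(sample_affine_inverse(policy, H, W))
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  Ainv <- solve(A)
  # output pixel p maps to source Ainv %*% (p - ctr - tr) + ctr
  off <- ctr - Ainv %*% (ctr + tr)
  cbind(Ainv, off)
}

#' Segmentation-variant augmentation
#'
#' Samples one affine transform from the policy and applies it identically
#' to every frame of the series (bilinear) and to the label mask
#' (nearest-neighbor, so no fractional labels appear). Regions mapped from
#' outside the frame are filled with intensity 0 / label 0.
#'
#' @param series a preprocessed `perfusion_series`.
#' @param mask the aligned label mask.
#' @param policy an [augment_policy()].
#' @param seed optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is used (one draw per call).
#' @return `list(series, mask)`.
#' @export
augment_variant <- function(series, mask, policy = augment_policy(),
                            seed = NULL) {
  stopifnot(inherits(series, "perfusion_series"))
  mask <- validate_mask(mask, series)
  run <- function() {
    if (runif(1) > policy$p_affine) return(list(series = series, mask = mask))
    d <- dim(series$intensities)
    minv <- sample_affine_inverse(policy, d[1], d[2])
    out <- series
    for (t in seq_len(d[3]))
      out$intensities[, , t] <- warp_affine_2d(series$intensities[, , t], minv,
                                               interp = "bilinear", fill = 0)
    new_mask <- warp_affine_2d(mask, minv, interp = "nearest", fill = 0)
    storage.mode(new_mask) <- "integer"
    list(series = out, mask = new_mask)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Segmentation-invariant augmentation
#'
#' Applies, each with its policy probability: additive Gaussian noise,
#' a gamma-style contrast change (`x^gamma` on the `[0, 1]` scale), and a
#' smooth multiplicative modulation field constant across time. The output
#' is clipped back to `[0, 1]` unless `clip = FALSE`. The mask is never
#' touched by these transforms.
#'
#' @inheritParams augment_variant
#' @param clip logical; clip the result to `[0, 1]` (default `TRUE`).
#' @return A `perfusion_series`.
#' @export
augment_invariant <- function(series, policy = augment_policy(), seed = NULL,
                              clip = TRUE) {
  stopifnot(inherits(series, "perfusion_series"))
  run <- function() {
    x <- series$intensities
    d <- dim(x)
    if (runif(1) <= policy$p_gamma) {
      g <- runif(1, policy$contrast_gamma_range[1], policy$contrast_gamma_range[2])
      x <- pmin(pmax(x, 0), 1)^g
    }
    if (runif(1) <= policy$p_modulation) {
      amp <- runif(1, policy$modulation_amplitude_range[1],
                   policy$modulation_amplitude_range[2])
      nb <- sample(policy$modulation_n_bumps[1]:policy$modulation_n_bumps[2], 1)
      rr <- matrix(seq_len(d[1]), d[1], d[2])
      cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
      g <- matrix(0, d[1], d[2])
      for (i in seq_len(nb)) {
        ctr <- runif(2, 1, c(d[1], d[2]))
        wid <- runif(1, policy$modulation_width_range[1],
                     policy$modulation_width_range[2]) * max(d[1:2])
        g <- g + exp(-((rr - ctr[1])^2 + (cc - ctr[2])^2) / (2 * wid^2))
      }
      if (max(g) > 0) g <- g / max(g)
      field <- 1 + amp * g
      x <- sweep(x, c(1, 2), field, "*")
    }
    if (runif(1) <= policy$p_noise) {
      sig <- runif(1, policy$noise_sigma_range[1], policy$noise_sigma_range[2])
      if (sig > 0) x <- x + array(rnorm(prod(d), sd = sig), d)
    }
    if (clip) x <- pmin(pmax(x, 0), 1)
    out <- series
    out$intensities <- x
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
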