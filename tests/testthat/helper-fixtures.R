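# Shared fixtures, built in code at test time.

desk_spec <- function() preprocess_spec(target_matrix = 64, target_frames = 16,
                                        upsample_factor = 1)

# One clean (noise/shading-free) phantom on the desk analysis grid.
clean_phantom_pp <- function(seed = 3, noise = 0, shading = 0, defect = NULL) {
  ph <- make_phantom(phantom_config(
    image_size = 72, n_frames = 20, cavity_radius = 10, ring_thickness = 6,
    defect_spec = defect, noise_sigma = noise, shading_strength = shading,
    seed = seed))
  pp <- preprocess_series(ph$series, ph$mask, desk_spec())
  list(series = pp$series, mask = pp$mask, raw = ph)
}

# A series whose pixels encode their ground-truth label in the temporal
# mean (label / 4), so a content-deterministic mock can recover the exact
# truth for any patch without knowing its origin.
label_encoded_series <- function(mask, T = 16) {
  enc <- array(rep(as.numeric(mask) / 4, T), c(dim(mask), T))
  perfusion_series(enc, series_id = "label-encoded")
}

mock_truth_model <- function() {
  function(patch) {
    lab <- round(apply(patch, c(1, 2), mean) * 4)
    P <- nrow(lab)
    a <- array(0, c(P, P, 3))
    for (cls in 0:2) a[, , cls + 1] <- (lab == cls) * 1
    a
  }
}

mock_constant_model <- function(p_bg = 1, p_myo = 0, p_bp = 0) {
  function(patch) {
    P <- nrow(patch)
    a <- array(0, c(P, P, 3))
    a[, , 1] <- p_bg; a[, , 2] <- p_myo; a[, , 3] <- p_bp
    a
  }
}

# Random valid probability maps (rows on the simplex) for a grid.
random_simplex_maps <- function(grid) {
  P <- grid$patch_size
  lapply(seq_len(nrow(grid$origins)), function(k) {
    m <- matrix(stats::rexp(P * P * 3), P * P, 3)
    m <- m / rowSums(m)
    array(m, c(P, P, 3))
  })
}

# An annular myocardium mask with LV-pool cavity, for failure-criterion
# tests. `gap` cuts an angular sector (radians) out of the ring.
ring_mask <- function(n = 64, r_in = 10, r_out = 16, gap = NULL) {
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
  m <- matrix(0L, n, n)
  m[d <= r_out] <- 1L
  m[d <= r_in] <- 2L
  if (!is.null(gap)) {
    theta <- atan2(rr - ctr, cc - ctr) %% (2 * pi)
    m[m == 1L & theta < gap] <- 0L
  }
  m
}
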