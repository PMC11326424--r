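test_that("gamma-variate curve has the stated onset, peak and closed form", {
  t <- seq(0, 30, by = 0.25)
  # onset value and peak-by-construction
  expect_equal(gamma_variate_curve(5, t0 = 5, alpha = 3, beta = 1.8, A = 1), 0)
  expect_equal(gamma_variate_curve(5 + 3 * 1.8, t0 = 5, alpha = 3, beta = 1.8, A = 0.7),
               0.7)
  # scalar evaluation of the closed form (alpha 2, beta 3, A 1, t0 0, t 3)
  expect_equal(gamma_variate_curve(3, 0, 2, 3, 1), 0.25 * exp(1))
  # peak is the maximum over a fine grid
  y <- gamma_variate_curve(t, t0 = 2, alpha = 3, beta = 1.5, A = 0.9)
  expect_lte(max(y), 0.9 + 1e-12)
  expect_true(all(y[t <= 2] == 0))
  expect_error(gamma_variate_curve(t, 0, -1, 1, 1), "positive")
  expect_error(gamma_variate_curve(t, 0, 1, 0, 1), "positive")
})

test_that("phantom geometry, homogeneity and determinism hold", {
  cfg <- phantom_config(image_size = 72, n_frames = 20, cavity_radius = 10,
                        ring_thickness = 6, noise_sigma = 0,
                        shading_strength = 0, seed = 11)
  ph <- make_phantom(cfg)
  expect_setequal(unique(as.vector(ph$mask)), 0:2)
  # every pixel has exactly one label by construction of a single matrix
  expect_identical(dim(ph$mask), dim(ph$series$intensities)[1:2])
  # homogeneous tissue: all myocardium pixels share one identical curve
  myo <- which(ph$mask == 1L, arr.ind = TRUE)
  curves <- apply(myo, 1, function(rc) ph$series$intensities[rc[1], rc[2], ])
  expect_true(all(abs(curves - curves[, 1]) < 1e-12))
  # determinism
  ph2 <- make_phantom(cfg)
  expect_identical(ph$series$intensities, ph2$series$intensities)
  expect_identical(ph$mask, ph2$mask)
  # noisy phantom is also deterministic given the seed
  cfgn <- phantom_config(image_size = 72, n_frames = 20, cavity_radius = 10,
                         ring_thickness = 6, seed = 12)
  expect_identical(make_phantom(cfgn)$series$intensities,
                   make_phantom(cfgn)$series$intensities)
  expect_error(phantom_config(image_size = 40, cavity_radius = 15,
                              ring_thickness = 6), "geometry")
  expect_error(phantom_config(defect_spec = list(theta_start = 0, theta_end = 1,
                                                 multiplier = 1)), "multiplier")
})

test_that("defect sector scales myocardial peak intensity by its multiplier", {
  cfg <- phantom_config(image_size = 72, n_frames = 20, cavity_radius = 10,
                        ring_thickness = 6, noise_sigma = 0, shading_strength = 0,
                        defect_spec = list(theta_start = 0, theta_end = pi / 2,
                                           multiplier = 0.5), seed = 2)
  ph <- make_phantom(cfg)
  peaks <- apply(ph$series$intensities, c(1, 2), max)
  ctr <- cfg$heart_center
  rr <- matrix(seq_len(72), 72, 72)
  cc <- matrix(seq_len(72), 72, 72, byrow = TRUE)
  theta <- atan2(rr - ctr[1], cc - ctr[2]) %% (2 * pi)
  in_sector <- theta >= 0 & theta < pi / 2
  myo <- ph$mask == 1L
  expect_equal(mean(peaks[myo & in_sector]) / mean(peaks[myo & !in_sector]), 0.5,
               tolerance = 1e-10)
})

test_that("wash-in stage ordering: bloodpool peaks before myocardium", {
  samp <- phantom_sampler("internal")
  for (seed in c(5, 17, 23)) {
    ph <- make_phantom(samp(seed))
    bp <- apply(ph$series$intensities, 3, function(f) mean(f[ph$mask == 2L]))
    my <- apply(ph$series$intensities, 3, function(f) mean(f[ph$mask == 1L]))
    expect_lt(which.max(bp), which.max(my))
  }
})

test_that("motion-error injection displaces exactly the requested frames", {
  ph <- make_phantom(phantom_config(image_size = 72, n_frames = 20,
                                    cavity_radius = 10, ring_thickness = 6,
                                    noise_sigma = 0, shading_strength = 0,
                                    seed = 8))
  # zero shift is the identity
  expect_identical(inject_motion_error(ph$series, 5, 0, seed = 1)$intensities,
                   ph$series$intensities)
  # exactly n_bad_frames frames differ
  out <- inject_motion_error(ph$series, 3, 4, seed = 2)
  differs <- vapply(1:20, function(t)
    !isTRUE(all.equal(out$intensities[, , t], ph$series$intensities[, , t])),
    logical(1))
  expect_identical(sum(differs), 3L)
  # displacing every frame moves the bright-structure centroid by ~ the shift
  s <- 3
  all_out <- inject_motion_error(ph$series, 20, s, seed = 3)
  shifts <- c()
  for (t in 1:20) {
    f0 <- ph$series$intensities[, , t]
    if (sum(f0 > 0.4) < 50) next
    c0 <- colMeans(which(f0 > 0.4, arr.ind = TRUE))
    c1 <- colMeans(which(all_out$intensities[, , t] > 0.4, arr.ind = TRUE))
    shifts <- c(shifts, sqrt(sum((c1 - c0)^2)))
  }
  expect_gt(length(shifts), 5)
  expect_equal(mean(shifts), s, tolerance = 0.2 * s)
  expect_error(inject_motion_error(ph$series, 2, 30, seed = 1), "parameter")
  expect_error(inject_motion_error(ph$series, 25, 2, seed = 1), "between")
})

test_that("make_dataset is reproducible and samplers encode the configured shift", {
  samp <- phantom_sampler("internal")
  expect_length(make_dataset(1, samp, seed = 4), 1)
  d1 <- make_dataset(3, samp, seed = 4)
  d2 <- make_dataset(3, samp, seed = 4)
  expect_identical(lapply(d1, function(e) e$series$intensities),
                   lapply(d2, function(e) e$series$intensities))
  expect_match(d1[[1]]$series$series_id, "^internal-001$")
  # shifted sampler: mean myocardial peak amplitude differs by the offset
  samp_sh <- phantom_sampler("shifted")
  seeds <- 1:400
  a_in <- vapply(seeds, function(s) samp(s)$curve_params$myo[["A"]], numeric(1))
  a_sh <- vapply(seeds + 1000, function(s) samp_sh(s)$curve_params$myo[["A"]],
                 numeric(1))
  expect_equal(mean(a_sh) - mean(a_in), -0.08, tolerance = 0.012)
})
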