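test_that("grid origin counts follow the sliding-window arithmetic", {
  expect_identical(nrow(build_grid(c(128, 128), 64, 16)$origins), 25L)
  expect_identical(nrow(build_grid(c(128, 128), 64, 32)$origins), 9L)
  g1 <- build_grid(c(64, 64), 64, 16)
  expect_identical(nrow(g1$origins), 1L)
  expect_identical(unname(g1$origins[1, ]), c(1L, 1L))
  expect_error(build_grid(c(32, 32), 64, 8), "geometry")
})

test_that("every grid covers all pixels, densest at the center", {
  set.seed(30)
  for (i in 1:20) {
    H <- sample(32:96, 1); W <- sample(32:96, 1)
    P <- sample(8:min(H, W), 1)
    s <- sample(seq_len(max(1, P %/% 2)), 1)  # method strides are <= P/2
    g <- build_grid(c(H, W), P, s)
    cov <- perfuseg:::grid_coverage(g)
    expect_gte(min(cov), 1L)
    # all patches fully inside
    expect_true(all(g$origins[, 1] >= 1 & g$origins[, 1] + P - 1 <= H))
    expect_true(all(g$origins[, 2] >= 1 & g$origins[, 2] + P - 1 <= W))
    if (s < P && H > P && W > P) {
      ctr <- cov[round(H / 2), round(W / 2)]
      expect_gt(ctr, cov[1, 1])
    }
  }
})

test_that("decomposition copies windows and tiles back exactly", {
  pp <- clean_phantom_pp(seed = 3)
  # single-patch grid: the patch is the series
  g1 <- build_grid(c(64, 64), 64, 64)
  p1 <- decompose_series(pp$series, g1)
  expect_equal(p1[[1]][, , ], pp$series$intensities, ignore_attr = TRUE)
  # constant series: all patches identical
  const <- perfusion_series(array(0.5, c(64, 64, 4)) +
                              rep(seq(0, 0.1, length.out = 4), each = 64 * 64))
  gc <- build_grid(c(64, 64), 32, 16)
  pc <- decompose_series(const, gc)
  for (k in seq_along(pc)) expect_equal(pc[[k]], pc[[1]], ignore_attr = TRUE)
  # non-overlapping tiling reassembles the series exactly
  gt <- build_grid(c(64, 64), 32, 32)
  pt <- decompose_series(pp$series, gt)
  rebuilt <- array(NA_real_, dim(pp$series$intensities))
  for (k in seq_len(nrow(gt$origins))) {
    r <- gt$origins[k, 1]; c <- gt$origins[k, 2]
    rebuilt[r:(r + 31), c:(c + 31), ] <- pt[[k]]
  }
  expect_identical(rebuilt, pp$series$intensities)
})

test_that("recombination averages overlapping probabilities on the simplex", {
  g <- build_grid(c(48, 48), 32, 16)  # origins 1 and 17: central overlap
  # identical maps from every patch recombine to that map
  m <- array(rep(c(0.2, 0.5, 0.3), each = 32 * 32), c(32, 32, 3))
  rec <- recombine_patches(rep(list(m), nrow(g$origins)), g)
  expect_equal(rec$probs[20, 20, ], c(0.2, 0.5, 0.3), tolerance = 1e-12)
  st <- rec$stack$probs[20, 20, ]
  expect_true(all(st[!is.na(st)] == 0.5))
  # two overlapping patches with myocardium 0.2 and 0.8 average to 0.5
  g2 <- build_grid(c(32, 48), 32, 16)
  m1 <- array(rep(c(0.5, 0.2, 0.3), each = 32 * 32), c(32, 32, 3))
  m2 <- array(rep(c(0.1, 0.8, 0.1), each = 32 * 32), c(32, 32, 3))
  rec2 <- recombine_patches(list(m1, m2), g2)
  expect_equal(rec2$probs[10, 20, 2], 0.5, tolerance = 1e-12)
  expect_equal(rec2$stack$coverage[10, 20], 2L)
  # property: random simplex inputs stay on the simplex after recombination
  set.seed(31)
  for (i in 1:10) {
    gr <- build_grid(c(40, 40), 16, sample(c(4, 8, 12), 1))
    rr <- recombine_patches(random_simplex_maps(gr), gr)
    sums <- apply(rr$probs, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-6)
    expect_gte(min(rr$stack$coverage), 1L)
  }
  expect_error(recombine_patches(list(m), g), "contract")
})

test_that("argmax mask conversion matches a brute-force loop with tie-breaks", {
  expect_identical(prob_to_mask(array(c(0.1, 0.7, 0.2), c(1, 1, 3)))[1, 1], 1L)
  expect_identical(prob_to_mask(array(rep(1 / 3, 3), c(1, 1, 3)))[1, 1], 0L)
  set.seed(32)
  for (i in 1:20) {
    m <- matrix(stats::rexp(12 * 12 * 3), ncol = 3)
    m <- m / rowSums(m)
    # inject exact ties
    ties <- sample(144, 10)
    m[ties, ] <- m[ties, c(2, 1, 3)] * 0 + 1 / 3
    probs <- array(m, c(12, 12, 3))
    expect_identical(prob_to_mask(probs), oracle_to_mask(probs))
  }
})
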