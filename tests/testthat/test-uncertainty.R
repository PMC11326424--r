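make_stack <- function(probs_list) {
  # probs_list: list of per-pixel probability vectors for a 1 x n frame
  n <- length(probs_list)
  K <- max(lengths(probs_list))
  arr <- array(NA_real_, c(1, n, K))
  for (i in seq_len(n)) arr[1, i, seq_along(probs_list[[i]])] <- probs_list[[i]]
  structure(list(probs = arr,
                 coverage = matrix(lengths(probs_list), 1, n)),
            class = "patch_prob_stack")
}

test_that("U-map is the population standard deviation with its printed bound", {
  st <- make_stack(list(c(0.7, 0.7, 0.7), c(0, 1), 0.4))
  u <- compute_umap(st)
  expect_identical(u[1, 1], 0)        # zero dispersion
  expect_identical(u[1, 2], 0.5)      # two-point {0,1} attains the bound
  expect_identical(u[1, 3], 0)        # coverage-1 pixels get 0
  expect_error(compute_umap(structure(list(), class = "list")), "contract")
})

test_that("U-map matches a brute-force per-pixel implementation on random stacks", {
  set.seed(70)
  for (i in 1:12) {
    g <- build_grid(c(24, 24), 8, sample(c(2, 4, 6), 1))
    maps <- random_simplex_maps(g)
    rec <- recombine_patches(maps, g)
    expect_equal(compute_umap(rec$stack), oracle_umap(maps, g), tolerance = 1e-12)
  }
})

test_that("Upp normalizes the U-map energy by the myocardial pixel count", {
  umap <- matrix(0, 10, 10)
  mask <- matrix(0L, 10, 10); mask[1:5, 1:5] <- 1L
  expect_identical(compute_upp(umap, mask), 0)
  umap[3, 3] <- 0.5
  expect_equal(compute_upp(umap, mask), 0.25 / 25)
  expect_identical(compute_upp(umap, matrix(0L, 10, 10)), Inf)
  expect_error(compute_upp(umap - 1, mask), "negative")
  # Upp ignores the non-myocardium label structure
  mask2 <- mask; mask2[mask2 == 0L] <- 2L
  expect_identical(compute_upp(umap, mask), compute_upp(umap, mask2))
})

test_that("total energy is the unnormalized Upp and scales quadratically", {
  set.seed(71)
  umap <- matrix(runif(64, 0, 0.5), 8, 8)
  mask <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
  expect_identical(total_energy_metric(matrix(0, 4, 4)), 0)
  expect_equal(total_energy_metric(0.3 * umap), 0.09 * total_energy_metric(umap),
               tolerance = 1e-12)
  n_myo <- sum(mask == 1L)
  if (n_myo > 0)
    expect_equal(total_energy_metric(umap), compute_upp(umap, mask) * n_myo,
                 tolerance = 1e-12)
})

test_that("minimum-uncertainty selection prefers self-consistent mock models", {
  pp <- clean_phantom_pp(seed = 6)
  g <- desk_grid()
  # consistent model: content-deterministic, Upp = 0
  consistent <- mock_truth_model()
  # inconsistent model: flips myocardium probability patch to patch
  flip <- local({
    state <- new.env(); state$i <- 0
    function(patch) {
      state$i <- state$i + 1
      P <- nrow(patch)
      a <- array(0, c(P, P, 3))
      a[, , 2] <- state$i %% 2
      a[, , 1] <- 1 - a[, , 2]
      a
    }
  })
  members <- list(
    list(params = flip, run_index = 1L, run_seed = 1L, checkpoint_epoch = 1L,
         validation_dice = 0.99, member_id = "flip"),
    list(params = consistent, run_index = 2L, run_seed = 2L,
         checkpoint_epoch = 1L, validation_dice = 0.9, member_id = "consistent"))
  # params being a function routes through the mock path
  pool <- perfuseg:::new_model_pool(members, micro_config())
  enc <- label_encoded_series(pp$mask)
  sol <- select_min_uncertainty(pool, enc, g)
  expect_identical(sol$member_id, "consistent")
  expect_identical(sol$upp, 0)
  expect_identical(nrow(sol$log), 2L)
  expect_gt(sol$log$upp[sol$log$member_id == "flip"], 0)
  # singleton pool returns its only member regardless of Upp
  allmyo <- list(params = mock_constant_model(0, 1, 0), run_index = 1L,
                 run_seed = 1L, checkpoint_epoch = 1L, validation_dice = 0.9,
                 member_id = "allmyo")
  solo <- perfuseg:::new_model_pool(list(allmyo), micro_config())
  expect_identical(select_min_uncertainty(solo, enc, g)$member_id, "allmyo")
  # all-empty pools are a diagnostic error naming the series
  empty_member <- list(params = mock_constant_model(1, 0, 0), run_index = 1L,
                       run_seed = 1L, checkpoint_epoch = 1L,
                       validation_dice = 0.9, member_id = "empty")
  pe <- pool; pe$members <- list(empty_member); pe$manifest <- pool$manifest[1, ]
  expect_error(select_min_uncertainty(pe, enc, g), "all-empty.*label-encoded")
})

test_that("U-map values never leave [0, 0.5] on random and adversarial stacks", {
  set.seed(72)
  for (i in 1:200) {
    n <- sample(2:25, 1)
    st <- make_stack(list(runif(n)))
    u <- compute_umap(st)[1, 1]
    expect_gte(u, 0); expect_lte(u, 0.5)
  }
  # adversarial all-0/all-1 mixtures
  for (n0 in 1:5) for (n1 in 1:5) {
    u <- compute_umap(make_stack(list(c(rep(0, n0), rep(1, n1)))))[1, 1]
    expect_lte(u, 0.5)
  }
})

test_that("motion-error sweep reports a deterministic tidy table", {
  pool <- desk_run()$pool
  member <- select_best_validation(pool)
  samp <- phantom_sampler("internal")
  ds <- preprocess_dataset(make_dataset(6, samp, 555), desk_spec())
  sw1 <- motion_error_sweep(member, ds, levels = c(0, 6), grid = desk_grid(),
                            seed = 2)
  sw2 <- motion_error_sweep(member, ds, levels = c(0, 6), grid = desk_grid(),
                            seed = 2)
  expect_identical(sw1$per_series, sw2$per_series)
  expect_identical(nrow(sw1$summary), 2L)
  expect_identical(sw1$summary$level, c(0, 6))
  expect_error(motion_error_sweep(member, ds, levels = 3, grid = desk_grid()),
               "parameter")
})
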