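test_that("established selection picks the best validation Dice with tie-breaks", {
  fake_member <- function(id, run, epoch, dice)
    list(params = list(), run_index = run, run_seed = run, checkpoint_epoch = epoch,
         validation_dice = dice, member_id = id)
  pool <- perfuseg:::new_model_pool(list(
    fake_member("a", 1, 5, 0.88), fake_member("b", 1, 9, 0.91),
    fake_member("c", 2, 3, 0.90)), micro_config())
  expect_identical(select_best_validation(pool)$member_id, "b")
  # all equal: first by (run_index, checkpoint_epoch)
  pool_eq <- perfuseg:::new_model_pool(list(
    fake_member("late", 2, 9, 0.9), fake_member("early", 1, 2, 0.9),
    fake_member("mid", 1, 7, 0.9)), micro_config())
  expect_identical(select_best_validation(pool_eq)$member_id, "early")
  # random dice vectors match the brute-force max scan
  set.seed(60)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    members <- lapply(seq_len(n), function(j)
      fake_member(paste0("m", j), sample(1:3, 1), sample(1:20, 1),
                  sample(round(runif(4, 0.87, 0.99), 2), 1)))
    pool_r <- perfuseg:::new_model_pool(members, micro_config())
    expect_identical(select_best_validation(pool_r)$member_id,
                     pool_r$manifest$member_id[oracle_best_validation(pool_r$manifest)])
  }
  expect_error(select_best_validation(perfuseg:::new_model_pool(list(), micro_config())),
               "empty")
})

test_that("mock models drive the segmentation path to known outputs", {
  pp <- clean_phantom_pp(seed = 5)
  g <- desk_grid()
  # constant background model: all-background mask, zero stack dispersion
  seg_bg <- segment_series(mock_constant_model(1, 0, 0), pp$series, g)
  expect_true(all(seg_bg$mask == 0L))
  expect_identical(max(compute_umap(seg_bg$stack)), 0)
  # ground-truth one-hot mock reproduces the truth exactly
  enc <- label_encoded_series(pp$mask)
  seg_gt <- segment_series(mock_truth_model(), enc, g)
  expect_identical(seg_gt$mask, pp$mask)
})

test_that("degenerate training configurations fail loudly", {
  expect_error(train_config(n_runs = 0), "n_runs")
  expect_error(train_config(dice_gate = 1.2), "dice_gate")
  sets <- micro_sets()
  expect_error(train_run(sets$train, sets$val, micro_config(epochs = 0)),
               "under-trained")
  # an unreachable gate reports the best Dice achieved
  expect_error(train_run(sets$train, sets$val,
                         micro_config(epochs = 1, dice_gate = 0.999)),
               "under-trained")
})

test_that("training runs are deterministic and gate their checkpoints", {
  sets <- micro_sets()
  cfg <- micro_config(epochs = 16, dice_gate = 0.05, checkpoints_per_run = 2)
  m1 <- train_run(sets$train, sets$val, cfg, run_index = 1)
  m2 <- train_run(sets$train, sets$val, cfg, run_index = 1)
  expect_identical(attr(m1, "history"), attr(m2, "history"))
  expect_identical(weights_hash(m1[[length(m1)]]), weights_hash(m2[[length(m2)]]))
  expect_lte(length(m1), 2L)
  expect_true(all(vapply(m1, `[[`, numeric(1), "validation_dice") >= 0.05))
})

test_that("the desk-profile pool trains to the reference gate with full metadata", {
  pool <- desk_run()$pool
  cfg <- pool$config
  # 2 runs x 3 checkpoints, all gated at >= 0.87 validation Dice
  expect_identical(length(pool), cfg$n_runs * cfg$checkpoints_per_run)
  expect_true(all(pool$manifest$validation_dice >= cfg$dice_gate))
  expect_identical(length(unique(pool$manifest$run_seed)), 2L)
  expect_identical(length(unique(pool$manifest$run_index)), 2L)
  # a trained member segments a clean phantom well above chance
  pp <- clean_phantom_pp(seed = 91)
  seg <- segment_series(select_best_validation(pool), pp$series, desk_grid())
  expect_gt(dice_score(seg$mask, pp$mask, 1L), 0.8)
})
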