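test_that("Dice handles the standard, empty and partial-overlap cases", {
  m <- ring_mask()
  expect_identical(dice_score(m, m, 1L), 1)
  empty <- matrix(0L, 64, 64)
  expect_identical(dice_score(empty, empty, 1L), 1)   # both empty
  expect_identical(dice_score(m, empty, 1L), 0)       # one empty
  a <- matrix(0L, 20, 20); a[1:10, 1:10] <- 1L        # |A| = 100
  b <- matrix(0L, 20, 20); b[1:10, 3:12] <- 1L        # |B| = 100, overlap 80
  expect_equal(dice_score(a, b, 1L), 0.8)
  # symmetry
  expect_identical(dice_score(a, b, 1L), dice_score(b, a, 1L))
  expect_error(dice_score(a, b, 7L), "parameter")
})

test_that("HD95 reproduces hand-computable distances and is symmetric", {
  a <- matrix(0L, 8, 8); a[1, 1] <- 1L
  b <- matrix(0L, 8, 8); b[1, 4] <- 1L
  expect_equal(hd95(a, b, 1L, c(1, 1)), 3)
  expect_equal(hd95(a, b, 1L, c(1, 2)), 6)  # anisotropic spacing
  m <- ring_mask()
  expect_identical(hd95(m, m, 1L), 0)
  expect_warning(h <- hd95(a, matrix(0L, 8, 8), 1L), "empty")
  expect_identical(h, Inf)
})

test_that("HD95 matches the all-pairs brute-force oracle on random masks", {
  set.seed(80)
  for (i in 1:15) {
    a <- random_blob_mask(); b <- random_blob_mask()
    for (cls in 1:2) {
      if (sum(a == cls) == 0 || sum(b == cls) == 0) next
      sp <- c(runif(1, 0.5, 2), runif(1, 0.5, 2))
      expect_equal(hd95(a, b, cls, sp), oracle_hd95(a, b, cls, sp),
                   tolerance = 1e-9)
      expect_equal(hd95(a, b, cls, sp), hd95(b, a, cls, sp), tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant to a common interior translation", {
  a <- ring_mask(48, 8, 13)
  b <- ring_mask(48, 9, 14)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  expect_equal(dice_score(shift(a, 3, 2), shift(b, 3, 2), 1L),
               dice_score(a, b, 1L), tolerance = 1e-12)
  expect_equal(hd95(shift(a, 3, 2), shift(b, 3, 2), 1L),
               hd95(a, b, 1L), tolerance = 1e-12)
})

test_that("failure criteria flag gaps and enclosed bloodpool pockets", {
  ring <- ring_mask()
  fl <- detect_failure(ring)
  expect_false(fl$failure_bloodpool)
  expect_false(fl$failure_noncontiguous)
  # ring with an angular gap: noncontiguous but no bloodpool inclusion
  gap <- ring_mask(gap = 15 * pi / 180)
  fl_gap <- detect_failure(gap)
  expect_false(fl_gap$failure_bloodpool)
  expect_true(fl_gap$failure_noncontiguous)
  # interior pocket relabelled bloodpool inside the myocardial band
  pocket <- ring_mask(64, 9, 17)
  pocket[33:34, 45:46] <- 2L  # inside the band at radius ~13
  fl_pocket <- detect_failure(pocket)
  expect_true(fl_pocket$failure_bloodpool)
  expect_false(fl_pocket$failure_noncontiguous)
  # empty prediction: both flags with a note
  fl_empty <- detect_failure(matrix(0L, 32, 32))
  expect_true(fl_empty$failure_bloodpool && fl_empty$failure_noncontiguous)
  expect_match(attr(fl_empty, "note"), "empty")
  # tiny speckles below the component threshold are ignored
  speck <- ring_mask()
  speck[2, 2] <- 1L
  expect_false(detect_failure(speck)$failure_noncontiguous)
})

test_that("ground-truth phantom masks never trigger the failure criteria", {
  samp <- phantom_sampler("internal")
  for (seed in c(3, 14, 27, 31)) {
    ph <- make_phantom(samp(seed))
    pp <- preprocess_series(ph$series, ph$mask, desk_spec())
    fl <- detect_failure(pp$mask)
    expect_false(fl$failure_bloodpool)
    expect_false(fl$failure_noncontiguous)
  }
})

test_that("a degenerate pool of identical members makes both methods agree", {
  pp <- clean_phantom_pp(seed = 44)
  g <- desk_grid()
  member <- function(id) list(params = mock_truth_model(), run_index = 1L,
                              run_seed = 1L, checkpoint_epoch = 1L,
                              validation_dice = 0.95, member_id = id)
  pool <- perfuseg:::new_model_pool(list(member("a"), member("b")),
                                    micro_config())
  enc <- label_encoded_series(pp$mask)
  sets <- list(test = list(list(series = enc, mask = pp$mask)))
  cmp <- compare_methods(pool, sets, g)
  wide <- split(cmp$per_series, cmp$per_series$method)
  expect_equal(wide$adaptive$dice_myo, wide$established$dice_myo)
  expect_equal(wide$adaptive$hd95_mm, wide$established$hd95_mm)
  expect_identical(cmp$summary$failure_rate, c(0, 0))
})
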