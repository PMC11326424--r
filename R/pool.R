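#' Training configuration for the model pool
#'
#' One configuration is shared by every member of the pool: the networks
#' differ only in their weight initialization (run seed) and in the epoch
#' their checkpoint was taken. Checkpoints enter the pool only if their
#' full-image validation Dice (myocardium class, through the inference
#' path) reaches `dice_gate`.
#'
#' @param n_runs number of independent training runs (different weight
#'   initializations).
#' @param checkpoints_per_run gated checkpoints kept per run.
#' @param dice_gate validation Dice threshold in (0, 1) a checkpoint must
#'   reach to enter the pool.
#' @param epochs training epochs per run.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size (patches).
#' @param width base channel count of the U-Net.
#' @param patch_size square space-time patch side in pixels.
#' @param train_stride sliding-window stride during training (default half
#'   the patch size).
#' @param infer_stride sliding-window stride during inference (default a
#'   quarter of the patch size, giving the dense overlap the uncertainty
#'   map relies on).
#' @param augment an [augment_policy()] applied on the fly each epoch, so
#'   different runs see different augmentation streams.
#' @param base_seed integer seed from which per-run seeds are derived.
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_runs = 5, checkpoints_per_run = 10, dice_gate = 0.87,
                         epochs = 40, learning_rate = 2e-3, batch_size = 8,
                         width = 8, patch_size = 64,
                         train_stride = patch_size %/% 2,
                         infer_stride = patch_size %/% 4,
                         augment = augment_policy(), base_seed = 1L) {
  if (n_runs < 1 || checkpoints_per_run < 1)
    stop("`n_runs` and `checkpoints_per_run` must be >= 1")
  if (dice_gate <= 0 || dice_gate >= 1) stop("`dice_gate` must be in (0, 1)")
  structure(list(n_runs = as.integer(n_runs),
                 checkpoints_per_run = as.integer(checkpoints_per_run),
                 dice_gate = dice_gate, epochs = as.integer(epochs),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 width = as.integer(width), patch_size = as.integer(patch_size),
                 train_stride = as.integer(train_stride),
                 infer_stride = as.integer(infer_stride),
                 augment = augment, base_seed = as.integer(base_seed)),
            class = "train_config")
}

#' Segment a series with one model
#'
#' The inference path: decompose the series into overlapping space-time
#' patches, run the model on each patch, average the per-patch softmax maps
#' into full-frame class probabilities, keep the raw per-patch myocardium
#' probabilities for uncertainty mapping, and take the per-pixel argmax.
#'
#' @param model anything [unet_predict()] accepts (pool member, model,
#'   parameter list, or mock function).
#' @param series a preprocessed `perfusion_series`.
#' @param grid the inference [build_grid()].
#' @return `list(probs, stack, mask)`.
#' @export
segment_series <- function(model, series, grid) {
  f <- forward_fun(model)
  patches <- decompose_series(series, grid)
  maps <- lapply(patches, f)
  rec <- recombine_patches(maps, grid)
  list(probs = rec$probs, stack = rec$stack, mask = prob_to_mask(rec$probs))
}

# Mean myocardium Dice of a parameter set over a validation set, computed
# through the full inference path.
validation_dice <- function(params, val_set, grid) {
  scores <- vapply(val_set, function(el) {
    seg <- segment_series(params, el$series, grid)
    dice_score(seg$mask, el$mask, class_code = 1L)
  }, numeric(1))
  mean(scores)
}

#' Run one seeded training run and return its gated checkpoints
#'
#' Trains the patch-level U-Net with on-the-fly augmentation and
#' half-patch-stride patch sampling, evaluating the full-image validation
#' Dice at the end of every epoch. Epochs reaching the Dice gate are
#' snapshotted; up to `checkpoints_per_run` snapshots, evenly spaced over
#' the qualifying epochs (earliest and latest included), become pool
#' members.
#'
#' @param train_set,val_set disjoint lists of `list(series, mask)` entries
#'   (preprocessed).
#' @param config a [train_config()].
#' @param run_index 1-based index of the run; determines the run seed.
#' @return A list of pool members, each
#'   `list(params, run_index, run_seed, checkpoint_epoch, validation_dice,
#'   member_id)`, with the per-epoch history attached as attribute
#'   `"history"` (a tibble with epoch, mean loss and validation Dice).
#' @export
train_run <- function(train_set, val_set, config, run_index = 1L) {
  stopifnot(inherits(config, "train_config"))
  if (config$epochs < 1)
    stop("under-trained error: `epochs` must be >= 1 to produce a gated checkpoint")
  run_seed <- config$base_seed + 7919L * as.integer(run_index)
  T <- dim(train_set[[1]]$series$intensities)[3]
  model <- build_unet(T, n_classes = 3, width = config$width, seed = run_seed)
  params <- model$params
  state <- adam_init(params)
  shape <- dim(train_set[[1]]$series$intensities)[1:2]
  grid_train <- build_grid(shape, config$patch_size, config$train_stride)
  grid_infer <- build_grid(shape, config$patch_size, config$infer_stride)
  P <- config$patch_size

  snapshots <- list()
  history <- vector("list", config$epochs)
  with_seed(run_seed, {
    for (epoch in seq_len(config$epochs)) {
      xs <- list(); ys <- list()
      for (el in train_set) {
        aug <- augment_variant(el$series, el$mask, config$augment)
        aug_series <- augment_invariant(aug$series, config$augment)
        for (k in seq_len(nrow(grid_train$origins))) {
          r <- grid_train$origins[k, 1]; c <- grid_train$origins[k, 2]
          xs[[length(xs) + 1L]] <-
            aug_series$intensities[r:(r + P - 1), c:(c + P - 1), , drop = FALSE]
          ys[[length(ys) + 1L]] <-
            as.integer(aug$mask[r:(r + P - 1), c:(c + P - 1)])
        }
      }
      ord <- sample.int(length(xs))
      losses <- c()
      for (b in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[b:min(b + config$batch_size - 1, length(ord))]
        g <- cpp_unet_batch_grad(params, xs[idx], ys[idx])
        upd <- adam_step(params, g$grads, state, lr = config$learning_rate)
        params <- upd$params; state <- upd$state
        losses <- c(losses, g$loss)
      }
      vd <- validation_dice(params, val_set, grid_infer)
      history[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean(losses),
                                         val_dice = vd)
      if (vd >= config$dice_gate)
        snapshots[[length(snapshots) + 1L]] <-
          list(params = params, epoch = epoch, dice = vd)
    }
  })
  history <- dplyr::bind_rows(history)
  nq <- length(snapshots)
  if (nq == 0)
    stop(sprintf(paste0(
      "under-trained error: no epoch of run %d reached validation Dice >= %.2f ",
      "(best %.3f); train longer or lower the gate for this task"),
      run_index, config$dice_gate, max(history$val_dice)))
  keep <- unique(round(seq(1, nq, length.out = min(nq, config$checkpoints_per_run))))
  members <- lapply(keep, function(i) {
    s <- snapshots[[i]]
    list(params = s$params, run_index = as.integer(run_index),
         run_seed = run_seed, checkpoint_epoch = s$epoch,
         validation_dice = s$dice,
         member_id = sprintf("r%02d_e%03d", run_index, s$epoch))
  })
  attr(members, "history") <- history
  members
}

#' Train the full model pool
#'
#' Runs [train_run()] `n_runs` times with different weight initializations
#' and concatenates the gated checkpoints into a pool. With the reference
#' configuration (5 runs x 10 checkpoints) this yields 50 members.
#'
#' @inheritParams train_run
#' @return An object of class `model_pool`: fields `members`, `config`,
#'   `manifest` (tibble: member, member_id, run_index, run_seed,
#'   checkpoint_epoch, validation_dice) and `histories`.
#' @export
build_pool <- function(train_set, val_set, config) {
  runs <- lapply(seq_len(config$n_runs), function(r)
    train_run(train_set, val_set, config, run_index = r))
  members <- do.call(c, lapply(runs, function(m) { attributes(m) <- NULL; m }))
  histories <- lapply(runs, attr, "history")
  new_model_pool(members, config, histories)
}

new_model_pool <- function(members, config, histories = list()) {
  manifest <- tibble::tibble(
    member = seq_along(members),
    member_id = vapply(members, `[[`, character(1), "member_id"),
    run_index = vapply(members, function(m) as.integer(m$run_index), integer(1)),
    run_seed = vapply(members, function(m) as.integer(m$run_seed), integer(1)),
    checkpoint_epoch = vapply(members, function(m) as.integer(m$checkpoint_epoch), integer(1)),
    validation_dice = vapply(members, `[[`, numeric(1), "validation_dice"))
  structure(list(members = members, config = config, manifest = manifest,
                 histories = histories),
            class = "model_pool")
}

#' @export
print.model_pool <- function(x, ...) {
  cat(sprintf("<model_pool> %d members from %d runs; validation Dice %.3f-%.3f\n",
              nrow(x$manifest), length(unique(x$manifest$run_index)),
              min(x$manifest$validation_dice), max(x$manifest$validation_dice)))
  invisible(x)
}

#' @export
length.model_pool <- function(x) length(x$members)

#' Established model selection: best validation Dice
#'
#' Returns the pool member with the highest validation Dice; ties are
#' broken by ascending `(run_index, checkpoint_epoch)`. This single member
#' is then used for every test case, in contrast to the per-case
#' uncertainty-guided selection of [select_min_uncertainty()].
#'
#' @param pool a `model_pool`.
#' @return The selected pool member.
#' @export
select_best_validation <- function(pool) {
  stopifnot(inherits(pool, "model_pool"))
  if (length(pool$members) == 0) stop("contract error: empty pool")
  m <- pool$manifest
  ord <- order(-m$validation_dice, m$run_index, m$checkpoint_epoch)
  pool$members[[m$member[ord[1]]]]
}
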