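# Heavy shared artifacts, built once per test run and memoized.

.cache <- new.env(parent = emptyenv())

# Full desk-profile end-to-end run (internal-style training, internal +
# shifted test sets, 2 runs x 3 checkpoints pool).
desk_run <- function() {
  if (is.null(.cache$run))
    .cache$run <- run_end_to_end(desk_preset(seed = 1))
  .cache$run
}

desk_grid <- function() build_grid(c(64, 64), patch_size = 32, stride = 8)

# A micro profile for fast training-loop tests: 32 px grid, 8 frames,
# 16 px patches, width-4 network.
micro_sets <- function(seed = 9) {
  samp <- phantom_sampler("internal", image_size = 48, n_frames = 8)
  spec <- preprocess_spec(target_matrix = 32, target_frames = 8,
                          upsample_factor = 1)
  list(train = preprocess_dataset(make_dataset(3, samp, seed), spec),
       val = preprocess_dataset(make_dataset(2, samp, seed + 1), spec))
}

micro_config <- function(epochs = 16, dice_gate = 0.3, n_runs = 1,
                         checkpoints_per_run = 2, base_seed = 4) {
  train_config(n_runs = n_runs, checkpoints_per_run = checkpoints_per_run,
               dice_gate = dice_gate, epochs = epochs, learning_rate = 5e-3,
               batch_size = 8, width = 4, patch_size = 16,
               base_seed = base_seed)
}
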