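# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the implementation they check.

# Population standard deviation of the covering-patch probabilities of
# every pixel, one pixel at a time.
oracle_umap <- function(patch_probs, grid) {
  H <- grid$image_shape[1]; W <- grid$image_shape[2]
  P <- grid$patch_size
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      vals <- c()
      for (k in seq_len(nrow(grid$origins))) {
        orow <- grid$origins[k, 1]; ocol <- grid$origins[k, 2]
        if (r >= orow && r < orow + P && c >= ocol && c < ocol + P)
          vals <- c(vals, patch_probs[[k]][r - orow + 1, c - ocol + 1, 2])
      }
      mu <- mean(vals)
      out[r, c] <- sqrt(mean((vals - mu)^2))
    }
  }
  out
}

# Per-pixel argmax with ties toward the lower class code.
oracle_to_mask <- function(probs) {
  H <- dim(probs)[1]; W <- dim(probs)[2]
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      best <- 0L
      for (cls in 1:2)
        if (probs[r, c, cls + 1] > probs[r, c, best + 1]) best <- cls
      out[r, c] <- best
    }
  }
  out
}

# Max-scan over validation Dice with (run_index, checkpoint_epoch)
# tie-break.
oracle_best_validation <- function(manifest) {
  best <- 1L
  for (i in seq_len(nrow(manifest))) {
    better <- manifest$validation_dice[i] > manifest$validation_dice[best]
    tie <- manifest$validation_dice[i] == manifest$validation_dice[best] &&
      (manifest$run_index[i] < manifest$run_index[best] ||
         (manifest$run_index[i] == manifest$run_index[best] &&
            manifest$checkpoint_epoch[i] < manifest$checkpoint_epoch[best]))
    if (better || tie) best <- i
  }
  best
}

# All-pairs boundary-distance HD95 (undirected = max of directed 95th
# percentiles), with explicit neighbor-loop boundary extraction.
oracle_hd95 <- function(pred, truth, class_code, spacing = c(1, 1)) {
  boundary <- function(mask) {
    H <- nrow(mask); W <- ncol(mask)
    pts <- NULL
    for (r in seq_len(H)) {
      for (c in seq_len(W)) {
        if (mask[r, c] != class_code) next
        edge <- r == 1 || r == H || c == 1 || c == W
        if (!edge)
          edge <- mask[r - 1, c] != class_code || mask[r + 1, c] != class_code ||
            mask[r, c - 1] != class_code || mask[r, c + 1] != class_code
        if (edge) pts <- rbind(pts, c(r, c))
      }
    }
    pts
  }
  a <- boundary(pred); b <- boundary(truth)
  if (is.null(a) || is.null(b)) return(Inf)
  directed <- function(from, to) {
    mins <- numeric(nrow(from))
    for (i in seq_len(nrow(from))) {
      dd <- Inf
      for (j in seq_len(nrow(to))) {
        d <- sqrt(((from[i, 1] - to[j, 1]) * spacing[1])^2 +
                    ((from[i, 2] - to[j, 2]) * spacing[2])^2)
        if (d < dd) dd <- d
      }
      mins[i] <- dd
    }
    stats::quantile(mins, 0.95, names = FALSE, type = 7)
  }
  max(directed(a, b), directed(b, a))
}

# Random label masks with a few blobs, for metric oracle tests.
random_blob_mask <- function(n = 24, n_blobs = 3) {
  m <- matrix(0L, n, n)
  for (i in seq_len(n_blobs)) {
    ctr <- runif(2, 4, n - 3)
    rad <- runif(1, 2, 5)
    cls <- sample(1:2, 1)
    rr <- matrix(seq_len(n), n, n)
    cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    m[(rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2] <- cls
  }
  m
}
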