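#' Build a sliding-window patch grid
#'
#' Origins are placed at multiples of `stride` starting from pixel 1
#' (row-major order); when the grid does not end flush with the image, a
#' final origin clamped to `H - patch_size + 1` (and likewise for columns)
#' is appended so that every pixel is covered by at least one patch and all
#' patches lie fully inside the frame.
#'
#' During training a stride of half the patch size is used; at inference a
#' quarter-patch stride gives the dense overlap the uncertainty map needs.
#'
#' @param image_shape integer `(H, W)`.
#' @param patch_size square patch side in pixels; at most `min(H, W)`.
#' @param stride step between consecutive origins, at least 1.
#' @return An object of class `patch_grid` with fields `origins` (k x 2
#'   matrix of 1-based top-left corners), `patch_size`, `stride`,
#'   `image_shape`.
#' @examples
#' g <- build_grid(c(128, 128), patch_size = 64, stride = 16)
#' nrow(g$origins)  # 25
#' @export
build_grid <- function(image_shape, patch_size, stride) {
  H <- image_shape[1]; W <- image_shape[2]
  if (patch_size > min(H, W))
    stop("geometry error: patch_size exceeds the image")
  if (stride < 1) stop("`stride` must be >= 1")
  axis_origins <- function(n) {
    o <- seq(1L, n - patch_size + 1L, by = stride)
    last <- n - patch_size + 1L
    if (o[length(o)] != last) o <- c(o, last)
    o
  }
  ro <- axis_origins(H); co <- axis_origins(W)
  origins <- cbind(rep(ro, each = length(co)), rep(co, times = length(ro)))
  colnames(origins) <- c("row", "col")
  structure(list(patch_size = as.integer(patch_size), stride = as.integer(stride),
                 origins = origins, image_shape = c(H, W)),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d patches of %d px (stride %d) on a %d x %d frame\n",
              nrow(x$origins), x$patch_size, x$stride,
              x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

# Per-pixel coverage count |Gamma(x, y)| implied by a grid.
grid_coverage <- function(grid) {
  cov <- matrix(0L, grid$image_shape[1], grid$image_shape[2])
  P <- grid$patch_size
  for (k in seq_len(nrow(grid$origins))) {
    r <- grid$origins[k, 1]; c <- grid$origins[k, 2]
    cov[r:(r + P - 1), c:(c + P - 1)] <- cov[r:(r + P - 1), c:(c + P - 1)] + 1L
  }
  cov
}

#' Decompose a series into space-time patches
#'
#' Each patch is an exact copy of a `patch_size` x `patch_size` x T window
#' of the series, in the order of `grid$origins`; the origin is attached as
#' an attribute.
#'
#' @param series a `perfusion_series` whose spatial shape matches the grid.
#' @param grid a [build_grid()] result.
#' @return A list of 3D arrays with attribute `"origin"`.
#' @export
decompose_series <- function(series, grid) {
  stopifnot(inherits(series, "perfusion_series"), inherits(grid, "patch_grid"))
  d <- dim(series$intensities)
  if (!identical(d[1:2], as.integer(grid$image_shape)))
    stop("geometry error: grid does not match the series shape")
  P <- grid$patch_size
  lapply(seq_len(nrow(grid$origins)), function(k) {
    r <- grid$origins[k, 1]; c <- grid$origins[k, 2]
    structure(series$intensities[r:(r + P - 1), c:(c + P - 1), , drop = FALSE],
              origin = grid$origins[k, ])
  })
}

#' Recombine patch-level class probabilities
#'
#' Averages the per-patch softmax maps into full-frame class probabilities
#' (arithmetic mean over the patches covering each pixel) and retains the
#' raw per-patch myocardium probabilities in a `patch_prob_stack` for
#' uncertainty mapping.
#'
#' @param patch_probs list of `P x P x 3` probability arrays (classes in
#'   label-code order: background, myocardium, bloodpool), one per grid
#'   origin, rows summing to 1.
#' @param grid the [build_grid()] the patches came from.
#' @return `list(probs, stack)`: `probs` is an `H x W x 3` array whose
#'   pixelwise values sum to 1; `stack` is a `patch_prob_stack` holding an
#'   `H x W x k` array of myocardium probabilities (`NA` where a patch does
#'   not cover a pixel) and the per-pixel `coverage` count.
#' @export
recombine_patches <- function(patch_probs, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  K <- nrow(grid$origins)
  if (length(patch_probs) != K)
    stop("contract error: need exactly one probability map per grid origin")
  H <- grid$image_shape[1]; W <- grid$image_shape[2]
  P <- grid$patch_size
  acc <- array(0, c(H, W, 3))
  cnt <- matrix(0L, H, W)
  stack <- array(NA_real_, c(H, W, K))
  for (k in seq_len(K)) {
    pp <- patch_probs[[k]]
    if (!identical(dim(pp), c(P, P, 3L)) && !identical(dim(pp), c(P, P, 3)))
      stop("contract error: each patch map must be patch_size x patch_size x 3")
    r <- grid$origins[k, 1]; c <- grid$origins[k, 2]
    ri <- r:(r + P - 1); ci <- c:(c + P - 1)
    acc[ri, ci, ] <- acc[ri, ci, , drop = FALSE] + pp
    cnt[ri, ci] <- cnt[ri, ci] + 1L
    stack[ri, ci, k] <- pp[, , 2]
  }
  probs <- acc / replicate(3, cnt)
  structure_stack <- structure(list(probs = stack, coverage = cnt),
                               class = "patch_prob_stack")
  list(probs = probs, stack = structure_stack)
}

#' Convert class probabilities to a label mask
#'
#' Per-pixel argmax over the three class probabilities; ties are broken
#' toward the lower label code (background < myocardium < bloodpool).
#'
#' @param probs an `H x W x 3` probability array.
#' @return Integer label matrix with codes `{0, 1, 2}`.
#' @export
prob_to_mask <- function(probs) {
  d <- dim(probs)
  stopifnot(length(d) == 3, d[3] == 3)
  m <- matrix(probs, d[1] * d[2], 3)
  lab <- max.col(m, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1], d[2])
}
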