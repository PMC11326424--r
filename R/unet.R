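#' Build a 2D+time U-Net for patch-level segmentation
#'
#' The network jointly processes all time frames of a space-time patch by
#' stacking them as input channels. It is a three-level encoder/decoder
#' with skip connections (two 3x3 convolutions per level, 2x2 max-pooling,
#' nearest-neighbor upsampling) ending in a 1x1 convolution and a per-pixel
#' softmax over the three classes. Its receptive field exceeds the default
#' patch size, so every pixel's prediction depends on the whole patch
#' context — the property that makes the disagreement between overlapping
#' patches an informative uncertainty signal. Weights use seeded He-normal
#' initialization; biases start at zero.
#'
#' @param in_frames number of time frames (input channels), at least 1.
#' @param n_classes number of output classes (3 for background /
#'   myocardium / bloodpool).
#' @param width base channel count of the encoder.
#' @param seed integer seed for the weight initialization.
#' @return An object of class `unet_model` with fields `params` (named list
#'   of weight matrices), `in_frames`, `n_classes`, `width`, `seed`,
#'   `n_params`.
#' @export
build_unet <- function(in_frames, n_classes = 3, width = 8, seed = 1L) {
  if (in_frames < 1) stop("architecture error: `in_frames` must be >= 1")
  if (width < 1) stop("architecture error: `width` must be >= 1")
  if (n_classes < 2) stop("architecture error: need at least 2 classes")
  he <- function(rows, cols) matrix(rnorm(rows * cols, sd = sqrt(2 / cols)), rows, cols)
  w <- width
  params <- with_seed(seed, list(
    W1 = he(w, in_frames * 9),       b1 = numeric(w),
    W2 = he(w, w * 9),               b2 = numeric(w),
    W3 = he(2 * w, w * 9),           b3 = numeric(2 * w),
    W4 = he(2 * w, 2 * w * 9),       b4 = numeric(2 * w),
    W5 = he(4 * w, 2 * w * 9),       b5 = numeric(4 * w),
    W6 = he(4 * w, 4 * w * 9),       b6 = numeric(4 * w),
    W7 = he(2 * w, 6 * w * 9),       b7 = numeric(2 * w),
    W8 = he(2 * w, 2 * w * 9),       b8 = numeric(2 * w),
    W9 = he(w, 3 * w * 9),           b9 = numeric(w),
    W10 = he(w, w * 9),              b10 = numeric(w),
    W11 = he(n_classes, w),          b11 = numeric(n_classes)))
  structure(list(params = params, in_frames = as.integer(in_frames),
                 n_classes = as.integer(n_classes), width = as.integer(width),
                 seed = as.integer(seed),
                 n_params = sum(vapply(params, length, integer(1)))),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %d input frames, width %d, %d classes, %d parameters (seed %d)\n",
              x$in_frames, x$width, x$n_classes, x$n_params, x$seed))
  invisible(x)
}

# Resolve the various model representations (unet_model, pool member, raw
# parameter list, or plain function) to a patch -> probability-map function.
forward_fun <- function(model) {
  if (is.function(model)) return(model)
  params <- if (!is.null(model$params)) model$params else model
  if (is.function(params)) return(params)
  if (is.null(params$W1)) stop("contract error: not a model, member or parameter list")
  function(patch) cpp_unet_forward(params, patch)
}

#' Forward pass of a model on one space-time patch
#'
#' @param model a `unet_model`, a pool member, a raw parameter list, or a
#'   function mapping a patch to a probability array (used for mocking).
#' @param patch numeric `P x P x T` array (P even).
#' @return `P x P x n_classes` array of softmax probabilities.
#' @export
unet_predict <- function(model, patch) forward_fun(model)(patch)

#' Stable digest of a model's weights
#' @param model a `unet_model`, pool member or parameter list.
#' @return A character hash.
#' @export
weights_hash <- function(model) {
  params <- if (!is.null(model$params)) model$params else model
  rlang::hash(lapply(params, round, digits = 12))
}

# --- Adam optimizer (per-parameter moment estimates) -----------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
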