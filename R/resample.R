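# Low-level resampling primitives shared by the phantom, preprocessing and
# augmentation modules. All coordinates are 1-based pixel centers.

# Gather img[r, c] for real-valued index vectors, returning `fill` outside
# the frame ("fill") or the nearest edge pixel ("replicate").
sample_nearest <- function(img, sr, sc, fill = 0, edge = c("fill", "replicate")) {
  edge <- match.arg(edge)
  H <- nrow(img); W <- ncol(img)
  ri <- round(sr); ci <- round(sc)
  if (edge == "replicate") {
    ri <- pmin(pmax(ri, 1), H); ci <- pmin(pmax(ci, 1), W)
    return(img[cbind(ri, ci)])
  }
  ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  out <- rep(fill, length(sr))
  if (any(ok)) out[ok] <- img[cbind(ri[ok], ci[ok])]
  out
}

sample_bilinear <- function(img, sr, sc, fill = 0, edge = c("fill", "replicate")) {
  edge <- match.arg(edge)
  H <- nrow(img); W <- ncol(img)
  if (edge == "replicate") {
    sr <- pmin(pmax(sr, 1), H)
    sc <- pmin(pmax(sc, 1), W)
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  gather <- function(ri, ci) {
    if (edge == "replicate") {
      ri <- pmin(pmax(ri, 1), H); ci <- pmin(pmax(ci, 1), W)
      return(img[cbind(ri, ci)])
    }
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- rep(fill, length(ri))
    if (any(ok)) out[ok] <- img[cbind(ri[ok], ci[ok])]
    out
  }
  v00 <- gather(r0, c0); v10 <- gather(r0 + 1, c0)
  v01 <- gather(r0, c0 + 1); v11 <- gather(r0 + 1, c0 + 1)
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Warp a 2D image through an inverse affine map: for each output pixel
# (r, c), the source location is minv %*% c(r, c, 1). `minv` is 2 x 3.
warp_affine_2d <- function(img, minv, interp = c("bilinear", "nearest"),
                           fill = 0, edge = c("fill", "replicate")) {
  interp <- match.arg(interp); edge <- match.arg(edge)
  H <- nrow(img); W <- ncol(img)
  rr <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  sr <- minv[1, 1] * rr + minv[1, 2] * cc + minv[1, 3]
  sc <- minv[2, 1] * rr + minv[2, 2] * cc + minv[2, 3]
  v <- if (interp == "bilinear") sample_bilinear(img, sr, sc, fill, edge)
       else sample_nearest(img, sr, sc, fill, edge)
  matrix(v, H, W)
}

# Translate a 2D frame by (dy, dx) pixels (content moves down/right for
# positive shifts) with bilinear interpolation and edge replication.
shift_frame <- function(img, dy, dx, edge = "replicate") {
  minv <- matrix(c(1, 0, 0, 1, -dy, -dx), 2, 3)
  warp_affine_2d(img, minv, interp = "bilinear", edge = edge)
}

# Separable cubic-spline image resize (intensities). Output pixel i maps to
# source coordinate (i - 0.5) * H/out_h + 0.5 (pixel-center alignment).
resize_cubic <- function(img, out_h, out_w) {
  H <- nrow(img); W <- ncol(img)
  src_r <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
  src_c <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
  src_r <- pmin(pmax(src_r, 1), H)
  src_c <- pmin(pmax(src_c, 1), W)
  tmp <- apply(img, 2, function(col)
    stats::spline(seq_len(H), col, xout = src_r, method = "fmm")$y)
  tmp <- matrix(tmp, out_h, W)
  out <- t(apply(tmp, 1, function(row)
    stats::spline(seq_len(W), row, xout = src_c, method = "fmm")$y))
  matrix(out, out_h, out_w)
}

resize_nearest <- function(img, out_h, out_w) {
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(pmax(round((seq_len(out_h) - 0.5) * H / out_h + 0.5), 1), H)
  ci <- pmin(pmax(round((seq_len(out_w) - 0.5) * W / out_w + 0.5), 1), W)
  img[ri, ci, drop = FALSE]
}

# Vectorized shape-preserving piecewise-cubic (PCHIP, Fritsch-Carlson)
# interpolation of many signals sharing one time grid. `y` is an
# n_signals x T matrix sampled at `x`; returns n_signals x length(xi).
pchip_resample <- function(y, x, xi) {
  y <- as.matrix(y)
  T <- length(x)
  if (ncol(y) != T) stop("ncol(y) must equal length(x)")
  if (T < 2) stop("need at least two time points")
  xi <- pmin(pmax(xi, x[1]), x[T])
  h <- diff(x)                                   # length T-1
  delta <- sweep(y[, -1, drop = FALSE] - y[, -T, drop = FALSE], 2, h, "/")
  d <- matrix(0, nrow(y), T)
  if (T == 2) {
    d[, 1] <- delta[, 1]; d[, 2] <- delta[, 1]
  } else {
    for (k in 2:(T - 1)) {
      d1 <- delta[, k - 1]; d2 <- delta[, k]
      w1 <- 2 * h[k] + h[k - 1]; w2 <- h[k] + 2 * h[k - 1]
      hm <- (w1 + w2) / (w1 / d1 + w2 / d2)
      use <- (d1 * d2 > 0)
      d[, k] <- ifelse(use, hm, 0)
    }
    end_slope <- function(h1, h2, d1, d2) {
      s <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
      s <- ifelse(s * d1 <= 0, 0, s)
      ifelse(d1 * d2 < 0 & abs(s) > 3 * abs(d1), 3 * d1, s)
    }
    d[, 1] <- end_slope(h[1], h[2], delta[, 1], delta[, 2])
    d[, T] <- end_slope(h[T - 1], h[T - 2], delta[, T - 1], delta[, T - 2])
  }
  out <- matrix(0, nrow(y), length(xi))
  k <- findInterval(xi, x, rightmost.closed = TRUE)
  k[k >= T] <- T - 1L
  for (j in seq_along(xi)) {
    kk <- k[j]
    hk <- h[kk]
    tt <- (xi[j] - x[kk]) / hk
    h00 <- 2 * tt^3 - 3 * tt^2 + 1
    h10 <- tt^3 - 2 * tt^2 + tt
    h01 <- -2 * tt^3 + 3 * tt^2
    h11 <- tt^3 - tt^2
    out[, j] <- h00 * y[, kk] + hk * h10 * d[, kk] +
      h01 * y[, kk + 1] + hk * h11 * d[, kk + 1]
  }
  out
}
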