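# Image-space primitives shared by preprocessing and augmentation. Images are
# H x W matrices indexed [y + 1, x + 1] (same raster convention as polylines).

# Cubic-convolution (Catmull-Rom, a = -0.5) kernel
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# 1D resampling matrix mapping n_in samples to n_out, pixel-centre aligned:
# src = (dst + 0.5) * n_in / n_out - 0.5, edge-clamped
resample_matrix <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  base <- floor(src)
  w <- matrix(0, n_out, n_in)
  for (k in -1:2) {
    idx <- pmin(pmax(base + k, 0), n_in - 1)
    wk <- cubic_kernel(src - (base + k))
    w[cbind(seq_len(n_out), idx + 1)] <- w[cbind(seq_len(n_out), idx + 1)] + wk
  }
  sweep(w, 1, rowSums(w), "/")
}

#' Bicubic image resampling
#'
#' Separable cubic-convolution (Catmull-Rom) resampling with pixel-centre
#' alignment: native coordinate `x` maps to `(x + 0.5) * out/in - 0.5`.
#' @param img `H x W` matrix.
#' @param out_h,out_w Output size in pixels.
#' @export
resize_bicubic <- function(img, out_h, out_w) {
  wy <- resample_matrix(nrow(img), out_h)
  wx <- resample_matrix(ncol(img), out_w)
  wy %*% img %*% t(wx)
}

# Bilinear sampling of img under the inverse of the affine p' = m p + off
# (p = c(x, y), 0-based); output pixel q takes img at m^{-1} (q - off).
affine_sample <- function(img, m, off = c(0, 0), fill = 0) {
  h <- nrow(img); w <- ncol(img)
  inv <- solve(m)
  qx <- rep(0:(w - 1L), each = h)
  qy <- rep(0:(h - 1L), times = w)
  sx <- inv[1, 1] * (qx - off[1]) + inv[1, 2] * (qy - off[2])
  sy <- inv[2, 1] * (qx - off[1]) + inv[2, 2] * (qy - off[2])
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  px <- function(xi, yi) {
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- rep(fill, length(xi))
    v[ok] <- img[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    v
  }
  v <- (1 - fx) * (1 - fy) * px(x0, y0) + fx * (1 - fy) * px(x0 + 1, y0) +
    (1 - fx) * fy * px(x0, y0 + 1) + fx * fy * px(x0 + 1, y0 + 1)
  matrix(v, h, w)
}

# Separable Gaussian blur (truncated at 3 sigma, renormalised)
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  band <- function(n) {
    m <- matrix(0, n, n)
    for (d in -r:r) {
      idx <- seq_len(n)
      j <- pmin(pmax(idx + d, 1L), n)  # clamp at edges
      m[cbind(idx, j)] <- m[cbind(idx, j)] + k[d + r + 1L]
    }
    m
  }
  band(nrow(img)) %*% img %*% t(band(ncol(img)))
}

#' Robust per-slice intensity normalisation
#'
#' Linearly rescales so the 1st and 99th intensity percentiles map to 0 and
#' 1, then clamps to `[0, 1]`.
#' @param img `H x W` matrix.
#' @param lo,hi Percentile bounds.
#' @export
normalise_intensity <- function(img, lo = 0.01, hi = 0.99) {
  q <- quantile(img, c(lo, hi), names = FALSE)
  if (q[2] <= q[1]) return(img * 0)
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}
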