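# shared fixture builders; all randomness is seeded by the caller

rand_poly <- function(n, size = 32, side = "left") {
  repeat {
    x <- runif(n, 2, size - 3)
    y <- runif(n, 2, size - 3)
    ok <- n < 2 || all(diff(x) != 0 | diff(y) != 0)
    if (ok) return(polyline(x, y, side))
  }
}

# brute-force closest-point RMS (independent of the package implementation)
bf_rms <- function(pred, gt) {
  d <- vapply(seq_along(gt$x), function(i) {
    min(sqrt((pred$x - gt$x[i])^2 + (pred$y - gt$y[i])^2))
  }, numeric(1))
  sqrt(mean(d^2))
}

# brute-force AUC by pairwise concordance
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

tiny_scene <- function() scene_spec(size = 32L, n_vertices = c(3L, 6L))
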