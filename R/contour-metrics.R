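#' Closest-point RMS error between contours
#'
#' For every ground-truth vertex, the distance to the nearest predicted
#' vertex is taken, and the root of the mean of the squared distances is
#' returned. This direction (truth to prediction) matches how sparse expert
#' landmarks are compared against a dense walked contour; set
#' `symmetric = TRUE` to pool both directions.
#'
#' @param pred,gt Present, non-empty `sij_polyline`s.
#' @param spacing Optional in-plane pixel spacing (mm/px); when supplied the
#'   result is in millimetres instead of pixels.
#' @param symmetric Pool distances from both directions.
#' @return RMS error (pixels, or mm when `spacing` is given).
#' @export
closest_point_rms <- function(pred, gt, spacing = NULL, symmetric = FALSE) {
  for (p in list(pred, gt)) {
    if (!inherits(p, "sij_polyline") || !p$present || n_vertices(p) == 0L) {
      abort("both contours must be present and non-empty",
            class = "sijmri_absent_contour")
    }
  }
  d2 <- directed_min_d2(gt, pred)
  if (symmetric) d2 <- c(d2, directed_min_d2(pred, gt))
  rms <- sqrt(mean(d2))
  if (!is.null(spacing)) rms <- rms * spacing
  rms
}

directed_min_d2 <- function(from, to) {
  vapply(seq_along(from$x), function(k) {
    min((to$x - from$x[k])^2 + (to$y - from$y[k])^2)
  }, numeric(1))
}

#' Empirical error quantiles per data proportion
#'
#' For each proportion q, the empirical q-quantile of the per-contour RMS
#' errors, using linear interpolation between order statistics
#' (`stats::quantile` type 7). The result is monotone non-decreasing in the
#' proportion.
#'
#' @param errors Non-empty numeric vector of errors.
#' @param proportions Proportions in (0, 1], sorted ascending. The default is
#'   the reporting grid used for contouring accuracy tables.
#' @return A tibble with columns `proportion` and `error`.
#' @export
error_quantiles <- function(errors,
                            proportions = c(0.1, 0.3, 0.5, 0.7, 0.9, 0.95)) {
  if (length(errors) == 0L) abort("`errors` must be non-empty")
  if (any(proportions <= 0 | proportions > 1)) {
    abort("`proportions` must lie in (0, 1]")
  }
  if (is.unsorted(proportions, strictly = FALSE)) {
    abort("`proportions` must be sorted ascending")
  }
  tibble(proportion = as.numeric(proportions),
         error = unname(quantile(errors, probs = proportions, type = 7)))
}
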