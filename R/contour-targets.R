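#' Target unit vector field for an annotated contour
#'
#' Builds the per-pixel training target for one open contour. Away from the
#' contour, the field at a pixel is the unit vector pointing to the nearest
#' annotated vertex. Within `on_contour_radius` of the polyline itself the
#' vector instead runs along the contour: it takes the direction of the
#' nearest segment, pointing toward that segment's later vertex, so that a
#' walker riding the contour is carried forward; pixels near the final vertex
#' reuse the direction of the final segment. Every vector has unit norm.
#'
#' @param poly A present `sij_polyline` with at least 2 vertices.
#' @param shape Integer `c(height, width)` in pixels.
#' @param on_contour_radius Width of the tangential band around the polyline,
#'   in pixels. The default covers every rasterised contour pixel: a segment
#'   crossing the grid diagonally can pass up to about 0.71 px from the
#'   nearest pixel centre, so a band of 0.75 px guarantees the pixels
#'   adjacent to the contour carry tangential directions.
#' @param centripetal Optional lane-keeping blend in `[0, 1]`: within the
#'   tangential band, mix in a pull toward the contour centreline scaled by
#'   the relative offset (`centripetal * d / on_contour_radius`). Zero (the
#'   default) gives the pure tangential rule; training targets for the
#'   regressor use a positive value so that a walker riding a smoothed,
#'   widened band is drawn back to the centreline.
#' @return A `sij_field`: matrices `ux`, `uy` of size `height x width`,
#'   indexed `[y + 1, x + 1]`.
#' @export
build_target_uvf <- function(poly, shape, on_contour_radius = 0.75,
                             centripetal = 0) {
  if (!inherits(poly, "sij_polyline") || !poly$present || n_vertices(poly) < 2L) {
    abort("`poly` must be a present polyline with >= 2 vertices")
  }
  h <- as.integer(shape[[1]]); w <- as.integer(shape[[2]])
  if (h < 1L || w < 1L) abort("`shape` must be positive")
  vx <- poly$x; vy <- poly$y; m <- length(vx)
  seg_len2 <- diff(vx)^2 + diff(vy)^2
  if (all(seg_len2 == 0)) abort("degenerate polyline: all vertices identical")

  px <- rep(0:(w - 1L), each = h)   # column-major over the h x w grid
  py <- rep(0:(h - 1L), times = w)
  np <- h * w

  # nearest vertex per pixel (ties -> lowest index via strict improvement)
  best_d2 <- rep(Inf, np); best_k <- rep(1L, np)
  for (k in seq_len(m)) {
    d2 <- (vx[k] - px)^2 + (vy[k] - py)^2
    imp <- d2 < best_d2
    best_d2[imp] <- d2[imp]; best_k[imp] <- k
  }

  # distance to the polyline (nearest segment), that segment's direction,
  # and the foot of the perpendicular (for the centripetal blend)
  seg_d2 <- rep(Inf, np); seg_tx <- rep(NA_real_, np); seg_ty <- rep(NA_real_, np)
  foot_x <- rep(NA_real_, np); foot_y <- rep(NA_real_, np)
  for (k in seq_len(m - 1L)) {
    if (seg_len2[k] == 0) next
    dx <- vx[k + 1L] - vx[k]; dy <- vy[k + 1L] - vy[k]
    t <- pmin(1, pmax(0, ((px - vx[k]) * dx + (py - vy[k]) * dy) / seg_len2[k]))
    fx <- vx[k] + t * dx; fy <- vy[k] + t * dy
    d2 <- (fx - px)^2 + (fy - py)^2
    imp <- d2 < seg_d2
    len <- sqrt(seg_len2[k])
    seg_d2[imp] <- d2[imp]; seg_tx[imp] <- dx / len; seg_ty[imp] <- dy / len
    foot_x[imp] <- fx[imp]; foot_y[imp] <- fy[imp]
  }

  ux <- vx[best_k] - px
  uy <- vy[best_k] - py
  nrm <- sqrt(ux^2 + uy^2)
  zero <- nrm == 0
  nrm[zero] <- 1  # overwritten by the tangential rule below
  ux <- ux / nrm; uy <- uy / nrm

  on <- seg_d2 <= on_contour_radius^2 | zero
  if (centripetal > 0) {
    d <- sqrt(seg_d2[on])
    cx <- foot_x[on] - px[on]; cy <- foot_y[on] - py[on]
    cn <- sqrt(cx^2 + cy^2)
    pos <- cn > 1e-9
    cx <- ifelse(pos, cx / pmax(cn, 1e-9), 0)
    cy <- ifelse(pos, cy / pmax(cn, 1e-9), 0)
    wgt <- centripetal * d / on_contour_radius
    bx <- seg_tx[on] + wgt * cx; by <- seg_ty[on] + wgt * cy
    bn <- pmax(sqrt(bx^2 + by^2), 1e-9)
    ux[on] <- bx / bn; uy[on] <- by / bn
  } else {
    ux[on] <- seg_tx[on]; uy[on] <- seg_ty[on]
  }

  # pixel vectors run y-fastest (px has each = h), i.e. column-major for an
  # h x w matrix, so matrix() places pixel (x, y) at [y + 1, x + 1]
  structure(list(ux = matrix(ux, h, w), uy = matrix(uy, h, w)),
            class = "sij_field")
}

#' Construct a vector field from component matrices
#' @param ux,uy Equal-sized matrices of x/y components, indexed `[y+1, x+1]`.
#' @keywords internal
#' @export
vector_field <- function(ux, uy) {
  if (!all(dim(ux) == dim(uy))) abort("`ux` and `uy` must share dimensions")
  structure(list(ux = ux, uy = uy), class = "sij_field")
}

#' Normalise a field to unit vectors
#'
#' Raw network regressions of the two field components need not be unit
#' length; they are renormalised before walking.
#' @param field A `sij_field`.
#' @param eps Norm floor below which the direction is left as-is (zeroed).
#' @export
normalise_field <- function(field, eps = 1e-8) {
  nrm <- sqrt(field$ux^2 + field$uy^2)
  scale <- ifelse(nrm < eps, 0, 1 / pmax(nrm, eps))
  vector_field(field$ux * scale, field$uy * scale)
}

#' Gaussian source and sink endpoint heatmaps
#'
#' The source heatmap peaks at the first vertex of the contour and the sink
#' at the last; each is an isotropic Gaussian of the distance to its peak,
#' `exp(-d^2 / (2 sigma^2))`, with maximum value 1 at the peak.
#'
#' @inheritParams build_target_uvf
#' @param sigma Gaussian standard deviation in pixels; see [heatmap_sigma()]
#'   for the default scaling used by the pipeline.
#' @return A list with `source` and `sink`, each a `sij_heatmap` matrix with
#'   attributes `peak` (`c(x, y)`) and `sigma`.
#' @export
build_endpoint_heatmaps <- function(poly, shape, sigma) {
  if (!inherits(poly, "sij_polyline") || !poly$present || n_vertices(poly) < 1L) {
    abort("`poly` must be a present polyline")
  }
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be > 0")
  m <- n_vertices(poly)
  list(source = gaussian_heatmap(c(poly$x[1], poly$y[1]), shape, sigma),
       sink   = gaussian_heatmap(c(poly$x[m], poly$y[m]), shape, sigma))
}

#' @rdname build_endpoint_heatmaps
#' @param peak `c(x, y)` peak location in pixels.
#' @export
gaussian_heatmap <- function(peak, shape, sigma) {
  h <- as.integer(shape[[1]]); w <- as.integer(shape[[2]])
  dx2 <- (0:(w - 1L) - peak[[1]])^2
  dy2 <- (0:(h - 1L) - peak[[2]])^2
  v <- exp(-(outer(dy2, dx2, "+")) / (2 * sigma^2))
  structure(v, class = "sij_heatmap", peak = as.numeric(peak), sigma = sigma)
}

zero_heatmap <- function(shape) {
  structure(matrix(0, shape[[1]], shape[[2]]), class = "sij_heatmap",
            peak = c(NA_real_, NA_real_), sigma = NA_real_)
}

#' Heatmap scale from the task-relevant region
#'
#' The endpoint Gaussians are scaled to the anatomy: when both joints are
#' present the variance is tied to the area of the inter-contour ("sacrum")
#' region, `sigma = frac * sqrt(area)`; for a lone contour with no enclosed
#' region it is tied to the contour length, `sigma = frac * length`. The
#' proportionality constant defaults to 0.05 and is configurable.
#'
#' @param left,right `sij_polyline`s (either may be absent).
#' @param frac Proportionality constant.
#' @param min_sigma Lower bound in pixels, guarding tiny contours.
#' @export
heatmap_sigma <- function(left, right, frac = 0.05, min_sigma = 1) {
  lp <- !is.null(left) && left$present && n_vertices(left) >= 2L
  rp <- !is.null(right) && right$present && n_vertices(right) >= 2L
  if (!lp && !rp) abort("at least one present contour is required")
  if (lp && rp) {
    # polygon between the two contours: left vertices then reversed right
    x <- c(left$x, rev(right$x)); y <- c(left$y, rev(right$y))
    n <- length(x); j <- c(2:n, 1L)
    area <- abs(sum(x * y[j] - x[j] * y)) / 2
    s <- frac * sqrt(area)
  } else {
    p <- if (lp) left else right
    s <- frac * sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
  }
  max(s, min_sigma)
}

contour_length <- function(poly) sum(sqrt(diff(poly$x)^2 + diff(poly$y)^2))

#' Full 8-plane training target for a slice
#'
#' Combines, for each of the two joints, the two unit-vector-field component
#' planes and the source/sink heatmaps: 8 scalar planes in total. An absent
#' side contributes all-zero planes, which trains the network to suppress
#' false positives on slices where a joint is outside the field of view.
#'
#' @param left,right `sij_polyline`s (may be absent).
#' @param shape `c(height, width)`.
#' @param sigma Heatmap scale; default derived via [heatmap_sigma()].
#' @param on_contour_radius,centripetal Passed to [build_target_uvf()].
#' @return A `sij_targets` object.
#' @export
contour_targets <- function(left, right, shape, sigma = NULL,
                            on_contour_radius = 0.75, centripetal = 0) {
  lp <- left$present && n_vertices(left) >= 2L
  rp <- right$present && n_vertices(right) >= 2L
  if (is.null(sigma)) {
    sigma <- if (lp || rp) heatmap_sigma(left, right) else NA_real_
  }
  side_targets <- function(poly, ok) {
    if (!ok) {
      return(list(field = vector_field(matrix(0, shape[[1]], shape[[2]]),
                                       matrix(0, shape[[1]], shape[[2]])),
                  source = zero_heatmap(shape), sink = zero_heatmap(shape),
                  present = FALSE))
    }
    hm <- build_endpoint_heatmaps(poly, shape, sigma)
    list(field = build_target_uvf(poly, shape, on_contour_radius, centripetal),
         source = hm$source, sink = hm$sink, present = TRUE)
  }
  structure(list(left = side_targets(left, lp), right = side_targets(right, rp),
                 shape = as.integer(shape), sigma = sigma),
            class = "sij_targets")
}

#' Convert targets to/from an 8-plane array
#'
#' Plane order: left ux, left uy, left source, left sink, then the same four
#' for the right side. This is the output layout of the delineation network.
#' @param targets A `sij_targets`.
#' @export
targets_to_planes <- function(targets) {
  s <- targets$shape
  a <- array(0, c(s[[1]], s[[2]], 8L))
  a[, , 1] <- targets$left$field$ux;  a[, , 2] <- targets$left$field$uy
  a[, , 3] <- targets$left$source;    a[, , 4] <- targets$left$sink
  a[, , 5] <- targets$right$field$ux; a[, , 6] <- targets$right$field$uy
  a[, , 7] <- targets$right$source;   a[, , 8] <- targets$right$sink
  a
}

#' @rdname targets_to_planes
#' @param planes `height x width x 8` array of network outputs.
#' @param sigma Heatmap scale recorded on the result (used for the walker's
#'   default stop radius).
#' @export
planes_to_targets <- function(planes, sigma = NA_real_) {
  hm <- function(v) structure(v, class = "sij_heatmap",
                              peak = c(NA_real_, NA_real_), sigma = sigma)
  side <- function(i0) list(
    field = vector_field(planes[, , i0], planes[, , i0 + 1L]),
    source = hm(planes[, , i0 + 2L]), sink = hm(planes[, , i0 + 3L]),
    present = NA)
  structure(list(left = side(1L), right = side(5L),
                 shape = dim(planes)[1:2], sigma = sigma),
            class = "sij_targets")
}
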