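#' Open-contour polylines
#'
#' A polyline is an ordered sequence of vertices delineating one sacroiliac
#' joint on a single coronal slice. Coordinates are 0-based pixels with
#' `x` the column, `y` the row, y increasing downward, and pixel centres at
#' integer coordinates; this convention is used throughout the package.
#' Expert annotations carry between 2 and 21 vertices per contour; walked
#' contours may carry more.
#'
#' @param x,y Numeric vectors of equal length: vertex coordinates in pixels.
#' @param side `"left"` or `"right"`.
#' @param present Logical; `FALSE` marks a joint outside the field of view.
#'   An absent polyline carries no vertices.
#' @return An object of class `sij_polyline`.
#' @examples
#' poly <- polyline(c(5, 5), c(3, 7), side = "left")
#' n_vertices(poly)
#' @export
polyline <- function(x = numeric(), y = numeric(),
                     side = c("left", "right"), present = TRUE) {
  side <- match.arg(side)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  x <- as.numeric(x); y <- as.numeric(y)
  if (present) {
    if (!all(is.finite(x)) || !all(is.finite(y))) {
      abort("polyline vertices must be finite")
    }
    if (length(x) >= 2L) {
      same <- x[-1] == x[-length(x)] & y[-1] == y[-length(y)]
      if (any(same)) abort("consecutive polyline vertices must be distinct")
    }
  } else {
    x <- numeric(); y <- numeric()
  }
  structure(list(x = x, y = y, side = side, present = present),
            class = "sij_polyline")
}

#' @rdname polyline
#' @export
absent_polyline <- function(side = c("left", "right")) {
  polyline(side = match.arg(side), present = FALSE)
}

#' @rdname polyline
#' @param poly A `sij_polyline`.
#' @export
n_vertices <- function(poly) length(poly$x)

#' @export
print.sij_polyline <- function(x, ...) {
  if (!x$present) {
    cat(sprintf("<sij_polyline side=%s absent>\n", x$side))
  } else {
    cat(sprintf("<sij_polyline side=%s vertices=%d>\n", x$side, n_vertices(x)))
  }
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.sij_polyline <- function(x, ...) {
  xs <- x$x; ys <- x$y; side <- x$side  # tibble() masks `x` sequentially
  tibble(x = xs, y = ys, side = side)
}

#' Reverse the vertex order of a polyline
#'
#' Reversal swaps the roles of the source (first vertex) and sink (last
#' vertex) endpoints and flips all on-contour field directions.
#'
#' @param poly A `sij_polyline`.
#' @export
reverse_polyline <- function(poly) {
  if (!poly$present) return(poly)
  polyline(rev(poly$x), rev(poly$y), side = poly$side)
}

#' Nearest polyline vertex to a point
#'
#' @param p Numeric length-2 vector `c(x, y)` in pixels.
#' @param poly A present `sij_polyline` with at least one vertex.
#' @return A list with `index` (1-based vertex index) and `distance` in
#'   pixels. Ties are broken toward the lowest index.
#' @examples
#' nearest_vertex(c(9, 3), polyline(c(5, 5), c(3, 7)))
#' @export
nearest_vertex <- function(p, poly) {
  if (!inherits(poly, "sij_polyline")) abort("`poly` must be a sij_polyline")
  if (!poly$present || n_vertices(poly) == 0L) {
    abort("cannot search an absent or empty polyline")
  }
  d2 <- (poly$x - p[[1]])^2 + (poly$y - p[[2]])^2
  k <- which.min(d2)  # which.min returns the first minimum: lowest index wins
  list(index = k, distance = sqrt(d2[[k]]))
}

#' Resample a polyline to a fixed vertex count by arclength
#'
#' Linear interpolation along the cumulative arclength of the contour; the
#' first and last vertices are preserved exactly. Used to up-sample sparse
#' annotations to the 21 landmark targets of the heatmap baseline network.
#'
#' @param poly A present `sij_polyline` with at least 2 vertices.
#' @param n Number of output vertices.
#' @export
resample_polyline <- function(poly, n = 21L) {
  if (!poly$present || n_vertices(poly) < 2L) {
    abort("resampling needs a present polyline with >= 2 vertices")
  }
  seg <- sqrt(diff(poly$x)^2 + diff(poly$y)^2)
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = n)
  x <- stats::approx(s, poly$x, xout = target, ties = "ordered")$y
  y <- stats::approx(s, poly$y, xout = target, ties = "ordered")$y
  # collapse accidental duplicates from zero-length spacing
  structure(list(x = x, y = y, side = poly$side, present = TRUE),
            class = "sij_polyline")
}

#' Apply an affine map to polyline vertices
#'
#' @param poly A `sij_polyline`.
#' @param m 2x2 linear part; `off` length-2 offset. Maps
#'   `p' = m %*% p + off` with `p = c(x, y)`.
#' @param off Length-2 numeric offset.
#' @param shape Optional `c(height, width)`; when given, a polyline with any
#'   vertex outside `[0, width-1] x [0, height-1]` is marked absent (the joint
#'   left the field of view).
#' @keywords internal
#' @export
transform_polyline <- function(poly, m, off = c(0, 0), shape = NULL) {
  if (!poly$present) return(poly)
  xy <- m %*% rbind(poly$x, poly$y) + as.numeric(off)
  if (!is.null(shape)) {
    h <- shape[[1]]; w <- shape[[2]]
    if (any(xy[1, ] < 0 | xy[1, ] > w - 1 | xy[2, ] < 0 | xy[2, ] > h - 1)) {
      return(absent_polyline(poly$side))
    }
  }
  polyline(xy[1, ], xy[2, ], side = poly$side)
}
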