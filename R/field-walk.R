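#' Walker parameters
#'
#' @param step_length Step size in pixels; each walking step is 1 unit in
#'   magnitude by default (smaller steps give higher-fidelity contours).
#' @param stop_radius Distance to the sink peak at which the walk terminates;
#'   defaults to the sink heatmap's sigma at walk time.
#' @param max_steps Hard step bound; defaults to 4 x the image diagonal,
#'   bounding runtime on pathological fields.
#' @param presence_threshold Minimum source-peak value for the joint to be
#'   considered present; below it an absent polyline is returned.
#' @param inertia Direction-memory weight in `[0, 1)`: the step direction is
#'   `normalise(inertia * previous + (1 - inertia) * field)`. Regressed
#'   fields carry sparse local defects (small attractors) that trap a
#'   memoryless walker in two-point orbits; inertia carries the walk
#'   through them. Steps keep length `step_length`.
#' @export
#' @param no_backtrack Forbid direction reversals of more than 90 degrees
#'   between consecutive steps by projecting out the backward component;
#'   escapes two-point orbits at local defects of regressed fields while
#'   following the field exactly elsewhere.
#' @param escape_loops Detect revisits of recent positions (limit cycles
#'   around defects of regressed fields) and tunnel straight ahead one
#'   double-length step to escape.
walk_params <- function(step_length = 1, stop_radius = NULL, max_steps = NULL,
                        presence_threshold = 0.3, inertia = 0,
                        no_backtrack = FALSE, escape_loops = FALSE) {
  if (step_length <= 0) abort("`step_length` must be > 0")
  if (!is.null(max_steps) && max_steps < 1) abort("`max_steps` must be >= 1")
  if (inertia < 0 || inertia >= 1) abort("`inertia` must be in [0, 1)")
  structure(list(step_length = step_length, stop_radius = stop_radius,
                 max_steps = max_steps, presence_threshold = presence_threshold,
                 inertia = inertia, no_backtrack = isTRUE(no_backtrack),
                 escape_loops = isTRUE(escape_loops)),
            class = "sij_walk_params")
}

#' Sample a vector field at a continuous location
#'
#' Bilinear interpolation of the two component planes, renormalised to unit
#' length. Walking follows continuous positions between pixel centres, so the
#' raster field must be interpolated off-grid.
#'
#' @param field A `sij_field`.
#' @param p `c(x, y)` inside the field extent
#'   (`0 <= x <= width-1`, `0 <= y <= height-1`).
#' @return Unit vector `c(ux, uy)`.
#' @export
sample_field <- function(field, p) {
  h <- nrow(field$ux); w <- ncol(field$ux)
  x <- p[[1]]; y <- p[[2]]
  if (!is.finite(x) || !is.finite(y) || x < 0 || y < 0 || x > w - 1 || y > h - 1) {
    abort("point outside field extent", class = "sijmri_out_of_bounds")
  }
  x0 <- min(floor(x), w - 2L); y0 <- min(floor(y), h - 2L)
  if (w == 1L) x0 <- 0L
  if (h == 1L) y0 <- 0L
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1L; j <- x0 + 1L
  bil <- function(m) {
    if (w == 1L && h == 1L) return(m[1, 1])
    m00 <- m[i, j]
    m10 <- if (h > 1L) m[i + 1L, j] else m00
    m01 <- if (w > 1L) m[i, j + 1L] else m00
    m11 <- if (w > 1L && h > 1L) m[i + 1L, j + 1L] else m00
    (1 - fx) * ((1 - fy) * m00 + fy * m10) + fx * ((1 - fy) * m01 + fy * m11)
  }
  ux <- bil(field$ux); uy <- bil(field$uy)
  nrm <- sqrt(ux^2 + uy^2)
  if (nrm < 1e-8) {
    abort("ambiguous field: interpolated vector has near-zero norm",
          class = "sijmri_ambiguous_field")
  }
  c(ux, uy) / nrm
}

heatmap_argmax <- function(hm) {
  k <- which.max(hm)  # first maximum in column-major order: deterministic
  i <- (k - 1L) %% nrow(hm) + 1L
  j <- (k - 1L) %/% nrow(hm) + 1L
  c(j - 1L, i - 1L)  # (x, y), 0-based
}

#' Extract an open contour by walking a unit vector field
#'
#' Starts at the argmax of the source heatmap and repeatedly steps
#' `step_length` pixels along the (interpolated) field direction; the walk
#' succeeds when it comes within `stop_radius` of the sink peak, which is
#' then appended as the final vertex. If the source peak value is below
#' `presence_threshold` the joint is declared absent. A walk that leaves the
#' image, stalls on an ambiguous field, or exhausts `max_steps` returns the
#' truncated polyline with the corresponding attribute flag set.
#'
#' @param field A `sij_field` (unit-normalised; see [normalise_field()]).
#' @param source,sink `sij_heatmap`s on the same grid as `field`.
#' @param params A [walk_params()] object.
#' @param side Side tag for the returned polyline.
#' @param start,goal Optional `c(x, y)` overrides of the source/sink
#'   argmax positions (used by [walk_targets()]'s endpoint candidates).
#' @return A `sij_polyline` with attributes `converged`, `out_of_bounds`,
#'   `stalled`.
#' @export
walk_contour <- function(field, source, sink, params = walk_params(),
                         side = c("left", "right"), start = NULL,
                         goal = NULL) {
  side <- match.arg(side)
  if (!all(dim(field$ux) == dim(source)) || !all(dim(source) == dim(sink))) {
    abort("field and heatmap shapes must agree")
  }
  if (max(source) < params$presence_threshold) {
    return(structure(absent_polyline(side),
                     converged = FALSE, out_of_bounds = FALSE, stalled = FALSE))
  }
  h <- nrow(source); w <- ncol(source)
  sg <- attr(sink, "sigma") %||% NA_real_
  if (!is.finite(sg)) sg <- estimate_heatmap_sigma(sink)
  stop_radius <- params$stop_radius %||% sg
  max_steps <- params$max_steps %||% ceiling(4 * sqrt(h^2 + w^2))
  start <- start %||% heatmap_argmax(source)
  goal <- goal %||% heatmap_argmax(sink)

  xs <- numeric(max_steps + 2L); ys <- numeric(max_steps + 2L)
  xs[1] <- start[[1]]; ys[1] <- start[[2]]; n <- 1L
  p <- as.numeric(start)
  u_prev <- NULL
  converged <- FALSE; oob <- FALSE; stalled <- FALSE
  for (step in seq_len(max_steps)) {
    if (sqrt(sum((p - goal)^2)) <= stop_radius) { converged <- TRUE; break }
    # midpoint (RK2) evaluation: the direction is re-sampled half a step
    # ahead, which stabilises integration across the tangential band where
    # the analytic field is discontinuous; each step is still step_length
    # in magnitude
    u1 <- tryCatch(sample_field(field, p),
                   sijmri_ambiguous_field = function(e) NULL)
    if (is.null(u1)) {
      # coast straight across a zero-norm patch when a direction exists
      if (is.null(u_prev)) { stalled <- TRUE; break }
      u1 <- u_prev
    }
    mid <- p + 0.5 * params$step_length * u1
    u <- if (mid[[1]] < 0 || mid[[2]] < 0 ||
             mid[[1]] > w - 1 || mid[[2]] > h - 1) u1 else
      tryCatch(sample_field(field, mid),
               sijmri_ambiguous_field = function(e) u1)
    if (params$no_backtrack && !is.null(u_prev)) {
      # remove any backward component: the walk follows the field exactly
      # unless the sampled direction reverses by more than 90 degrees, which
      # on a regressed field signals a local defect rather than the contour
      back <- sum(u * u_prev)
      if (back < 0) {
        u <- u - back * u_prev
        nu <- sqrt(sum(u^2))
        if (nu < 1e-8) u <- u_prev else u <- u / nu
      }
    }
    if (params$inertia > 0 && !is.null(u_prev)) {
      u <- params$inertia * u_prev + (1 - params$inertia) * u
      nu <- sqrt(sum(u^2))
      if (nu < 1e-8) { stalled <- TRUE; break }
      u <- u / nu
    }
    u_prev <- u
    p_next <- p + params$step_length * u
    if (params$escape_loops && n > 3L) {
      # limit-cycle escape: revisiting a recent position means the walk is
      # orbiting a local defect of a regressed field; tunnel straight ahead
      recent <- max(1L, n - 8L):(n - 1L)
      if (any((xs[recent] - p_next[[1]])^2 + (ys[recent] - p_next[[2]])^2 <
                (0.5 * params$step_length)^2)) {
        p_next <- p + 2 * params$step_length * u
      }
    }
    if (p_next[[1]] < 0 || p_next[[2]] < 0 ||
        p_next[[1]] > w - 1 || p_next[[2]] > h - 1) { oob <- TRUE; break }
    p <- p_next
    n <- n + 1L; xs[n] <- p[[1]]; ys[n] <- p[[2]]
  }
  xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]
  if (converged && (xs[n] != goal[[1]] || ys[n] != goal[[2]])) {
    xs <- c(xs, goal[[1]]); ys <- c(ys, goal[[2]])
  }
  out <- structure(list(x = xs, y = ys, side = side, present = TRUE),
                   class = "sij_polyline")
  structure(out, converged = converged, out_of_bounds = oob, stalled = stalled)
}

#' Walk both sides of a predicted 8-plane target
#'
#' Convenience wrapper: normalises the field planes of a `sij_targets`
#' (typically network output) and walks each side. When `params` is a list
#' of [walk_params()], they form a cascade: each is tried in order and the
#' first non-degenerate converged walk (at least 3 vertices) is kept.
#'
#' On regressed targets the endpoint planes can fail in characteristic
#' ways — the two peaks can collapse onto one end, or the source and sink
#' planes can swap identities. When the plain cascade fails, two fallback
#' endpoint candidates are tried: a source argmax masked away from the
#' sink position (the two endpoints of a contour are distinct by
#' definition), and the swapped pair (walking from the sink-labelled peak;
#' the field's own direction still orients the contour correctly). The
#' last attempt is returned if nothing converges.
#'
#' @param targets A `sij_targets`.
#' @param params A [walk_params()] object, or a list of them.
#' @param min_separation Mask radius (pixels) for the masked-source
#'   candidate.
#' @export
walk_targets <- function(targets, params = walk_params(),
                         min_separation = 6) {
  if (inherits(params, "sij_walk_params")) params <- list(params)
  one_side <- function(side) {
    field <- normalise_field(targets[[side]]$field)
    src <- targets[[side]]$source; snk <- targets[[side]]$sink
    ok <- function(w) {
      !w$present || (isTRUE(attr(w, "converged")) && n_vertices(w) >= 3L)
    }
    run <- function(start, goal) {
      out <- NULL
      for (wp in params) {
        out <- walk_contour(field, src, snk, wp, side, start = start,
                            goal = goal)
        if (ok(out)) break
      }
      out
    }
    out <- run(NULL, NULL)
    if (ok(out)) return(out)
    sp <- heatmap_argmax(src); kp <- heatmap_argmax(snk)
    masked <- mask_heatmap(src, kp, min_separation)
    cand <- list(list(heatmap_argmax(masked), kp),  # distinct-endpoint source
                 list(kp, sp))                      # swapped identities
    for (cc in cand) {
      alt <- run(cc[[1]], cc[[2]])
      if (ok(alt)) return(alt)
    }
    out
  }
  list(left = one_side("left"), right = one_side("right"))
}

# zero a heatmap within `radius` of a point (x, y)
mask_heatmap <- function(hm, centre, radius) {
  x <- matrix(rep(0:(ncol(hm) - 1L), each = nrow(hm)), nrow(hm))
  y <- matrix(rep(0:(nrow(hm) - 1L), times = ncol(hm)), nrow(hm))
  out <- unclass(hm)
  out[(x - centre[[1]])^2 + (y - centre[[2]])^2 <= radius^2] <- 0
  structure(out, class = "sij_heatmap", peak = attr(hm, "peak"),
            sigma = attr(hm, "sigma"))
}

#' A robust walker cascade for regressed fields
#'
#' Plain field-following first, then increasingly inertial retries for
#' walks that fail to converge on local field defects.
#' @param stop_radius Termination distance passed to every stage.
#' @export
walk_cascade <- function(stop_radius = 2) {
  list(walk_params(stop_radius = stop_radius),
       walk_params(stop_radius = stop_radius, inertia = 0.5),
       walk_params(stop_radius = stop_radius, inertia = 0.7),
       walk_params(stop_radius = stop_radius, inertia = 0.85))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scale of a (roughly Gaussian) heatmap from its mass: a unit-peak isotropic
# Gaussian integrates to 2*pi*sigma^2. Used for the walker's default stop
# radius on predicted heatmaps, whose sigma is not known a priori.
estimate_heatmap_sigma <- function(hm) {
  pk <- max(hm)
  if (pk <= 0) return(1)
  max(1, sqrt(sum(hm) / (2 * pi * pk)))
}
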