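#' Synthetic scene specification
#'
#' Describes the synthetic coronal slices used to exercise the delineation
#' pipeline: two smooth, roughly vertical open contours (the left and right
#' joint lines) on either side of an inter-contour "sacrum" region, rendered
#' as dark joint-space bands over a brighter background with Gaussian noise
#' and mild blur. Either side may be absent, emulating joints outside the
#' field of view.
#'
#' @param size Square image size in pixels.
#' @param n_vertices Integer range `c(min, max)` of annotation vertices per
#'   contour (annotations carry 2 to 21 vertices).
#' @param absence_prob Probability that a side is absent from a slice.
#' @param edge_strength Intensity depth of the joint-space band.
#' @param line_width Gaussian width of the band in pixels.
#' @param noise_sd Additive noise sd (intensity units).
#' @param blur_sigma Blur applied after rendering, in pixels.
#' @param wiggle Lateral smoothness of the contours (fraction of size).
#' @export
scene_spec <- function(size = 64L, n_vertices = c(4L, 12L),
                       absence_prob = 0.1, edge_strength = 0.55,
                       line_width = 1.2, noise_sd = 0.04, blur_sigma = 0.6,
                       wiggle = 0.06) {
  structure(list(size = as.integer(size), n_vertices = as.integer(n_vertices),
                 absence_prob = absence_prob, edge_strength = edge_strength,
                 line_width = line_width, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, wiggle = wiggle),
            class = "sij_scene_spec")
}

# one roughly vertical smooth contour for a side; vertices run top to bottom
random_side_contour <- function(spec, side) {
  s <- spec$size
  n <- sample(spec$n_vertices[1]:spec$n_vertices[2], 1L)
  cx <- if (side == "left") runif(1, 0.26, 0.36) else runif(1, 0.64, 0.74)
  y0 <- runif(1, 0.12, 0.25); y1 <- runif(1, 0.75, 0.88)
  ys <- seq(y0, y1, length.out = n) * (s - 1)
  ys <- ys + c(0, runif(n - 2L, -0.2, 0.2) * diff(ys)[1], 0)
  # smoothed lateral offsets: random walk passed through a moving average
  steps <- rnorm(n, sd = spec$wiggle * s)
  off <- cumsum(steps)
  if (n >= 3L) off <- stats::filter(off, rep(1 / 3, 3), sides = 2)
  off[is.na(off)] <- 0
  off <- off - mean(off)
  bow <- runif(1, -0.06, 0.06) * s  # gentle arc
  t <- seq(-1, 1, length.out = n)
  xs <- cx * (s - 1) + off + bow * (1 - t^2)
  # clamp each side to its own half so the two joint lines never cross
  if (side == "left") {
    xs <- pmin(pmax(xs, 2), s * 0.47)
  } else {
    xs <- pmin(pmax(xs, s * 0.53), s - 3)
  }
  ys <- pmin(pmax(ys, 2), s - 3)
  # enforce distinct consecutive vertices
  keep <- c(TRUE, diff(xs) != 0 | diff(ys) != 0)
  polyline(xs[keep], ys[keep], side)
}

render_contours <- function(left, right, spec) {
  s <- spec$size
  img <- matrix(0.55, s, s)
  # brighter bone plates on either side of each joint line
  gx <- matrix(rep(0:(s - 1), each = s), s, s)
  img <- img + 0.1 * sin(gx / s * pi)
  for (poly in list(left, right)) {
    if (!poly$present || n_vertices(poly) < 2L) next
    d <- distance_to_polyline(poly, c(s, s))
    img <- img - spec$edge_strength * exp(-d^2 / (2 * spec$line_width^2))
  }
  if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_sd > 0) img <- img + matrix(rnorm(s * s, sd = spec$noise_sd), s, s)
  img
}

# unsigned distance from every pixel to the polyline
distance_to_polyline <- function(poly, shape) {
  h <- shape[[1]]; w <- shape[[2]]
  px <- rep(0:(w - 1L), each = h); py <- rep(0:(h - 1L), times = w)
  vx <- poly$x; vy <- poly$y
  d2 <- rep(Inf, h * w)
  for (k in seq_len(length(vx) - 1L)) {
    dx <- vx[k + 1L] - vx[k]; dy <- vy[k + 1L] - vy[k]
    l2 <- dx^2 + dy^2
    if (l2 == 0) next
    t <- pmin(1, pmax(0, ((px - vx[k]) * dx + (py - vy[k]) * dy) / l2))
    d2 <- pmin(d2, (vx[k] + t * dx - px)^2 + (vy[k] + t * dy - py)^2)
  }
  matrix(sqrt(d2), h, w)
}

#' Random simple open polyline
#'
#' A smooth random-heading walk with bounded turning, rejected until it is
#' simple (non-self-intersecting by a pairwise vertex-distance test) and
#' fully in-frame. Used by the analytic walker-recovery experiments.
#'
#' @param size Square frame size in pixels.
#' @param n_vertices `c(min, max)` vertex count.
#' @param spacing `c(min, max)` step between consecutive vertices (pixels).
#' @param side Side tag.
#' @export
random_polyline <- function(size = 64L, n_vertices = c(4L, 21L),
                            spacing = c(2, 5), side = "left") {
  repeat {
    n <- sample(n_vertices[1]:n_vertices[2], 1L)
    start <- runif(2, size * 0.2, size * 0.8)
    heading <- runif(1, 0, 2 * pi)
    step <- runif(1, spacing[1], spacing[2])
    xs <- start[1]; ys <- start[2]
    for (k in seq_len(n - 1L)) {
      heading <- heading + runif(1, -0.5, 0.5)
      xs <- c(xs, xs[k] + step * cos(heading))
      ys <- c(ys, ys[k] + step * sin(heading))
    }
    if (any(xs < 2 | xs > size - 3 | ys < 2 | ys > size - 3)) next
    if (n > 2L) {
      d <- as.matrix(stats::dist(cbind(xs, ys)))
      far <- abs(row(d) - col(d)) > 1
      if (min(d[far]) < spacing[1] * 0.8) next
    }
    return(polyline(xs, ys, side))
  }
}

#' Generate one synthetic annotated slice
#'
#' @param spec A [scene_spec()].
#' @param seed Optional seed; with a seed the result is a pure function of
#'   `(spec, seed)`.
#' @return A [slice_sample()] with rendered image and landmark annotations.
#' @export
make_slice <- function(spec = scene_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  left <- if (runif(1) < spec$absence_prob) absent_polyline("left") else
    random_side_contour(spec, "left")
  right <- if (runif(1) < spec$absence_prob) absent_polyline("right") else
    random_side_contour(spec, "right")
  img <- render_contours(left, right, spec)
  slice_sample(img, left, right)
}

#' Generate a synthetic annotated volume
#'
#' A base pair of contours drifts smoothly across slices: each slice
#' displaces every vertex by at most `drift` pixels from the previous
#' slice, emulating the anterior-to-posterior change of the joint line.
#'
#' @param spec A [scene_spec()].
#' @param n_slices Number of coronal slices (scans carry roughly 20).
#' @param drift Per-slice vertex displacement bound in pixels.
#' @param seed Optional seed.
#' @return List with `volume` (`size x size x n_slices`), `contours`
#'   (tibble `slice`, `side`, `present`, `contour` list-column) and
#'   `spacing`.
#' @export
make_volume <- function(spec = scene_spec(), n_slices = 20L, drift = 0.8,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- spec$size
  left <- random_side_contour(spec, "left")
  right <- random_side_contour(spec, "right")
  vol <- array(0, c(s, s, n_slices))
  rows <- vector("list", 2L * n_slices)
  for (k in seq_len(n_slices)) {
    if (k > 1L) {
      shift_poly <- function(p) {
        ang <- runif(1, 0, 2 * pi); mag <- runif(1, 0, drift)
        dx <- mag * cos(ang) + rnorm(n_vertices(p), sd = drift / 4)
        dy <- mag * sin(ang) + rnorm(n_vertices(p), sd = drift / 4)
        dx <- pmin(pmax(dx, -drift), drift); dy <- pmin(pmax(dy, -drift), drift)
        polyline(pmin(pmax(p$x + dx, 1), s - 2), pmin(pmax(p$y + dy, 1), s - 2),
                 p$side)
      }
      left <- shift_poly(left); right <- shift_poly(right)
    }
    vol[, , k] <- render_contours(left, right, spec)
    rows[[2L * k - 1L]] <- tibble(slice = k, side = "left", present = TRUE,
                                  contour = list(left))
    rows[[2L * k]] <- tibble(slice = k, side = "right", present = TRUE,
                             contour = list(right))
  }
  list(volume = vol, contours = dplyr::bind_rows(rows), spacing = 1)
}

#' Reader noise model
#'
#' Per-reader flip probabilities applied independently per session (given
#' the latent truth). A `correlation` knob makes a reader's sessions share
#' one flip decision with the given probability, producing intra-reader
#' correlated errors.
#'
#' @param rates Per-reader flip probability (applied to both classes) —
#'   length R.
#' @param sessions Read sessions per reader.
#' @param pos_rates,neg_rates Optional class-specific flip rates (flip a
#'   true positive / true negative), overriding `rates`.
#' @param correlation Probability that a reader's sessions share one flip
#'   draw.
#' @export
reader_model <- function(rates = c(0.1, 0.25), sessions = 3L,
                         pos_rates = NULL, neg_rates = NULL,
                         correlation = 0) {
  pos_rates <- pos_rates %||% rates
  neg_rates <- neg_rates %||% rates
  if (any(c(pos_rates, neg_rates) < 0 | c(pos_rates, neg_rates) >= 0.5)) {
    abort("flip probabilities must lie in [0, 0.5)")
  }
  structure(list(readers = length(pos_rates), sessions = as.integer(sessions),
                 pos_rates = pos_rates, neg_rates = neg_rates,
                 correlation = correlation),
            class = "sij_reader_model")
}

#' Simulate a multi-reader label table from latent truth
#'
#' @param truth Tibble with `sample_id`, `task_id`, `truth` (0/1).
#' @param readers A [reader_model()].
#' @param seed Optional seed.
#' @return Raw label tibble (`sample_id`, `task_id`, `reader`, `session`,
#'   `label`).
#' @export
make_reader_labels <- function(truth, readers = reader_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  rows <- vector("list", readers$readers * readers$sessions)
  i <- 0L
  for (r in seq_len(readers$readers)) {
    rate <- ifelse(truth$truth == 1, readers$pos_rates[r], readers$neg_rates[r])
    shared <- rbinom(n, 1L, rate)             # one draw per sample
    corr <- runif(n) < readers$correlation    # sessions share it?
    for (s in seq_len(readers$sessions)) {
      flip <- ifelse(corr, shared, rbinom(n, 1L, rate))
      i <- i + 1L
      rows[[i]] <- tibble(sample_id = truth$sample_id,
                          task_id = truth$task_id,
                          reader = r, session = s,
                          label = as.numeric(xor(truth$truth, flip)))
    }
  }
  dplyr::bind_rows(rows)
}

#' Planted lesion model for synthetic ROI pairs
#'
#' Defines latent truth prevalences and the image effect of each lesion in
#' the synthetic joint crops. Effects are localised regional intensity
#' shifts in a canonical crop geometry (ilium = lateral half, sacrum =
#' medial half, upper/lower = vertical halves; the joint line runs down the
#' crop centre): oedema brightens a quadrant of the STIR crop, fatty lesions
#' brighten a quadrant of the T1 crop, erosions darken the joint margin of a
#' quadrant in T1, sclerosis darkens a band along the whole joint line in
#' T1, and ankylosis bridges the joint line with bright signal in both
#' sequences. Truth is recoverable from regional crop means by
#' construction.
#'
#' @param prevalence Named per-lesion positive prevalence.
#' @param strength Intensity amplitude of the planted effects.
#' @export
lesion_plant <- function(prevalence = c(oedema = 0.3, fatty = 0.3,
                                        erosion = 0.3, sclerosis = 0.3,
                                        ankylosis = 0.3),
                         strength = 0.45) {
  structure(list(prevalence = prevalence, strength = strength),
            class = "sij_lesion_plant")
}

#' The 14 lesion classification tasks per joint
#'
#' Bone marrow oedema, fatty lesions and erosions are scored per quadrant
#' (upper/lower ilium, upper/lower sacrum); sclerosis and ankylosis per
#' joint: 3 x 4 + 2 = 14 tasks per SIJ, 28 per left-right pair.
#' @return Tibble with `task_id`, `lesion`, `level`, `quadrant`.
#' @export
lesion_task_spec <- function() {
  quads <- c("upper_ilium", "lower_ilium", "upper_sacrum", "lower_sacrum")
  q <- tidyr::expand_grid(lesion = c("oedema", "fatty", "erosion"),
                          quadrant = quads)
  dplyr::bind_rows(
    tibble(task_id = paste(q$lesion, q$quadrant, sep = "_"),
           lesion = q$lesion, level = "quadrant", quadrant = q$quadrant),
    tibble(task_id = c("sclerosis", "ankylosis"),
           lesion = c("sclerosis", "ankylosis"), level = "joint",
           quadrant = NA_character_))
}

# quadrant mask in canonical crop coordinates (x: 0 = lateral/ilium edge)
quadrant_mask <- function(size, quadrant) {
  half <- size %/% 2L
  xs <- if (grepl("ilium", quadrant)) seq_len(half) else (half + 1L):size
  ys <- if (grepl("upper", quadrant)) seq_len(half) else (half + 1L):size
  list(ys = ys, xs = xs)
}

plant_effects <- function(t1, stir, truth_row, plant, tasks) {
  size <- nrow(t1[, , 1])
  ctr <- (size + 1) / 2
  band <- abs(col(t1[, , 1]) - ctr) <= max(1, size * 0.08)
  st <- plant$strength
  for (k in seq_len(nrow(tasks))) {
    if (truth_row[[tasks$task_id[k]]] != 1) next
    lesion <- tasks$lesion[k]
    if (tasks$level[k] == "quadrant") {
      m <- quadrant_mask(size, tasks$quadrant[k])
      if (lesion == "oedema") {
        stir[m$ys, m$xs, ] <- stir[m$ys, m$xs, ] + st
      } else if (lesion == "fatty") {
        t1[m$ys, m$xs, ] <- t1[m$ys, m$xs, ] + st
      } else if (lesion == "erosion") {
        sel <- band
        sel[-m$ys, ] <- FALSE; sel[, -m$xs] <- FALSE
        for (sl in seq_len(dim(t1)[3])) {
          pl <- t1[, , sl]; pl[sel] <- pl[sel] - st; t1[, , sl] <- pl
        }
      }
    } else if (lesion == "sclerosis") {
      for (sl in seq_len(dim(t1)[3])) {
        pl <- t1[, , sl]; pl[band] <- pl[band] - st; t1[, , sl] <- pl
      }
    } else if (lesion == "ankylosis") {
      rows <- abs(row(t1[, , 1]) - ctr) <= max(1, size * 0.12)
      sel <- rows & band
      for (sl in seq_len(dim(t1)[3])) {
        pl <- t1[, , sl]; pl[sel] <- pl[sel] + st; t1[, , sl] <- pl
        ps <- stir[, , sl]; ps[sel] <- ps[sel] + st; stir[, , sl] <- ps
      }
    }
  }
  list(t1 = t1, stir = stir)
}

#' Generate a planted-lesion classification corpus
#'
#' Per patient, two joints (left and right); per joint, a paired T1-like and
#' STIR-like ROI crop volume with lesions planted according to the latent
#' truth, and a multi-reader label table produced by flipping the truth
#' through the reader model. The latent truth is returned for recovery
#' experiments.
#'
#' @param n_patients Number of patients.
#' @param plant A [lesion_plant()].
#' @param readers A [reader_model()].
#' @param roi_size Square crop size in pixels.
#' @param n_slices Slices per ROI volume.
#' @param noise_sd Background noise sd.
#' @param seed Optional seed.
#' @return List with `rois` (tibble: `sample_id`, `patient`, `side`, `t1`,
#'   `stir` list-columns), `labels` (raw label tibble over all 14 tasks),
#'   `truth` (tibble `sample_id`, `task_id`, `truth`) and `tasks`.
#' @export
make_lesion_dataset <- function(n_patients, plant = lesion_plant(),
                                readers = reader_model(), roi_size = 32L,
                                n_slices = 3L, noise_sd = 0.05, seed = NULL) {
  if (n_patients < 1L) abort("`n_patients` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tasks <- lesion_task_spec()
  roi_rows <- vector("list", 2L * n_patients)
  truth_rows <- vector("list", 2L * n_patients)
  i <- 0L
  for (pat in seq_len(n_patients)) {
    for (side in c("left", "right")) {
      i <- i + 1L
      sample_id <- sprintf("P%03d_%s", pat, side)
      tr <- setNames(as.list(rbinom(nrow(tasks), 1L,
                                    plant$prevalence[tasks$lesion])),
                     tasks$task_id)
      base <- function() {
        a <- array(0.5, c(roi_size, roi_size, n_slices))
        a + array(rnorm(length(a), sd = noise_sd), dim(a))
      }
      planted <- plant_effects(base(), base(), tr, plant, tasks)
      roi_rows[[i]] <- tibble(sample_id = sample_id, patient = pat,
                              side = side, t1 = list(planted$t1),
                              stir = list(planted$stir))
      truth_rows[[i]] <- tibble(sample_id = sample_id,
                                task_id = tasks$task_id,
                                truth = as.numeric(unlist(tr)))
    }
  }
  truth <- dplyr::bind_rows(truth_rows)
  labels <- make_reader_labels(truth, readers)
  list(rois = dplyr::bind_rows(roi_rows), labels = labels, truth = truth,
       tasks = tasks)
}
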