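#' Coronal alignment angle from delineated contours
#'
#' Aggregates, over every slice, the extreme (upper and lower) contour
#' vertices of each joint and returns the mean of the angles of the
#' upper-left-to-upper-right and lower-left-to-lower-right lines, in
#' degrees. Rotating the volume by the negative of this angle brings the
#' two lines close to horizontal.
#'
#' @param contours Tibble with columns `slice`, `side`, `present`,
#'   `contour` (list of `sij_polyline`), as produced by
#'   [delineate_volume()] or [make_volume()].
#' @return Angle in degrees (positive = the right joint sits lower).
#' @export
volume_alignment_angle <- function(contours) {
  pts <- side_extremes(contours)
  if (is.null(pts$left) || is.null(pts$right)) {
    abort("both joints must be present in at least one slice")
  }
  ang <- function(a, b) atan2(b[2] - a[2], b[1] - a[1]) * 180 / pi
  upper <- ang(pts$left$upper, pts$right$upper)
  lower <- ang(pts$left$lower, pts$right$lower)
  (upper + lower) / 2
}

# extreme-y vertices per side, pooled across all slices
side_extremes <- function(contours) {
  out <- list()
  for (sd in c("left", "right")) {
    rows <- contours[contours$side == sd & contours$present, ]
    if (nrow(rows) == 0L) { out[sd] <- list(NULL); next }
    xs <- unlist(lapply(rows$contour, function(p) p$x))
    ys <- unlist(lapply(rows$contour, function(p) p$y))
    out[[sd]] <- list(upper = c(xs[which.min(ys)], min(ys)),
                      lower = c(xs[which.max(ys)], max(ys)))
  }
  out
}

#' Rotate a volume and its contours in the coronal plane
#'
#' Every slice is rotated by `-degrees` about the slice centre (bilinear
#' interpolation, zero fill) and the contour vertices are transformed by
#' the exact matching rotation, so image and annotations stay consistent.
#'
#' @param volume `H x W x n_slices` array.
#' @param contours Contour tibble (see [volume_alignment_angle()]).
#' @param degrees Angle returned by [volume_alignment_angle()].
#' @return List with rotated `volume` and `contours`.
#' @export
rotate_volume <- function(volume, contours, degrees) {
  if (!is.finite(degrees)) abort("`degrees` must be finite")
  if (length(dim(volume)) == 2L) volume <- array(volume, c(dim(volume), 1L))
  h <- dim(volume)[1]; w <- dim(volume)[2]
  th <- -degrees * pi / 180
  m <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  off <- ctr - m %*% ctr
  out <- volume
  if (degrees != 0) {
    for (s in seq_len(dim(volume)[3])) {
      out[, , s] <- affine_sample(volume[, , s], m, off)
    }
  }
  contours$contour <- lapply(contours$contour, function(p) {
    if (!p$present) return(p)
    transform_polyline(p, m, off)
  })
  list(volume = out, contours = contours)
}

#' Slice-consistent minimum bounding boxes per joint
#'
#' Per side, the box is the integer-snapped (floor/ceil, half-open) hull of
#' every contour vertex over all slices: one static box per side per
#' volume, with no margin.
#'
#' @param contours Aligned contour tibble.
#' @return Tibble with `side`, `x0`, `y0` (inclusive), `x1`, `y1`
#'   (exclusive); absent sides are omitted.
#' @export
extract_roi_boxes <- function(contours) {
  rows <- lapply(c("left", "right"), function(sd) {
    sub <- contours[contours$side == sd & contours$present, ]
    if (nrow(sub) == 0L) return(NULL)
    xs <- unlist(lapply(sub$contour, function(p) p$x))
    ys <- unlist(lapply(sub$contour, function(p) p$y))
    tibble(side = sd, x0 = floor(min(xs)), y0 = floor(min(ys)),
           x1 = ceiling(max(xs)) + (ceiling(max(xs)) == max(xs)),
           y1 = ceiling(max(ys)) + (ceiling(max(ys)) == max(ys)))
  })
  dplyr::bind_rows(rows)
}

#' Crop a registered T1/STIR pair to the joint boxes
#'
#' The same box is applied to every slice of both sequences (which must
#' share in-plane shape; slice counts may differ and are preserved). Left
#' crops are mirrored horizontally to the canonical (right-joint)
#' orientation; the flag is recorded so downstream labels can be unflipped.
#'
#' @param t1,stir `H x W x n_slices` arrays.
#' @param boxes Box tibble from [extract_roi_boxes()].
#' @param mirror_left Mirror left crops to canonical orientation.
#' @return Named list of `sij_roi_pair` objects (`left`, `right` as
#'   available): each has `t1`, `stir`, `box`, `side`, `mirrored`,
#'   `clipped`.
#' @export
crop_roi_pair <- function(t1, stir, boxes, mirror_left = TRUE) {
  if (length(dim(t1)) == 2L) t1 <- array(t1, c(dim(t1), 1L))
  if (length(dim(stir)) == 2L) stir <- array(stir, c(dim(stir), 1L))
  if (!all(dim(t1)[1:2] == dim(stir)[1:2])) {
    abort("T1 and STIR must share in-plane shape (registered at ROI scale)")
  }
  h <- dim(t1)[1]; w <- dim(t1)[2]
  out <- list()
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    clipped <- b$x0 < 0 || b$y0 < 0 || b$x1 > w || b$y1 > h
    if (clipped) {
      warn(sprintf("box for side %s clipped to the image extent", b$side))
    }
    x0 <- max(b$x0, 0); y0 <- max(b$y0, 0)
    x1 <- min(b$x1, w); y1 <- min(b$y1, h)
    xs <- (x0 + 1L):x1; ys <- (y0 + 1L):y1
    crop <- function(v) v[ys, xs, , drop = FALSE]
    ct1 <- crop(t1); cstir <- crop(stir)
    mirrored <- FALSE
    if (b$side == "left" && mirror_left) {
      ct1 <- ct1[, rev(seq_len(dim(ct1)[2])), , drop = FALSE]
      cstir <- cstir[, rev(seq_len(dim(cstir)[2])), , drop = FALSE]
      mirrored <- TRUE
    }
    out[[b$side]] <- structure(
      list(t1 = ct1, stir = cstir, side = b$side,
           box = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
           mirrored = mirrored, clipped = clipped),
      class = "sij_roi_pair")
  }
  out
}

#' Full ROI extraction for one study
#'
#' Convenience pipeline: estimate the alignment angle from the (T1-derived)
#' contours, rotate both sequences and the contours, take the
#' slice-consistent boxes and crop both sequences.
#'
#' @param t1,stir Sequence volumes (registered in-plane).
#' @param contours Contour tibble for the T1 volume.
#' @param mirror_left Mirror left crops to canonical orientation.
#' @return List with `pairs` (from [crop_roi_pair()]), `angle`, `boxes`.
#' @export
extract_rois <- function(t1, stir, contours, mirror_left = TRUE) {
  angle <- volume_alignment_angle(contours)
  rt1 <- rotate_volume(t1, contours, angle)
  rstir <- rotate_volume(stir, contours, angle)
  boxes <- extract_roi_boxes(rt1$contours)
  list(pairs = crop_roi_pair(rt1$volume, rstir$volume, boxes,
                             mirror_left = mirror_left),
       angle = angle, boxes = boxes)
}
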