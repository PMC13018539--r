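ct_row <- function(slice, side, poly) {
  tibble::tibble(slice = slice, side = side, present = poly$present,
                 contour = list(poly))
}

test_that("symmetric contours give a zero alignment angle", {
  left <- polyline(c(8, 8), c(10, 30), "left")
  right <- polyline(c(40, 40), c(10, 30), "right")
  ct <- dplyr::bind_rows(ct_row(1, "left", left), ct_row(1, "right", right))
  expect_equal(volume_alignment_angle(ct), 0)
})

test_that("the angle is the mean of the upper and lower line angles", {
  # upper line at +6 degrees, lower at +2 degrees -> 4
  up_l <- c(10, 10); up_r <- c(40, 10 + 30 * tan(6 * pi / 180))
  lo_l <- c(10, 40); lo_r <- c(40, 40 + 30 * tan(2 * pi / 180))
  left <- polyline(c(up_l[1], lo_l[1]), c(up_l[2], lo_l[2]), "left")
  right <- polyline(c(up_r[1], lo_r[1]), c(up_r[2], lo_r[2]), "right")
  ct <- dplyr::bind_rows(ct_row(1, "left", left), ct_row(1, "right", right))
  expect_equal(volume_alignment_angle(ct), 4, tolerance = 1e-10)
  expect_error(volume_alignment_angle(ct_row(1, "left", left)), "both")
})

test_that("a rotated stack's angle is recovered and rotation is invertible", {
  set.seed(3)
  vol <- make_volume(scene_spec(size = 48), n_slices = 4)
  th <- 10 * pi / 180
  m <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c(23.5, 23.5)
  rot <- vol$contours
  rot$contour <- lapply(rot$contour, function(p) {
    transform_polyline(p, m, ctr - m %*% ctr)
  })
  expect_equal(volume_alignment_angle(rot),
               volume_alignment_angle(vol$contours) + 10, tolerance = 0.5)
  # rotate by a then -a returns landmarks to within numerical noise
  r1 <- rotate_volume(vol$volume, vol$contours, 7)
  r2 <- rotate_volume(r1$volume, r1$contours, -7)
  p0 <- vol$contours$contour[[1]]; p2 <- r2$contours$contour[[1]]
  expect_lt(max(abs(p0$x - p2$x), abs(p0$y - p2$y)), 1e-6)
  # rotating by zero is the identity
  r0 <- rotate_volume(vol$volume, vol$contours, 0)
  expect_identical(r0$volume, vol$volume)
})

test_that("aligning a volume is idempotent to within half a degree", {
  set.seed(5)
  vol <- make_volume(scene_spec(size = 48), n_slices = 5)
  ang <- volume_alignment_angle(vol$contours)
  aligned <- rotate_volume(vol$volume, vol$contours, ang)
  expect_lt(abs(volume_alignment_angle(aligned$contours)), 0.5)
})

test_that("boxes snap to integers with the half-open convention", {
  poly <- polyline(c(3, 7), c(4, 9), "left")
  boxes <- extract_roi_boxes(ct_row(1, "left", poly))
  expect_equal(unlist(boxes[1, c("x0", "y0", "x1", "y1")]),
               c(x0 = 3, y0 = 4, x1 = 8, y1 = 10))
  # a vertex on another slice grows the shared box
  more <- dplyr::bind_rows(ct_row(1, "left", poly),
                           ct_row(2, "left", polyline(c(2, 5), c(2, 5), "left")))
  grown <- extract_roi_boxes(more)
  expect_equal(grown$x0, 2); expect_equal(grown$y0, 2)
  expect_equal(grown$x1, 8); expect_equal(grown$y1, 10)
})

test_that("boxes are minimal: every face is pinned by a vertex", {
  set.seed(7)
  for (rep in 1:100) {
    polys <- lapply(1:3, function(s) rand_poly(sample(2:8, 1), size = 30))
    ct <- dplyr::bind_rows(lapply(seq_along(polys), function(s) {
      ct_row(s, "left", polys[[s]])
    }))
    b <- extract_roi_boxes(ct)
    xs <- unlist(lapply(polys, `[[`, "x")); ys <- unlist(lapply(polys, `[[`, "y"))
    # every vertex inside the half-open box
    expect_true(all(xs >= b$x0 & xs < b$x1 & ys >= b$y0 & ys < b$y1))
    # shrinking any face by one pixel excludes at least one vertex
    expect_true(any(xs < b$x0 + 1)); expect_true(any(xs >= b$x1 - 1))
    expect_true(any(ys < b$y0 + 1)); expect_true(any(ys >= b$y1 - 1))
  }
})

test_that("crops share the box across sequences and preserve slice counts", {
  set.seed(9)
  t1 <- array(runif(48 * 48 * 12), c(48, 48, 12))
  stir <- array(runif(48 * 48 * 14), c(48, 48, 14))
  boxes <- tibble::tibble(side = c("left", "right"),
                          x0 = c(5, 30), y0 = c(10, 10),
                          x1 = c(15, 42), y1 = c(40, 40))
  pairs <- crop_roi_pair(t1, stir, boxes)
  expect_equal(dim(pairs$left$t1), c(30L, 10L, 12L))
  expect_equal(dim(pairs$left$stir), c(30L, 10L, 14L))
  expect_equal(dim(pairs$right$t1), c(30L, 12L, 12L))
  expect_true(pairs$left$mirrored)
  expect_false(pairs$right$mirrored)
  # mirroring twice is the identity
  m <- pairs$left$t1
  expect_equal(m[, rev(seq_len(dim(m)[2])), , drop = FALSE][, rev(seq_len(dim(m)[2])), , drop = FALSE], m)
  # raw left crop data equals the unmirrored region mirrored once
  raw <- t1[11:40, 6:15, , drop = FALSE]
  expect_equal(pairs$left$t1, raw[, 10:1, , drop = FALSE])
  # out-of-image boxes are clipped with a warning
  bad <- tibble::tibble(side = "right", x0 = 40, y0 = -2, x1 = 60, y1 = 20)
  expect_warning(clipped <- crop_roi_pair(t1, stir, bad), "clipped")
  expect_equal(dim(clipped$right$t1)[1:2], c(20L, 8L))
  expect_error(crop_roi_pair(t1, array(0, c(10, 10, 3)), boxes), "share")
})

test_that("crops contain every contour vertex of their side", {
  set.seed(11)
  vol <- make_volume(scene_spec(size = 48), n_slices = 3)
  rois <- extract_rois(vol$volume, vol$volume, vol$contours)
  for (sd in c("left", "right")) {
    b <- rois$boxes[rois$boxes$side == sd, ]
    rot_ct <- rotate_volume(vol$volume, vol$contours, rois$angle)$contours
    sub <- rot_ct[rot_ct$side == sd, ]
    xs <- unlist(lapply(sub$contour, `[[`, "x"))
    ys <- unlist(lapply(sub$contour, `[[`, "y"))
    expect_true(all(xs >= b$x0 & xs < b$x1 & ys >= b$y0 & ys < b$y1))
  }
})
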