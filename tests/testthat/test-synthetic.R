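test_that("slice generation is a pure function of spec and seed", {
  spec <- scene_spec(size = 32)
  a <- make_slice(spec, seed = 5)
  b <- make_slice(spec, seed = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$left, b$left)
  c <- make_slice(spec, seed = 6)
  expect_false(identical(a$image, c$image))
})

test_that("forced absence yields absent sides with zero heatmap targets", {
  spec <- scene_spec(size = 32, absence_prob = 1)
  s <- make_slice(spec, seed = 3)
  expect_false(s$left$present)
  expect_false(s$right$present)
  planes <- targets_to_planes(contour_targets(s$left, s$right, c(32, 32)))
  expect_true(all(planes == 0))
})

test_that("generated scenes have valid non-intersecting contours", {
  set.seed(9)
  spec <- scene_spec(size = 48)
  seg_intersect <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
      (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  for (rep in 1:200) {
    s <- make_slice(spec)
    for (side in c("left", "right")) {
      p <- s[[side]]
      if (!p$present) next
      expect_gte(n_vertices(p), 2L)
      expect_lte(n_vertices(p), 21L)
      expect_true(all(p$x >= 0 & p$x <= 47 & p$y >= 0 & p$y <= 47))
    }
    if (s$left$present && s$right$present) {
      crossed <- FALSE
      for (i in seq_len(n_vertices(s$left) - 1L)) {
        for (j in seq_len(n_vertices(s$right) - 1L)) {
          crossed <- crossed || seg_intersect(
            c(s$left$x[i], s$left$y[i]), c(s$left$x[i + 1], s$left$y[i + 1]),
            c(s$right$x[j], s$right$y[j]), c(s$right$x[j + 1], s$right$y[j + 1]))
        }
      }
      expect_false(crossed)
    }
  }
})

test_that("volumes drift smoothly and recover an applied rotation", {
  vol <- make_volume(scene_spec(size = 48), n_slices = 20, drift = 0.8,
                     seed = 13)
  expect_equal(dim(vol$volume)[3], 20L)
  expect_equal(nrow(vol$contours), 40L)
  for (sd in c("left", "right")) {
    sub <- vol$contours[vol$contours$side == sd, ]
    for (k in 2:20) {
      a <- sub$contour[[k - 1L]]; b <- sub$contour[[k]]
      expect_lte(max(abs(b$x - a$x), abs(b$y - a$y)), 0.8 + 1e-9)
    }
  }
  th <- 8 * pi / 180
  m <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- vol$contours
  rot$contour <- lapply(rot$contour, function(p) {
    transform_polyline(p, m, c(23.5, 23.5) - m %*% c(23.5, 23.5))
  })
  expect_equal(volume_alignment_angle(rot) - volume_alignment_angle(vol$contours),
               8, tolerance = 0.5)
})

test_that("reader flips hit their nominal rate", {
  set.seed(17)
  n <- 2000
  truth <- tibble::tibble(sample_id = sprintf("s%04d", 1:n), task_id = "t",
                          truth = rbinom(n, 1, 0.5))
  labels <- make_reader_labels(truth, reader_model(rates = c(0.2, 0.2),
                                                   sessions = 1))
  joined <- dplyr::inner_join(labels, truth, by = c("sample_id", "task_id"))
  flip_rate <- mean(joined$label != joined$truth)
  expect_lt(abs(flip_rate - 0.2), 0.02)
  # zero noise: labels equal truth and inter-consensus exists everywhere
  clean <- make_reader_labels(truth, reader_model(rates = c(0, 0)))
  ct <- compute_consensus(clean)
  expect_true(all(!is.na(ct$inter$label)))
  expect_equal(ct$inter$label[order(ct$inter$sample_id)],
               truth$truth[order(truth$sample_id)])
})

test_that("less noisy readers retain more intra-consensus labels", {
  set.seed(19)
  n <- 2000
  truth <- tibble::tibble(sample_id = sprintf("s%04d", 1:n), task_id = "t",
                          truth = rbinom(n, 1, 0.5))
  labels <- make_reader_labels(truth, reader_model(rates = c(0.05, 0.3)))
  ct <- compute_consensus(labels)
  kept <- tapply(!is.na(ct$intra$label), ct$intra$reader, sum)
  expect_gt(kept[["1"]], kept[["2"]])
})

test_that("consensus coverage decreases with the flip probability", {
  set.seed(23)
  n <- 600
  truth <- tibble::tibble(sample_id = sprintf("s%04d", 1:n), task_id = "t",
                          truth = rbinom(n, 1, 0.5))
  coverage <- sapply(c(0, 0.1, 0.3), function(r) {
    labels <- make_reader_labels(truth, reader_model(rates = c(r, r)))
    mean(!is.na(compute_consensus(labels)$inter$label))
  })
  expect_true(all(diff(coverage) < 0))
})

test_that("planted lesions are recoverable from regional crop means", {
  ds <- make_lesion_dataset(40, readers = reader_model(rates = c(0, 0)),
                            seed = 29)
  expect_equal(nrow(ds$rois), 80L)
  expect_equal(nrow(ds$truth), 80L * 14L)
  # oedema truth vs mean STIR intensity in its quadrant separates linearly
  task <- "oedema_upper_ilium"
  tr <- ds$truth[ds$truth$task_id == task, ]
  feat <- vapply(seq_len(nrow(ds$rois)), function(i) {
    v <- ds$rois$stir[[i]]
    mean(v[1:16, 1:16, ])
  }, numeric(1))
  y <- tr$truth[match(ds$rois$sample_id, tr$sample_id)]
  expect_gt(min(feat[y == 1]), max(feat[y == 0]))
})

test_that("correlated sessions share their flip decisions", {
  set.seed(31)
  n <- 1500
  truth <- tibble::tibble(sample_id = sprintf("s%04d", 1:n), task_id = "t",
                          truth = rbinom(n, 1, 0.5))
  labels <- make_reader_labels(truth, reader_model(rates = c(0.3, 0.3),
                                                   correlation = 1))
  ct <- compute_consensus(labels)
  # perfect correlation: sessions always agree, intra-consensus everywhere
  expect_true(all(!is.na(ct$intra$label)))
})
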