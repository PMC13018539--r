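test_that("square slices resample isotropically", {
  img <- matrix(runif(448 * 448), 448, 448)
  prep <- preprocess_slice(img, size = 224)
  expect_equal(dim(prep$image), c(224L, 224L))
  expect_equal(prep$scale, 0.5)
  expect_equal(prep$pad_to, 448L)
})

test_that("non-square slices are zero-padded before resampling", {
  set.seed(3)
  img <- matrix(runif(400 * 300), 400, 300)
  prep <- preprocess_slice(img, size = 224)
  expect_equal(prep$pad_to, 400L)
  # content occupies 300/400 of the width; the rest is the zero padding
  pad_cols <- (ceiling(300 / 400 * 224) + 2):224
  expect_lt(max(abs(prep$image[, pad_cols])), 1e-6)
  # aspect ratio preserved: a landmark keeps its x/y ratio under the map
  poly <- polyline(c(100, 260), c(100, 380))
  mapped <- map_to_preprocessed(poly, prep)
  expect_equal(diff(mapped$x) / diff(mapped$y),
               diff(poly$x) / diff(poly$y), tolerance = 1e-10)
})

test_that("landmark round-trips through the model frame are exact", {
  set.seed(5)
  for (shape in list(c(64, 64), c(80, 50), c(37, 91))) {
    img <- matrix(runif(prod(shape)), shape[1], shape[2])
    prep <- preprocess_slice(img, size = 32)
    poly <- polyline(runif(5, 0, shape[2] - 1), runif(5, 0, shape[1] - 1))
    back <- map_to_native(map_to_preprocessed(poly, prep), prep)
    expect_lt(max(abs(back$x - poly$x), abs(back$y - poly$y)), 0.51)
  }
})

test_that("bicubic resampling is exact on constants and near-exact on ramps", {
  img <- matrix(3.7, 20, 20)
  expect_equal(resize_bicubic(img, 10, 10),
               matrix(3.7, 10, 10), tolerance = 1e-10)
  ramp <- matrix(rep(seq(0, 1, length.out = 40), each = 40), 40, 40)
  small <- resize_bicubic(ramp, 20, 20)
  expect_equal(dim(small), c(20L, 20L))
  expect_lt(max(abs(small[10, ] - seq(0.0125, 0.9875, length.out = 20))), 0.02)
})

test_that("a zero-range augmentation is the identity", {
  set.seed(7)
  s <- make_slice(scene_spec(size = 32, absence_prob = 0))
  spec <- augment_spec(translate = 0, scale = 0, rotate = 0, lr_flip = FALSE,
                       noise_sigma = 0, blur_sigma = 0)
  a <- augment_slice(s, spec)
  expect_equal(a$image, s$image, tolerance = 1e-10)
  expect_equal(a$left$x, s$left$x)
  expect_equal(a$right$y, s$right$y)
})

test_that("a pure left-right flip mirrors x and swaps the sides", {
  set.seed(9)
  s <- make_slice(scene_spec(size = 32, absence_prob = 0))
  s$right <- absent_polyline("right")  # only a left contour
  spec <- augment_spec(translate = 0, scale = 0, rotate = 0, lr_flip = TRUE,
                       noise_sigma = 0, blur_sigma = 0)
  # draw until the flip fires (probability 1/2 per draw)
  repeat {
    a <- augment_slice(s, spec)
    if (a$right$present || a$left$present) {
      if (a$right$present) break
    }
  }
  expect_false(a$left$present)
  expect_equal(a$right$side, "right")
  expect_equal(sort(a$right$x), sort(31 - s$left$x), tolerance = 1e-10)
})

test_that("targets regenerated after rotation match direct construction", {
  set.seed(11)
  s <- make_slice(scene_spec(size = 32, absence_prob = 0))
  spec <- augment_spec(translate = 0, scale = 0, rotate = 15, lr_flip = FALSE,
                       noise_sigma = 0, blur_sigma = 0)
  a <- augment_slice(s, spec)
  skip_if(!a$left$present || !a$right$present)  # rotated out of frame
  tg <- contour_targets(a$left, a$right, c(32, 32))
  direct <- build_target_uvf(a$left, c(32, 32))
  probes <- cbind(sample(0:31, 20, replace = TRUE),
                  sample(0:31, 20, replace = TRUE))
  for (i in 1:20) {
    x <- probes[i, 1]; y <- probes[i, 2]
    expect_equal(c(tg$left$field$ux[y + 1, x + 1],
                   tg$left$field$uy[y + 1, x + 1]),
                 c(direct$ux[y + 1, x + 1], direct$uy[y + 1, x + 1]),
                 tolerance = 1e-10)
  }
})

test_that("the delineation loss separates exactly into its two terms", {
  set.seed(13)
  tgt <- array(runif(16 * 16 * 8), c(16, 16, 8))
  pred <- array(runif(16 * 16 * 8), c(16, 16, 8))
  l <- delineation_loss(pred, tgt, alpha = 7)
  expect_equal(l$total, l$field + l$heatmap)
  expect_gte(l$field, 0); expect_gte(l$heatmap, 0)
  expect_equal(delineation_loss(tgt, tgt, alpha = 7)$total, 0)
  # alpha = 0 degenerates to plain MSE on the heatmap planes
  l0 <- delineation_loss(pred, tgt, alpha = 0)
  expect_equal(l0$heatmap, mean((pred[, , c(3, 4, 7, 8)] -
                                   tgt[, , c(3, 4, 7, 8)])^2))
  expect_error(delineation_loss(pred * NaN, tgt), "NaN")
})

test_that("the hand-computed 2x2 weighted heatmap case evaluates to 2.75", {
  tgt <- array(0, c(2, 2, 8))
  tgt[1, 1, 3] <- 1  # one heatmap pixel at 1, all else 0
  pred <- array(0, c(2, 2, 8))
  l <- delineation_loss(pred, tgt, alpha = 10)
  # weighted heatmap term: (1 + 10*1) * 1 / (2*2*4 heat pixels) * 4 planes
  expect_equal(l$heatmap, 11 / 16)
  tgt2 <- array(0, c(2, 2, 8)); tgt2[, , 3] <- matrix(c(1, 0, 0, 0), 2, 2)
  l2 <- delineation_loss(array(0, c(2, 2, 8)), tgt2, alpha = 10)
  expect_equal(l2$heatmap * 4, 2.75)  # per-plane mean of the worked example
})
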