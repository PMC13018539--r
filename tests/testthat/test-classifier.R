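desk_cfg <- function(seed = 1L) {
  classifier_config(input_size = 16L, depth = 2L, width = 4L, seed = seed)
}

test_that("the task table has 14 heads per joint", {
  tasks <- lesion_task_spec()
  expect_equal(nrow(tasks), 14L)
  expect_equal(sum(tasks$level == "quadrant"), 12L)
  expect_equal(sum(tasks$level == "joint"), 2L)
  expect_setequal(unique(tasks$lesion),
                  c("oedema", "fatty", "erosion", "sclerosis", "ankylosis"))
})

test_that("ROI encoding pools slice embeddings", {
  model <- build_classifier(desk_cfg())
  set.seed(3)
  slice <- array(runif(16 * 16), c(16, 16, 1))
  one <- encode_roi(model, slice)
  # duplicated slices with mean pooling leave the embedding unchanged
  five <- encode_roi(model, array(rep(slice, 5), c(16, 16, 5)))
  expect_equal(five, one, tolerance = 1e-6)
  # mean pooling equals the hand-averaged per-slice embeddings
  vol <- array(runif(16 * 16 * 3), c(16, 16, 3))
  pooled <- encode_roi(model, vol)
  per_slice <- sapply(1:3, function(s) {
    encode_roi(model, vol[, , s, drop = FALSE])
  })
  expect_equal(pooled, rowMeans(per_slice), tolerance = 1e-6)
  expect_error(encode_roi(model, array(0, c(16, 16, 0))), "empty")
})

test_that("predictions cover 14 tasks per joint on the simplex", {
  model <- build_classifier(desk_cfg())
  set.seed(5)
  pair <- list(t1 = array(runif(16 * 16 * 2), c(16, 16, 2)),
               stir = array(runif(16 * 16 * 2), c(16, 16, 2)))
  p1 <- predict_lesions(model, pair)
  expect_equal(nrow(p1), 14L)
  expect_true(all(p1$p_positive >= 0 & p1$p_positive <= 1))
  bundles <- attr(p1, "bundles")
  for (b in bundles) {
    for (q in b$nodes) expect_equal(sum(q), 1, tolerance = 1e-6)
  }
  # left-right pair -> 28 predictions
  p2 <- predict_lesions(model, pair)
  expect_equal(nrow(p1) + nrow(p2), 28L)
  # deterministic for fixed weights and input
  expect_identical(p1$p_positive, p2$p_positive)
  expect_error(predict_lesions(model, list(t1 = pair$t1)), "required")
})

test_that("per-patient folds partition subjects into near-equal groups", {
  folds <- crossval_split(sprintf("pat%02d", 1:16), k = 8, seed = 4)
  expect_equal(nrow(folds), 16L)
  expect_equal(unname(as.vector(table(folds$fold))), rep(2L, 8))
  expect_setequal(folds$subject, sprintf("pat%02d", 1:16))
  # repeated subjects collapse to one row each (scans stay with the patient)
  folds2 <- crossval_split(rep(c("a", "b", "c"), each = 5), k = 3, seed = 1)
  expect_equal(nrow(folds2), 3L)
  expect_error(crossval_split(c("a", "b"), k = 3), "exceeds")
  # uneven split differs by at most one
  f3 <- crossval_split(letters[1:11], k = 3, seed = 2)
  expect_lte(diff(range(table(f3$fold))), 1)
})

test_that("rank AUC matches pairwise concordance and handles ties", {
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    expect_equal(auc_rank(scores, labels), bf_auc(scores, labels))
  }
  expect_true(is.na(auc_rank(runif(5), rep(1, 5))))
  expect_equal(auc_rank(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
})

test_that("evaluation uses only consensus-labelled samples", {
  preds <- tibble::tibble(sample_id = c("a", "b", "c"), task_id = "t",
                          p_positive = c(0.9, 0.2, 0.7))
  labels <- tibble::tibble(sample_id = c("a", "b", "c"), task_id = "t",
                           label = c(1, 0, NA))
  m <- evaluate_predictions(preds, labels)
  expect_equal(m$n, 2L)
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1); expect_equal(m$specificity, 1)
  # adding another non-consensus sample changes nothing
  preds2 <- dplyr::bind_rows(preds, tibble::tibble(sample_id = "d",
                                                   task_id = "t",
                                                   p_positive = 0.99))
  labels2 <- dplyr::bind_rows(labels, tibble::tibble(sample_id = "d",
                                                     task_id = "t",
                                                     label = NA_real_))
  expect_equal(as.data.frame(evaluate_predictions(preds2, labels2)),
               as.data.frame(m))
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  # 10 positives at sensitivity 0.6, 25 negatives at specificity 0.96
  preds <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:35), task_id = "t",
    p_positive = c(rep(0.9, 6), rep(0.1, 4), rep(0.1, 24), 0.9))
  labels <- tibble::tibble(sample_id = preds$sample_id, task_id = "t",
                           label = c(rep(1, 10), rep(0, 25)))
  m <- evaluate_predictions(preds, labels)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.96)
  expect_equal(m$balanced_accuracy, 0.78)
})

test_that("AUC is flagged undefined when a class is missing", {
  preds <- tibble::tibble(sample_id = c("a", "b"), task_id = "t",
                          p_positive = c(0.8, 0.6))
  labels <- tibble::tibble(sample_id = c("a", "b"), task_id = "t",
                           label = c(1, 1))
  m <- evaluate_predictions(preds, labels)
  expect_false(m$auc_defined)
  expect_equal(m$sensitivity, 1)
  expect_true(is.na(m$specificity))
})

test_that("short classifier training reduces the loss deterministically", {
  ds <- make_lesion_dataset(8, roi_size = 16L, n_slices = 2L,
                            readers = reader_model(rates = c(0, 0)),
                            seed = 11)
  cfg <- desk_cfg(seed = 2)
  m1 <- train_classifier(ds, cfg, steps = 40, batch_size = 4)
  m2 <- train_classifier(ds, cfg, steps = 40, batch_size = 4)
  expect_identical(m1$history$loss, m2$history$loss)
  first10 <- mean(head(m1$history$loss, 10))
  last10 <- mean(tail(m1$history$loss, 10))
  expect_lt(last10, first10)
  expect_error(train_classifier(list(rois = ds$rois[0, ], labels = ds$labels),
                                cfg), "empty")
})
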