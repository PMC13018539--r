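# Self-contained benchmark experiments over the synthetic test bed. Each is
# a pure function of its seed and sizes; the acceptance suite and the
# reproduction script both call these.

#' Analytic-field walker recovery
#'
#' Generates random simple polylines, builds their analytic unit vector
#' field and endpoint heatmaps, walks from source to sink, and measures the
#' closest-point RMS against the generating polyline. With an exact field
#' the walk should recover the contour to sub-pixel accuracy in nearly
#' every case.
#'
#' @param n_cases Number of random polylines.
#' @param size Grid size in pixels.
#' @param seed RNG seed.
#' @param sigma_frac Endpoint heatmap scale relative to contour length.
#' @return List with `recovery_rate` (fraction with RMS < 1 px), `mean_rms`
#'   and the per-case tibble.
#' @export
experiment_walker_oracle <- function(n_cases = 200L, size = 64L, seed = 1L,
                                     sigma_frac = 0.05) {
  set.seed(seed)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    poly <- random_polyline(size)
    field <- build_target_uvf(poly, c(size, size))
    sg <- max(1, sigma_frac * contour_length(poly))
    hm <- build_endpoint_heatmaps(poly, c(size, size), sg)
    walked <- walk_contour(field, hm$source, hm$sink, walk_params(), "left")
    rms <- if (walked$present) closest_point_rms(walked, poly) else Inf
    rows[[i]] <- tibble(case = i, n_vertices = n_vertices(poly), rms = rms,
                        converged = isTRUE(attr(walked, "converged")))
  }
  cases <- dplyr::bind_rows(rows)
  list(recovery_rate = mean(cases$rms < 1), mean_rms = mean(cases$rms),
       cases = cases)
}

#' Desk-scale delineation benchmark
#'
#' Trains the unit-vector-field delineator and the 21-heatmap landmark
#' baseline on the same synthetic slices with the same optimisation budget,
#' then compares held-out closest-point RMS. Only joints present in the
#' truth are scored; a predicted absence counts as a miss and is reported
#' separately.
#'
#' @param n_train,n_test Training and held-out slice counts.
#' @param steps,batch_size Optimisation budget (shared by both networks).
#' @param seed RNG seed (scene generation and both trainings).
#' @param scene A [scene_spec()].
#' @param config,baseline_config Network configurations; the defaults are
#'   the desk-scale recipe described in the methods vignette.
#' @param walk Walker parameter cascade for the field network.
#' @return List with `uvf` and `baseline` summaries (mean/median RMS,
#'   detection counts), the per-case tibble, and the trained models.
#' @export
experiment_delineation <- function(n_train = 200L, n_test = 40L,
                                   steps = 300L, batch_size = 8L, seed = 1L,
                                   scene = scene_spec(),
                                   config = desk_delineator_config(),
                                   baseline_config = desk_delineator_config("landmarks"),
                                   walk = walk_cascade()) {
  set.seed(seed)
  train <- lapply(seq_len(n_train), function(i) make_slice(scene))
  test <- lapply(seq_len(n_test), function(i) make_slice(scene))
  uvf <- train_delineator(train, config, augment = NULL, steps = steps,
                          batch_size = batch_size)
  base <- train_delineator(train, baseline_config, augment = NULL,
                           steps = steps, batch_size = batch_size)
  score <- function(model, wp) {
    rows <- list()
    for (i in seq_along(test)) {
      s <- test[[i]]
      res <- delineate_volume(model, s$image, walk = wp)
      for (side in c("left", "right")) {
        gt <- s[[side]]
        if (!gt$present || n_vertices(gt) < 2L) next
        pred <- res$contour[res$side == side][[1]]
        rows[[length(rows) + 1L]] <- tibble(
          case = i, side = side, detected = pred$present,
          rms = if (pred$present) closest_point_rms(pred, gt) else NA_real_)
      }
    }
    dplyr::bind_rows(rows)
  }
  summarise_rms <- function(cases) {
    list(mean_rms = mean(cases$rms, na.rm = TRUE),
         median_rms = median(cases$rms, na.rm = TRUE),
         detected = sum(cases$detected), total = nrow(cases))
  }
  uvf_cases <- score(uvf, walk)
  base_cases <- score(base, walk_params())
  list(uvf = summarise_rms(uvf_cases), baseline = summarise_rms(base_cases),
       uvf_cases = uvf_cases, baseline_cases = base_cases,
       uvf_model = uvf, baseline_model = base)
}

#' Endpoint-plane health of a trained delineator
#'
#' Predicts a handful of annotated validation slices and checks that the
#' decoded endpoint (or landmark) positions sit near the annotated contour
#' ends. A failed check indicates a training run stuck in a wrong endpoint
#' mode; training slices are unsuitable here because they are memorised.
#'
#' @param model A trained `sij_delineator`.
#' @param samples Annotated slices the model was not trained on.
#' @param tol Median decoded-endpoint error tolerance in pixels.
#' @export
delineator_health <- function(model, samples, tol = 6) {
  cfg <- model$config
  errs <- list(left = c(), right = c())  # judged per side: one bad side fails
  for (s in samples) {
    planes <- delineator_predict(model, normalise_intensity(s$image))
    for (side in c("left", "right")) {
      gt <- s[[side]]
      if (!gt$present || n_vertices(gt) < 2L) next
      m <- n_vertices(gt)
      if (cfg$mode == "uvf") {
        off <- if (side == "left") 0L else 4L
        src_plane <- off + 3L; snk_plane <- off + 4L
      } else {
        off <- if (side == "left") 0L else cfg$n_landmarks
        src_plane <- off + 1L; snk_plane <- off + cfg$n_landmarks
      }
      sp <- heatmap_argmax(planes[, , src_plane])
      kp <- heatmap_argmax(planes[, , snk_plane])
      errs[[side]] <- c(errs[[side]],
                        sqrt(sum((sp - c(gt$x[1], gt$y[1]))^2)),
                        sqrt(sum((kp - c(gt$x[m], gt$y[m]))^2)))
    }
  }
  all(vapply(errs, function(e) length(e) == 0L || median(e) <= tol,
             logical(1)))
}

#' The desk-scale delineator recipe
#'
#' 64 px inputs, depth-3, width-16 encoder-decoder with coordinate
#' channels; heatmap scale tied to a tenth of the sacrum scale, a widened
#' tangential band, and a doubled heatmap loss weight. Rationale for each
#' choice is in the methods vignette.
#' @param mode `"uvf"` or `"landmarks"`.
#' @param seed Initialisation seed.
#' @export
desk_delineator_config <- function(mode = "uvf", seed = 2L) {
  delineator_config(input_size = 64L, depth = 3L, width = 16L, mode = mode,
                    alpha = 50, heat_weight = 2, sigma_frac = 0.1,
                    on_contour_radius = 2, seed = seed)
}

#' Reader-noise recovery
#'
#' Simulates binary truth with separable scalar features, generates
#' multi-reader session labels by flipping the truth at per-reader rates,
#' fits the logistic multi-reader model, and compares each session node's
#' disagreement with the root prediction against the simulated rate.
#'
#' @param n Number of samples.
#' @param rates Per-reader flip probabilities.
#' @param sessions Read sessions per reader.
#' @param seed RNG seed.
#' @param steps,lr Optimiser budget for [fit_multireader_glm()].
#' @return List with the per-node tibble (`node`, `disagreement`,
#'   `true_rate`, `abs_error`), the fit, and the root accuracy vs truth.
#' @export
experiment_reader_noise <- function(n = 2000L, rates = c(0.1, 0.25),
                                    sessions = 3L, seed = 1L,
                                    steps = 1500L, lr = 0.05) {
  set.seed(seed)
  truth <- tibble(sample_id = sprintf("S%05d", seq_len(n)), task_id = "task",
                  truth = rbinom(n, 1L, 0.5))
  x <- matrix(rnorm(n, mean = ifelse(truth$truth == 1, 1, -1), sd = 0.4),
              ncol = 1)
  labels <- make_reader_labels(truth, reader_model(rates, sessions))
  tree <- consensus_tree(length(rates), sessions)
  fit <- fit_multireader_glm(x, labels, tree, steps = steps, lr = lr,
                             seed = seed)
  dis <- node_disagreement(fit, x)
  dis$reader <- as.integer(sub("^R([0-9]+)S.*$", "\\1", dis$node))
  dis$true_rate <- rates[dis$reader]
  dis$abs_error <- abs(dis$disagreement - dis$true_rate)
  root <- predict_multireader(fit, x)[[tree$root_id]]
  list(nodes = dis, fit = fit,
       root_accuracy = mean((root[, 2] > 0.5) == (truth$truth == 1)))
}

#' Desk-scale planted-lesion classification benchmark
#'
#' Generates the planted-lesion corpus and cross-fits the dual-sequence
#' classifier over per-patient folds: each fold's joints are predicted by a
#' model trained on the other folds, so every joint receives a held-out
#' prediction. Per lesion type, AUC pools the root-node predictions of the
#' lesion's tasks (quadrants are exchangeable in the synthetic corpus)
#' against inter-consensus labels.
#'
#' @param n_patients Patients in the corpus (two joints each).
#' @param steps,batch_size Optimiser budget per fold.
#' @param k Cross-fit folds.
#' @param seed RNG seed.
#' @param lr Learning rate of the desk recipe.
#' @param reader_rates Per-reader flip rates of the label simulator.
#' @return List with `lesion_auc` (per-lesion tibble), `metrics` (per-task
#'   tibble), `n_auc_ge_0.9`, the pooled held-out `preds`, and the
#'   last-fold model.
#' @export
experiment_classification <- function(n_patients = 100L, steps = 600L,
                                      batch_size = 8L, k = 2L,
                                      seed = 1L, lr = 3e-3,
                                      reader_rates = c(0.1, 0.25)) {
  set.seed(seed)
  ds <- make_lesion_dataset(n_patients, readers = reader_model(reader_rates))
  folds <- crossval_split(unique(ds$rois$patient), k = k, seed = seed)
  cfg <- classifier_config(seed = seed, lr = lr)
  preds <- list(); model <- NULL
  for (f in seq_len(k)) {
    test_pat <- folds$subject[folds$fold == f]
    tr <- !(ds$rois$patient %in% test_pat)
    train <- list(rois = ds$rois[tr, ],
                  labels = ds$labels[ds$labels$sample_id %in%
                                       ds$rois$sample_id[tr], ])
    model <- train_classifier(train, cfg, steps = steps,
                              batch_size = batch_size)
    test_rois <- ds$rois[!tr, ]
    preds[[f]] <- dplyr::bind_rows(lapply(seq_len(nrow(test_rois)), function(i) {
      p <- predict_lesions(model, list(t1 = test_rois$t1[[i]],
                                       stir = test_rois$stir[[i]]))
      p$sample_id <- test_rois$sample_id[i]
      p
    }))
  }
  preds <- dplyr::bind_rows(preds)
  lt <- compute_consensus(ds$labels)
  metrics <- evaluate_predictions(preds, lt, threshold = cfg$threshold)
  lesion_auc <- preds |>
    dplyr::inner_join(lt$inter, by = c("sample_id", "task_id")) |>
    dplyr::filter(!is.na(.data$label)) |>
    dplyr::left_join(lesion_task_spec(), by = "task_id") |>
    dplyr::group_by(.data$lesion) |>
    dplyr::summarise(auc = auc_rank(.data$p_positive, .data$label),
                     n = dplyr::n(), .groups = "drop")
  list(lesion_auc = lesion_auc, metrics = metrics,
       n_auc_ge_0.9 = sum(lesion_auc$auc >= 0.9, na.rm = TRUE),
       model = model, preds = preds, dataset = ds)
}
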