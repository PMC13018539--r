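#' Lesion classifier configuration
#'
#' A shared convolutional encoder consumes every slice of each sequence's
#' ROI crop; slice embeddings are pooled (mean by default), the T1 and STIR
#' embeddings are concatenated, and 14 task-specific linear heads produce
#' per-lesion class probabilities that are branched through per-task
#' consensus trees during training.
#'
#' @param input_size Square size crops are resampled to before encoding.
#'   The full profile uses 224; the desk profile of 32 suffices for the
#'   coarse regional contrasts of the synthetic lesions.
#' @param depth,width Encoder stages and first-stage channels.
#' @param grid Spatial pooling grid of the embedding (a `grid x grid`
#'   average rather than a global one, so quadrant-localised lesions stay
#'   decodable).
#' @param slice_pool `"mean"` or `"max"` pooling over slice embeddings.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param threshold Operating threshold on the positive-class probability.
#' @param lambda Trace regulariser weight.
#' @param seed Initialisation / training seed.
#' @export
classifier_config <- function(input_size = 32L, depth = 3L, width = 8L,
                              grid = 2L, slice_pool = c("mean", "max"),
                              lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                              threshold = 0.5, lambda = 1, seed = 1L) {
  slice_pool <- match.arg(slice_pool)
  if (input_size %% 2^depth != 0L) {
    abort("`input_size` must be divisible by 2^depth")
  }
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 width = as.integer(width), grid = as.integer(grid),
                 slice_pool = slice_pool, lr = lr, beta1 = beta1,
                 beta2 = beta2, threshold = threshold, lambda = lambda,
                 seed = as.integer(seed)),
            class = "sij_classifier_config")
}

embedding_dim <- function(config) {
  config$grid^2 * config$width * 2^(config$depth - 1L)
}

#' Build an untrained lesion classifier
#'
#' @param config A [classifier_config()].
#' @param tasks Task table from [lesion_task_spec()].
#' @param tree A template [consensus_tree()]; each task receives an
#'   independent copy (annotator matrices are not shared across tasks).
#' @export
build_classifier <- function(config, tasks = lesion_task_spec(),
                             tree = consensus_tree()) {
  set.seed(config$seed)
  encoder <- encoder_init(1L, config$depth, config$width)
  d <- 2L * embedding_dim(config)
  heads <- setNames(lapply(tasks$task_id, function(id) {
    list(w = matrix(rnorm(2L * d, sd = sqrt(1 / d)), 2L, d), b = rep(0, 2L))
  }), tasks$task_id)
  trees <- setNames(lapply(tasks$task_id, function(id) tree), tasks$task_id)
  structure(list(encoder = encoder, heads = heads, trees = trees,
                 tasks = tasks, config = config,
                 history = tibble(step = integer(), loss = numeric())),
            class = "sij_classifier")
}

#' @export
print.sij_classifier <- function(x, ...) {
  cat(sprintf("<sij_classifier %d tasks, %dpx depth=%d, %d training steps>\n",
              nrow(x$tasks), x$config$input_size, x$config$depth,
              nrow(x$history)))
  invisible(x)
}

prep_crop <- function(vol, config) {
  n <- dim(vol)[3]
  out <- array(0, c(config$input_size, config$input_size, n))
  for (s in seq_len(n)) {
    sl <- vol[, , s]
    if (!all(dim(sl) == config$input_size)) {
      sl <- resize_bicubic(sl, config$input_size, config$input_size)
    }
    out[, , s] <- normalise_intensity(sl)
  }
  out
}

#' Encode an ROI volume into one embedding
#'
#' Every slice is encoded independently by the shared encoder and the slice
#' embeddings are pooled into a single vector; deterministic given the
#' weights.
#'
#' @param model A `sij_classifier`.
#' @param roi `H x W x n_slices` array with at least one slice.
#' @export
encode_roi <- function(model, roi) {
  if (length(dim(roi)) == 2L) roi <- array(roi, c(dim(roi), 1L))
  if (dim(roi)[3] < 1L) abort("empty ROI volume")
  cfg <- model$config
  x <- prep_crop(roi, cfg)
  embs <- vapply(seq_len(dim(x)[3]), function(s) {
    encoder_forward(model$encoder, array(x[, , s], c(cfg$input_size,
                                                     cfg$input_size, 1L)),
                    cfg$depth, cfg$grid)$emb
  }, numeric(embedding_dim(cfg)))
  if (is.null(dim(embs))) embs <- matrix(embs, ncol = 1L)
  if (cfg$slice_pool == "mean") rowMeans(embs) else apply(embs, 1, max)
}

softmax2 <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Predict the 14 lesion tasks for one ROI pair
#'
#' The pair of sequence embeddings is concatenated and passed through each
#' task head; each base prediction is branched through that task's
#' consensus tree. The root-node (inter-consensus) positive probability is
#' the headline prediction.
#'
#' @param model A `sij_classifier`.
#' @param pair List with `t1` and `stir` ROI volumes for one joint.
#' @return Tibble with `task_id`, `p_positive` (root node),
#'   `base_positive`; the full per-task `sij_bundle`s are attached as the
#'   `"bundles"` attribute.
#' @export
predict_lesions <- function(model, pair) {
  if (is.null(pair$t1) || is.null(pair$stir)) {
    abort("both T1 and STIR crops are required")
  }
  e <- c(encode_roi(model, pair$t1), encode_roi(model, pair$stir))
  bundles <- list()
  rows <- lapply(model$tasks$task_id, function(id) {
    h <- model$heads[[id]]
    p <- softmax2(as.numeric(h$w %*% e + h$b))
    bundle <- branch_predictions(p, model$trees[[id]])
    bundles[[id]] <<- bundle
    tibble(task_id = id, p_positive = consensus_inference(bundle)[2],
           base_positive = p[2])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "bundles") <- bundles
  out
}

#' Per-patient cross-validation folds
#'
#' Seeded shuffle into k folds of near-equal size (differing by at most
#' one); every scan of a patient shares its fold, so folds are leakage-free
#' by construction.
#'
#' @param subjects Vector of unique subject identifiers.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return Tibble with `subject` and `fold`.
#' @export
crossval_split <- function(subjects, k = 8L, seed = 1L) {
  subjects <- unique(subjects)
  if (k > length(subjects)) abort("`k` exceeds the number of subjects")
  set.seed(seed)
  shuffled <- sample(subjects)
  tibble(subject = shuffled,
         fold = rep(seq_len(k), length.out = length(shuffled))) |>
    dplyr::arrange(.data$subject)
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve via the Mann-Whitney statistic with midranks
#' (tied scores averaged).
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC, or `NA` when a class is absent.
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate predictions against inter-consensus labels
#'
#' Samples without an inter-consensus label are excluded. Sensitivity and
#' specificity are computed at the operating threshold on the positive
#' probability; balanced accuracy is their mean; AUC uses [auc_rank()].
#'
#' @param preds Tibble with `sample_id`, `task_id`, `p_positive`.
#' @param labels A `sij_label_table` (from [compute_consensus()]) or a
#'   tibble with `sample_id`, `task_id`, `label` of consensus labels.
#' @param threshold Operating threshold.
#' @return A `sij_metrics` tibble: per task `auc`, `balanced_accuracy`,
#'   `sensitivity`, `specificity`, `n`, `threshold`, `auc_defined`.
#' @export
evaluate_predictions <- function(preds, labels, threshold = 0.5) {
  inter <- if (inherits(labels, "sij_label_table")) labels$inter else labels
  joined <- dplyr::inner_join(preds, inter, by = c("sample_id", "task_id")) |>
    dplyr::filter(!is.na(.data$label))
  out <- joined |>
    dplyr::group_by(.data$task_id) |>
    dplyr::summarise(
      auc = auc_rank(.data$p_positive, .data$label),
      sensitivity = {
        pos <- .data$label == 1
        if (any(pos)) mean(.data$p_positive[pos] >= threshold) else NA_real_
      },
      specificity = {
        neg <- .data$label == 0
        if (any(neg)) mean(.data$p_positive[neg] < threshold) else NA_real_
      },
      n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      balanced_accuracy = (.data$sensitivity + .data$specificity) / 2,
      threshold = threshold, auc_defined = !is.na(.data$auc)) |>
    dplyr::select("task_id", "auc", "balanced_accuracy", "sensitivity",
                  "specificity", "n", "threshold", "auc_defined")
  class(out) <- c("sij_metrics", class(out))
  out
}

#' Train the lesion classifier with the hierarchical multi-reader loss
#'
#' Adam on minibatches of joints: per sample and task, cross-entropy is
#' accumulated at every tree node with an available label (sessions on raw
#' labels, readers on intra-consensus, root on inter-consensus), averaged
#' over the batch, and the summed annotator traces enter once per batch
#' with weight `lambda`.
#'
#' @param dataset List with `rois` (tibble of `sample_id`, `t1`, `stir`
#'   list-columns) and `labels` (raw label table over the 14 tasks).
#' @param config A [classifier_config()].
#' @param tree Template [consensus_tree()] matching the label structure.
#' @param steps,batch_size Optimisation steps and minibatch size.
#' @return A trained `sij_classifier`.
#' @export
train_classifier <- function(dataset, config, tree = consensus_tree(),
                             steps = 300L, batch_size = 8L) {
  rois <- dataset$rois
  if (nrow(rois) == 0L) abort("empty training set")
  model <- build_classifier(config, tree = tree)
  model$trees <- lapply(model$trees, tree_jitter)
  cfg <- config
  lt <- compute_consensus(dataset$labels, tree$readers, tree$sessions)
  task_ids <- model$tasks$task_id
  # per-task node labels aligned to roi rows
  node_lab <- lapply(task_ids, function(tid) {
    sub <- lt
    sub$raw <- lt$raw[lt$raw$task_id == tid, ]
    sub$intra <- lt$intra[lt$intra$task_id == tid, ]
    sub$inter <- lt$inter[lt$inter$task_id == tid, ]
    mr_node_labels(sub, tree, rois$sample_id)
  })
  names(node_lab) <- task_ids
  d_emb <- embedding_dim(cfg)
  enc_state <- adam_init(model$encoder)
  head_state <- lapply(model$heads, function(h) {
    list(t = 0L, mw = 0 * h$w, vw = 0 * h$w, mb = 0 * h$b, vb = 0 * h$b)
  })
  tree_states <- lapply(model$trees, tree_adam_init)
  # pre-resampled crops (they are small)
  crops_t1 <- lapply(rois$t1, prep_crop, config = cfg)
  crops_stir <- lapply(rois$stir, prep_crop, config = cfg)
  hist <- numeric(steps)
  for (step in seq_len(steps)) {
    idx <- sample.int(nrow(rois), batch_size, replace = TRUE)
    enc_grads <- zero_grads(model$encoder)
    head_grads <- lapply(model$heads, function(h) list(dw = 0 * h$w, db = 0 * h$b))
    tree_grads <- lapply(model$trees, function(tr) NULL)
    loss_acc <- 0
    for (i in idx) {
      seqs <- list(t1 = crops_t1[[i]], stir = crops_stir[[i]])
      caches <- list(); embs <- list()
      for (sq in names(seqs)) {
        vol <- seqs[[sq]]
        ns <- dim(vol)[3]
        sc <- vector("list", ns); se <- matrix(0, d_emb, ns)
        for (s in seq_len(ns)) {
          fw <- encoder_forward(model$encoder,
                                array(vol[, , s], c(cfg$input_size,
                                                    cfg$input_size, 1L)),
                                cfg$depth, cfg$grid)
          sc[[s]] <- fw$cache; se[, s] <- fw$emb
        }
        caches[[sq]] <- sc
        embs[[sq]] <- se
      }
      e <- c(rowMeans(embs$t1), rowMeans(embs$stir))
      de <- 0 * e
      for (tid in task_ids) {
        h <- model$heads[[tid]]
        z <- as.numeric(h$w %*% e + h$b)
        P <- matrix(softmax2(z), 1L, 2L)
        tcaches <- mr_tree_forward(P, model$trees[[tid]])
        nl <- lapply(node_lab[[tid]], function(v) v[i])
        cg <- mr_ce_grads(tcaches, nl, n_eff = batch_size)
        loss_acc <- loss_acc + cg$ce
        bw <- mr_tree_backward(tcaches, cg$dQs, model$trees[[tid]],
                               lambda = cfg$lambda / batch_size)
        tree_grads[[tid]] <- if (is.null(tree_grads[[tid]])) bw$node_grads else
          mapply(function(a, b) list(da_raw = a$da_raw + b$da_raw,
                                     db_raw = a$db_raw + b$db_raw),
                 tree_grads[[tid]], bw$node_grads, SIMPLIFY = FALSE)
        dP <- as.numeric(bw$dP)
        dz <- P[1, ] * (dP - sum(dP * P[1, ]))
        head_grads[[tid]]$dw <- head_grads[[tid]]$dw + outer(dz, e)
        head_grads[[tid]]$db <- head_grads[[tid]]$db + dz
        de <- de + as.numeric(t(h$w) %*% dz)
      }
      for (sq in names(seqs)) {
        off <- if (sq == "t1") 0L else d_emb
        ns <- length(caches[[sq]])
        dslice <- de[off + seq_len(d_emb)] / ns  # mean pooling backward
        for (s in seq_len(ns)) {
          g <- encoder_backward(model$encoder, caches[[sq]][[s]], dslice,
                                cfg$depth, cfg$grid)
          enc_grads <- acc_grads(enc_grads, g)
        }
      }
    }
    upd <- adam_step(model$encoder, enc_grads, enc_state, lr = cfg$lr,
                     beta1 = cfg$beta1, beta2 = cfg$beta2)
    model$encoder <- upd$params; enc_state <- upd$state
    for (tid in task_ids) {
      hs <- head_state[[tid]]; hg <- head_grads[[tid]]
      hs$t <- hs$t + 1L
      c1 <- 1 - cfg$beta1^hs$t; c2 <- 1 - cfg$beta2^hs$t
      hs$mw <- cfg$beta1 * hs$mw + (1 - cfg$beta1) * hg$dw
      hs$vw <- cfg$beta2 * hs$vw + (1 - cfg$beta2) * hg$dw^2
      hs$mb <- cfg$beta1 * hs$mb + (1 - cfg$beta1) * hg$db
      hs$vb <- cfg$beta2 * hs$vb + (1 - cfg$beta2) * hg$db^2
      model$heads[[tid]]$w <- model$heads[[tid]]$w -
        cfg$lr * (hs$mw / c1) / (sqrt(hs$vw / c2) + 1e-8)
      model$heads[[tid]]$b <- model$heads[[tid]]$b -
        cfg$lr * (hs$mb / c1) / (sqrt(hs$vb / c2) + 1e-8)
      head_state[[tid]] <- hs
      tu <- tree_adam_step(model$trees[[tid]], tree_grads[[tid]],
                           tree_states[[tid]], lr = 10 * cfg$lr)
      model$trees[[tid]] <- tu$tree; tree_states[[tid]] <- tu$state
    }
    hist[step] <- loss_acc
  }
  model$history <- tibble(step = seq_len(steps), loss = hist)
  model
}
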