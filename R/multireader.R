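#' Rank-1 annotator matrices
#'
#' Each reader, read session, and consensus level is modelled by an
#' annotator matrix `A = a %o% b` of rank 1 (two learnable C-vectors rather
#' than a full confusion matrix), applied to the model's prediction as
#' `B p` with `B = I + A`. The vectors are parameterised through a tanh
#' squashing to `(-0.5, 0.5)` so that `B` stays near the identity and `B p`
#' stays near the probability simplex; the trace regulariser is otherwise
#' unbounded below.
#'
#' @param a,b Numeric vectors of equal length (the class dimension).
#' @return `rank1_matrix()`: the outer-product matrix `A[i, j] = a[i] b[j]`.
#' @examples
#' rank1_matrix(c(1, 0), c(0, 1))
#' @export
rank1_matrix <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length")
  outer(as.numeric(a), as.numeric(b))
}

#' @rdname rank1_matrix
#' @param node_id Node identifier (e.g. `"R1R2"`, `"R1"`, `"R1S2"`).
#' @param a_raw,b_raw Unconstrained parameters; the effective vectors are
#'   `0.5 * tanh(raw)`.
#' @export
annotator_node <- function(node_id, a_raw = c(0, 0), b_raw = c(0, 0)) {
  if (length(a_raw) != length(b_raw)) abort("parameter dims must agree")
  structure(list(node_id = node_id, a_raw = as.numeric(a_raw),
                 b_raw = as.numeric(b_raw)),
            class = "sij_annotator_node")
}

node_a <- function(node) 0.5 * tanh(node$a_raw)
node_b <- function(node) 0.5 * tanh(node$b_raw)

#' @rdname rank1_matrix
#' @param node An `sij_annotator_node`.
#' @export
annotator_matrix <- function(node) rank1_matrix(node_a(node), node_b(node))

#' @rdname rank1_matrix
#' @export
annotator_trace <- function(node) sum(node_a(node) * node_b(node))

#' Apply an annotator to a prediction
#'
#' Computes `q = (I + A) p`, clamps entries at `1e-6` and renormalises so
#' the result is a valid probability vector.
#'
#' @param node An [annotator_node()].
#' @param p Probability vector on the simplex (tolerance 1e-4).
#' @export
apply_annotator <- function(node, p) {
  if (any(p < -1e-4) || abs(sum(p) - 1) > 1e-4) {
    abort("`p` must lie on the probability simplex")
  }
  q <- p + node_a(node) * sum(node_b(node) * p)  # (I + a b^T) p
  q <- pmax(q, 1e-6)
  q / sum(q)
}

#' Consensus tree of annotator nodes
#'
#' The hierarchy mirrors how consensus labels are formed: the root models
#' the inter-reader consensus, its children the per-reader (intra-reader)
#' consensus, and their children the individual read sessions. With two
#' readers and three sessions the node set is
#' R1S1, R1S2, R1S3, R2S1, R2S2, R2S3, R1, R2, R1R2 (9 nodes). With one
#' session per reader the session level collapses and the tree is the root
#' plus one node per reader.
#'
#' @param readers Number of readers R.
#' @param sessions Read sessions per reader S.
#' @param classes Number of classes C (binary lesions: 2).
#' @export
consensus_tree <- function(readers = 2L, sessions = 3L, classes = 2L) {
  if (readers < 1L || sessions < 1L) abort("readers and sessions must be >= 1")
  root_id <- paste0("R", seq_len(readers), collapse = "")
  ids <- root_id
  reader_ids <- paste0("R", seq_len(readers))
  ids <- c(ids, reader_ids)
  session_ids <- character()
  if (sessions > 1L) {
    session_ids <- as.character(t(outer(reader_ids, paste0("S", seq_len(sessions)),
                                        paste0)))
    ids <- c(ids, session_ids)
  }
  nodes <- setNames(lapply(ids, function(id) {
    annotator_node(id, rep(0, classes), rep(0, classes))
  }), ids)
  structure(list(nodes = nodes, readers = as.integer(readers),
                 sessions = as.integer(sessions), classes = as.integer(classes),
                 root_id = root_id, reader_ids = reader_ids,
                 session_ids = session_ids),
            class = "sij_consensus_tree")
}

#' @export
print.sij_consensus_tree <- function(x, ...) {
  cat(sprintf("<sij_consensus_tree R=%d S=%d nodes=%d>\n",
              x$readers, x$sessions, length(x$nodes)))
  invisible(x)
}

session_parent <- function(id) sub("S[0-9]+$", "", id)

#' Branch a prediction through the consensus tree
#'
#' The base prediction is transformed by the root (inter-consensus) matrix,
#' then by each reader's matrix, then by each session's matrix, populating
#' every node of the tree.
#'
#' @param p Base prediction on the simplex.
#' @param tree A [consensus_tree()].
#' @return A `sij_bundle`: `base` plus one prediction per node.
#' @export
branch_predictions <- function(p, tree) {
  preds <- list()
  preds[[tree$root_id]] <- apply_annotator(tree$nodes[[tree$root_id]], p)
  for (r in tree$reader_ids) {
    preds[[r]] <- apply_annotator(tree$nodes[[r]], preds[[tree$root_id]])
  }
  for (s in tree$session_ids) {
    preds[[s]] <- apply_annotator(tree$nodes[[s]], preds[[session_parent(s)]])
  }
  structure(list(base = p, nodes = preds, root_id = tree$root_id),
            class = "sij_bundle")
}

#' Root-node (inter-consensus) prediction
#'
#' The root prediction is the model's best estimate when compared against
#' inter-reader consensus labels.
#' @param bundle A `sij_bundle` from [branch_predictions()].
#' @export
consensus_inference <- function(bundle) bundle$nodes[[bundle$root_id]]

#' Consensus labels from a multi-reader label table
#'
#' Intra-reader consensus exists where a reader agrees with themselves over
#' all read sessions; inter-reader consensus exists where both (all) readers
#' agree at all sessions. Disagreement or a missing session yields a missing
#' consensus, never a majority vote.
#'
#' @param labels Tibble with columns `sample_id`, `task_id`, `reader`
#'   (integer), `session` (integer), `label` (0/1, `NA` = missing).
#' @param readers,sessions Expected counts; defaults are inferred from the
#'   table.
#' @return A `sij_label_table`: list of tibbles `raw`, `intra`
#'   (`sample_id, task_id, reader, label`) and `inter`
#'   (`sample_id, task_id, label`), with `NA` labels marking missing
#'   consensus.
#' @export
compute_consensus <- function(labels, readers = NULL, sessions = NULL) {
  need <- c("sample_id", "task_id", "reader", "session", "label")
  if (!all(need %in% names(labels))) {
    abort(paste("label table needs columns:", paste(need, collapse = ", ")))
  }
  readers <- readers %||% length(unique(labels$reader))
  sessions <- sessions %||% length(unique(labels$session))
  cons <- function(x, n) {
    x <- x[!is.na(x)]
    if (length(x) == n && length(unique(x)) == 1L) x[1] else NA_real_
  }
  intra <- labels |>
    dplyr::group_by(.data$sample_id, .data$task_id, .data$reader) |>
    dplyr::summarise(label = cons(.data$label, sessions), .groups = "drop")
  inter <- labels |>
    dplyr::group_by(.data$sample_id, .data$task_id) |>
    dplyr::summarise(label = cons(.data$label, readers * sessions),
                     .groups = "drop")
  structure(list(raw = labels, intra = intra, inter = inter,
                 readers = readers, sessions = sessions),
            class = "sij_label_table")
}

#' Hierarchical multi-reader loss for one sample and task
#'
#' Cross-entropy is accumulated at every node that has a label available:
#' session nodes against the raw per-session labels, reader nodes against
#' the reader's intra-consensus label (when it exists), and the root against
#' the inter-consensus label (when it exists). The regulariser is the sum of
#' the traces of all annotator matrices; `total = ce + lambda * trace`.
#'
#' @param bundle A `sij_bundle` for this sample-task.
#' @param labels Raw label rows (tibble as in [compute_consensus()]) for a
#'   single sample and task.
#' @param tree The [consensus_tree()] whose nodes produced the bundle.
#' @param lambda Trace regulariser weight.
#' @return A `sij_loss_report`: `total`, `ce`, `trace`, `per_node` tibble,
#'   and `no_labels` flag.
#' @export
multireader_loss <- function(bundle, labels, tree, lambda = 1) {
  ct <- compute_consensus(labels, tree$readers, tree$sessions)
  per <- list()
  add <- function(id, y) {
    if (is.na(y)) return()
    q <- bundle$nodes[[id]]
    per[[length(per) + 1L]] <<- tibble(node = id, label = y,
                                       ce = -log(q[y + 1L]))
  }
  add(tree$root_id, if (nrow(ct$inter)) ct$inter$label[1] else NA_real_)
  for (r in seq_len(tree$readers)) {
    row <- ct$intra[ct$intra$reader == r, ]
    add(tree$reader_ids[r], if (nrow(row)) row$label[1] else NA_real_)
  }
  for (id in tree$session_ids) {
    m <- regmatches(id, regexec("^R([0-9]+)S([0-9]+)$", id))[[1]]
    row <- labels[labels$reader == as.integer(m[2]) &
                    labels$session == as.integer(m[3]), ]
    add(id, if (nrow(row) && !is.na(row$label[1])) row$label[1] else NA_real_)
  }
  per_node <- if (length(per)) dplyr::bind_rows(per) else
    tibble(node = character(), label = numeric(), ce = numeric())
  tr <- sum(vapply(tree$nodes, annotator_trace, numeric(1)))
  ce <- sum(per_node$ce)
  structure(list(total = ce + lambda * tr, ce = ce, trace = tr,
                 per_node = per_node, no_labels = nrow(per_node) == 0L),
            class = "sij_loss_report")
}

# ---- vectorised tree machinery (training) ---------------------------------

# Forward one node over an n x C matrix of parent predictions.
mr_node_forward <- function(P, node, eps = 1e-6) {
  B <- diag(ncol(P)) + annotator_matrix(node)
  Z <- P %*% t(B)
  Zc <- pmax(Z, eps)
  S <- rowSums(Zc)
  list(Q = Zc / S, Z = Z, Zc = Zc, S = S, P = P, B = B)
}

# Backward: dQ (n x C) -> gradient wrt parent P and node raw parameters.
mr_node_backward <- function(cache, dQ, node) {
  Q <- cache$Q
  dZc <- (dQ - rowSums(dQ * Q)) / cache$S
  dZ <- dZc * (cache$Z > 1e-6)
  dP <- dZ %*% cache$B
  dB <- t(dZ) %*% cache$P
  a <- node_a(node); b <- node_b(node)
  da <- as.numeric(dB %*% b)
  db <- as.numeric(t(dB) %*% a)
  list(dP = dP,
       da_raw = da * 0.5 * (1 - tanh(node$a_raw)^2),
       db_raw = db * 0.5 * (1 - tanh(node$b_raw)^2))
}

# Full-tree forward for an n x C base prediction matrix.
mr_tree_forward <- function(P, tree) {
  caches <- list()
  caches[[tree$root_id]] <- mr_node_forward(P, tree$nodes[[tree$root_id]])
  for (r in tree$reader_ids) {
    caches[[r]] <- mr_node_forward(caches[[tree$root_id]]$Q, tree$nodes[[r]])
  }
  for (s in tree$session_ids) {
    caches[[s]] <- mr_node_forward(caches[[session_parent(s)]]$Q,
                                   tree$nodes[[s]])
  }
  caches
}

# Per-node CE gradients dQ from label vectors (NA = missing), averaged over
# n_eff samples; returns total CE and the dQ list.
mr_ce_grads <- function(caches, node_labels, n_eff) {
  ce <- 0
  dQs <- list()
  for (id in names(node_labels)) {
    y <- node_labels[[id]]
    Q <- caches[[id]]$Q
    dQ <- matrix(0, nrow(Q), ncol(Q))
    ok <- which(!is.na(y))
    if (length(ok)) {
      idx <- cbind(ok, y[ok] + 1L)
      ce <- ce + sum(-log(Q[idx])) / n_eff
      dQ[idx] <- -1 / Q[idx] / n_eff
    }
    dQs[[id]] <- dQ
  }
  list(ce = ce, dQs = dQs)
}

# Backward through the whole tree; returns dP for the base prediction and
# per-node raw-parameter gradients (trace term included with weight lambda).
mr_tree_backward <- function(caches, dQs, tree, lambda = 1) {
  g <- list()
  acc <- function(dQ, id) {
    bw <- mr_node_backward(caches[[id]], dQ, tree$nodes[[id]])
    a_raw <- tree$nodes[[id]]$a_raw; b_raw <- tree$nodes[[id]]$b_raw
    # d(lambda * tr(A))/da_raw = lambda * b * 0.5 (1 - tanh^2)
    g[[id]] <<- list(
      da_raw = bw$da_raw + lambda * node_b(tree$nodes[[id]]) *
        0.5 * (1 - tanh(a_raw)^2),
      db_raw = bw$db_raw + lambda * node_a(tree$nodes[[id]]) *
        0.5 * (1 - tanh(b_raw)^2))
    bw$dP
  }
  dreader <- list()
  for (r in tree$reader_ids) dreader[[r]] <- dQs[[r]] %||% 0
  for (s in tree$session_ids) {
    dP <- acc(dQs[[s]], s)
    pr <- session_parent(s)
    dreader[[pr]] <- dreader[[pr]] + dP
  }
  droot <- dQs[[tree$root_id]] %||% 0
  for (r in tree$reader_ids) droot <- droot + acc(dreader[[r]], r)
  dP_base <- acc(droot, tree$root_id)
  list(dP = dP_base, node_grads = g)
}

# Node labels (named list of per-sample vectors, NA = missing) from a label
# table restricted to one task, aligned to sample_ids.
mr_node_labels <- function(label_table, tree, sample_ids) {
  out <- list()
  inter <- label_table$inter
  out[[tree$root_id]] <- inter$label[match(sample_ids, inter$sample_id)]
  for (r in seq_len(tree$readers)) {
    ri <- label_table$intra[label_table$intra$reader == r, ]
    out[[tree$reader_ids[r]]] <- ri$label[match(sample_ids, ri$sample_id)]
  }
  raw <- label_table$raw
  for (s in tree$session_ids) {
    m <- regmatches(s, regexec("^R([0-9]+)S([0-9]+)$", s))[[1]]
    rs <- raw[raw$reader == as.integer(m[2]) & raw$session == as.integer(m[3]), ]
    out[[s]] <- rs$label[match(sample_ids, rs$sample_id)]
  }
  lapply(out, function(v) { storage.mode(v) <- "integer"; v })
}

sum_trace <- function(tree) sum(vapply(tree$nodes, annotator_trace, numeric(1)))

# apply Adam-style update to tree node parameters given gradient list
tree_adam_step <- function(tree, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (id in names(grads)) {
    for (slot in c("a_raw", "b_raw")) {
      gname <- paste0("d", slot)
      g <- grads[[id]][[gname]]
      state$m[[id]][[slot]] <- beta1 * state$m[[id]][[slot]] + (1 - beta1) * g
      state$v[[id]][[slot]] <- beta2 * state$v[[id]][[slot]] + (1 - beta2) * g^2
      tree$nodes[[id]][[slot]] <- tree$nodes[[id]][[slot]] -
        lr * (state$m[[id]][[slot]] / c1) / (sqrt(state$v[[id]][[slot]] / c2) + eps)
    }
  }
  list(tree = tree, state = state)
}

# Break the saddle at a = b = 0 (where all rank-1 gradients vanish) with a
# small random initialisation of every node's raw vectors; uses the current
# RNG state.
tree_jitter <- function(tree, sd = 0.1) {
  for (id in names(tree$nodes)) {
    tree$nodes[[id]]$a_raw <- rnorm(tree$classes, sd = sd)
    tree$nodes[[id]]$b_raw <- rnorm(tree$classes, sd = sd)
  }
  tree
}

tree_adam_init <- function(tree) {
  zeros <- lapply(tree$nodes, function(n) {
    list(a_raw = 0 * n$a_raw, b_raw = 0 * n$b_raw)
  })
  list(t = 0L, m = zeros, v = zeros)
}

#' Fit a multi-reader model with a logistic base learner
#'
#' A compact fitting routine for studying the annotator machinery on
#' tabular features: the base prediction is a logistic regression on `x`,
#' branched through the consensus tree, and all parameters (weights plus
#' every node's rank-1 vectors) are optimised jointly by full-batch Adam on
#' mean cross-entropy at the labelled nodes plus `lambda` times the summed
#' annotator traces.
#'
#' @param x Numeric feature matrix (n x d).
#' @param labels Raw label table covering one task
#'   (columns as in [compute_consensus()]).
#' @param tree A [consensus_tree()].
#' @param lambda Trace regulariser weight.
#' @param steps,lr Adam steps and learning rate.
#' @param seed RNG seed for initialisation.
#' @return A `sij_mr_fit` with the fitted tree, weights and history.
#' @export
fit_multireader_glm <- function(x, labels, tree, lambda = 1, steps = 1500L,
                                lr = 0.05, seed = 1L) {
  x <- as.matrix(x)
  set.seed(seed)
  tree <- tree_jitter(tree)
  sample_ids <- sort(unique(labels$sample_id))
  n <- length(sample_ids)
  if (nrow(x) != n) abort("`x` rows must match the distinct sample_ids")
  lt <- compute_consensus(labels, tree$readers, tree$sessions)
  node_labels <- mr_node_labels(lt, tree, sample_ids)
  w <- rnorm(ncol(x), sd = 0.1); b0 <- 0
  mw <- 0 * w; vw <- 0 * w; mb <- 0; vb <- 0
  tstate <- tree_adam_init(tree)
  hist <- numeric(steps)
  for (step in seq_len(steps)) {
    z <- as.numeric(x %*% w) + b0
    p1 <- 1 / (1 + exp(-z))
    P <- cbind(1 - p1, p1)
    caches <- mr_tree_forward(P, tree)
    cg <- mr_ce_grads(caches, node_labels, n_eff = n)
    # objective: (summed CE + lambda * trace) / n  — the trace enters once
    # for the whole sample, not once per observation
    hist[step] <- cg$ce + lambda / n * sum_trace(tree)
    bw <- mr_tree_backward(caches, cg$dQs, tree, lambda / n)
    node_g <- bw$node_grads
    dPbase <- bw$dP
    # logistic head gradient
    dz <- (dPbase[, 2] - dPbase[, 1]) * p1 * (1 - p1)
    gw <- as.numeric(t(x) %*% dz); gb <- sum(dz)
    mw <- 0.9 * mw + 0.1 * gw; vw <- 0.999 * vw + 0.001 * gw^2
    mb <- 0.9 * mb + 0.1 * gb; vb <- 0.999 * vb + 0.001 * gb^2
    c1 <- 1 - 0.9^step; c2 <- 1 - 0.999^step
    w <- w - lr * (mw / c1) / (sqrt(vw / c2) + 1e-8)
    b0 <- b0 - lr * (mb / c1) / (sqrt(vb / c2) + 1e-8)
    upd <- tree_adam_step(tree, node_g, tstate, lr)
    tree <- upd$tree; tstate <- upd$state
  }
  structure(list(tree = tree, w = w, b = b0, sample_ids = sample_ids,
                 lambda = lambda,
                 history = tibble(step = seq_len(steps), loss = hist)),
            class = "sij_mr_fit")
}

#' @rdname fit_multireader_glm
#' @param fit A `sij_mr_fit`.
#' @param newdata Feature matrix.
#' @return `predict_multireader()`: list of per-node n x 2 probability
#'   matrices plus `base`.
#' @export
predict_multireader <- function(fit, newdata) {
  z <- as.numeric(as.matrix(newdata) %*% fit$w) + fit$b
  p1 <- 1 / (1 + exp(-z))
  P <- cbind(1 - p1, p1)
  caches <- mr_tree_forward(P, fit$tree)
  c(list(base = P), lapply(caches, function(cc) cc$Q))
}

#' Session-node disagreement with the root prediction
#'
#' For each session node, the mean probability mass the node assigns
#' against the root node's predicted class. On synthetic data with known
#' per-reader flip rates, a well-fitted model's session disagreement rates
#' recover those rates.
#'
#' @param fit A `sij_mr_fit`.
#' @param newdata Feature matrix.
#' @return Tibble with `node` and `disagreement`.
#' @export
node_disagreement <- function(fit, newdata) {
  preds <- predict_multireader(fit, newdata)
  root <- preds[[fit$tree$root_id]]
  cls <- max.col(root)
  rows <- lapply(fit$tree$session_ids, function(id) {
    Q <- preds[[id]]
    tibble(node = id,
           disagreement = mean(1 - Q[cbind(seq_len(nrow(Q)), cls)]))
  })
  dplyr::bind_rows(rows)
}
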