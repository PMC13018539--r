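test_that("rank-1 matrices are outer products", {
  expect_equal(rank1_matrix(c(1, 0), c(0, 1)),
               matrix(c(0, 0, 1, 0), 2, 2))
  expect_equal(rank1_matrix(c(0, 0), c(0.3, -0.2)), matrix(0, 2, 2))
  set.seed(3)
  for (rep in 1:100) {
    a <- rnorm(2); b <- rnorm(2)
    ref <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) ref[i, j] <- a[i] * b[j]
    expect_equal(rank1_matrix(a, b), ref)
  }
  expect_error(rank1_matrix(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("the trace of a rank-1 matrix is the dot product", {
  set.seed(5)
  for (rep in 1:50) {
    a <- rnorm(2); b <- rnorm(2)
    expect_equal(sum(diag(rank1_matrix(a, b))), sum(a * b))
  }
})

test_that("applying an annotator is (I + A) p with clamping", {
  id <- annotator_node("R1")
  expect_equal(apply_annotator(id, c(0.3, 0.7)), c(0.3, 0.7))
  # raw vectors chosen so a = (0.2, -0.2), b = (0.4, -0.4)
  nd <- annotator_node("R1", atanh(c(0.4, -0.4)), atanh(c(0.8, -0.8)))
  # rows of A sum to zero here, so the uniform vector is unchanged
  expect_equal(apply_annotator(nd, c(0.5, 0.5)), c(0.5, 0.5))
  expect_error(apply_annotator(id, c(0.6, 0.6)), "simplex")
  set.seed(7)
  for (rep in 1:100) {
    nd <- annotator_node("x", rnorm(2, sd = 0.5), rnorm(2, sd = 0.5))
    p <- runif(2); p <- p / sum(p)
    B <- diag(2) + annotator_matrix(nd)
    q <- pmax(as.numeric(B %*% p), 1e-6); q <- q / sum(q)
    expect_equal(apply_annotator(nd, p), q)
  }
})

test_that("the two-reader three-session tree has the canonical node set", {
  tree <- consensus_tree(2, 3)
  expect_setequal(names(tree$nodes),
                  c("R1S1", "R1S2", "R1S3", "R2S1", "R2S2", "R2S3",
                    "R1", "R2", "R1R2"))
  surpass <- consensus_tree(3, 1)
  expect_setequal(names(surpass$nodes), c("R1R2R3", "R1", "R2", "R3"))
})

test_that("branching populates every node; identity tree passes p through", {
  tree <- consensus_tree(2, 3)
  p <- c(0.2, 0.8)
  bundle <- branch_predictions(p, tree)
  expect_length(bundle$nodes, 9L)
  for (q in bundle$nodes) expect_equal(q, p)
  expect_equal(consensus_inference(bundle), p)
})

test_that("session predictions compose root, reader and session matrices", {
  set.seed(11)
  tree <- consensus_tree(2, 3)
  for (id in names(tree$nodes)) {
    tree$nodes[[id]] <- annotator_node(id, rnorm(2, sd = 0.3),
                                       rnorm(2, sd = 0.3))
  }
  p <- c(0.35, 0.65)
  bundle <- branch_predictions(p, tree)
  longhand <- apply_annotator(tree$nodes[["R1S2"]],
                              apply_annotator(tree$nodes[["R1"]],
                                              apply_annotator(tree$nodes[["R1R2"]], p)))
  expect_equal(bundle$nodes[["R1S2"]], longhand)
  # simplex conservation at every node
  for (q in bundle$nodes) {
    expect_true(all(q >= 0))
    expect_equal(sum(q), 1, tolerance = 1e-6)
  }
})

test_that("consensus labels require unanimity", {
  lab <- function(r, s, v) tibble::tibble(sample_id = "a", task_id = "t",
                                          reader = r, session = s, label = v)
  tb <- dplyr::bind_rows(lab(1, 1, 1), lab(1, 2, 1), lab(1, 3, 1),
                         lab(2, 1, 1), lab(2, 2, 1), lab(2, 3, 1))
  ct <- compute_consensus(tb)
  expect_equal(ct$inter$label, 1)
  tb2 <- tb; tb2$label[2] <- 0  # reader 1 disagrees with themselves
  ct2 <- compute_consensus(tb2)
  expect_true(is.na(ct2$intra$label[ct2$intra$reader == 1]))
  expect_equal(ct2$intra$label[ct2$intra$reader == 2], 1)
  expect_true(is.na(ct2$inter$label))
})

test_that("consensus matches an exhaustive all-equal scan on random tables", {
  set.seed(13)
  for (rep in 1:25) {
    n <- 40
    tb <- tidyr::expand_grid(sample_id = sprintf("s%02d", 1:n),
                             task_id = "t", reader = 1:2, session = 1:3)
    tb$label <- sample(c(0, 1, NA), nrow(tb), replace = TRUE,
                       prob = c(0.45, 0.45, 0.1))
    ct <- compute_consensus(tb)
    for (sid in unique(tb$sample_id)) {
      sub <- tb[tb$sample_id == sid, ]
      for (r in 1:2) {
        v <- sub$label[sub$reader == r]
        want <- if (!anyNA(v) && length(unique(v)) == 1L) v[1] else NA_real_
        got <- ct$intra$label[ct$intra$sample_id == sid & ct$intra$reader == r]
        expect_identical(got, want)
      }
      v <- sub$label
      want <- if (!anyNA(v) && length(unique(v)) == 1L) v[1] else NA_real_
      expect_identical(ct$inter$label[ct$inter$sample_id == sid], want)
    }
  }
})

test_that("adding a disagreeing session only degrades consensus to missing", {
  set.seed(17)
  for (rep in 1:50) {
    base <- tidyr::expand_grid(sample_id = "a", task_id = "t",
                               reader = 1:2, session = 1:2)
    base$label <- sample(0:1, nrow(base), replace = TRUE)
    extra <- tibble::tibble(sample_id = "a", task_id = "t", reader = 1:2,
                            session = 3, label = sample(0:1, 2, replace = TRUE))
    before <- compute_consensus(base, sessions = 2)
    after <- compute_consensus(dplyr::bind_rows(base, extra), sessions = 3)
    for (r in 1:2) {
      b <- before$intra$label[before$intra$reader == r]
      a <- after$intra$label[after$intra$reader == r]
      expect_true(is.na(a) || (!is.na(b) && a == b))
    }
  }
})

test_that("the loss reduces to plain cross-entropy with identity annotators", {
  tree <- consensus_tree(2, 3)
  p <- c(0.8, 0.2)
  bundle <- branch_predictions(p, tree)
  lab <- tidyr::expand_grid(sample_id = "a", task_id = "t", reader = 1:2,
                            session = 1:3)
  lab$label <- 0
  rep <- multireader_loss(bundle, lab, tree, lambda = 1)
  # 6 session nodes + 2 intra + 1 inter, all labelled 0, all predict p
  expect_equal(rep$trace, 0)
  expect_equal(rep$ce, 9 * -log(0.8), tolerance = 1e-10)
  expect_equal(rep$total, rep$ce, tolerance = 1e-12)
  expect_equal(nrow(rep$per_node), 9L)
})

test_that("trace term and hand-computed CE enter the loss as stated", {
  tree <- consensus_tree(2, 3)
  tree$nodes[["R1"]] <- annotator_node("R1", atanh(c(0.2, 0)),
                                       atanh(c(0.8, 0)))
  # a = (0.1, 0), b = (0.4, 0) -> tr(A) = a . b = 0.04
  expect_equal(annotator_trace(tree$nodes[["R1"]]), 0.04)
  p <- c(0.8, 0.2)
  bundle <- branch_predictions(p, tree)
  lab <- tibble::tibble(sample_id = "a", task_id = "t", reader = 1,
                        session = 1, label = 0)
  rep <- multireader_loss(bundle, lab, tree, lambda = 2)
  expect_equal(rep$total, rep$ce + 2 * 0.04)
  # only the R1S1 node carries a label (consensus undefined with 1 session
  # of 3 present)
  expect_equal(rep$per_node$node, "R1S1")
  expect_equal(rep$per_node$ce, -log(bundle$nodes[["R1S1"]][1]))
})

test_that("a sample without any labels is flagged, not an error", {
  tree <- consensus_tree(2, 3)
  bundle <- branch_predictions(c(0.5, 0.5), tree)
  lab <- tibble::tibble(sample_id = "a", task_id = "t", reader = 1,
                        session = 1, label = NA_real_)
  rep <- multireader_loss(bundle, lab, tree)
  expect_true(rep$no_labels)
  expect_equal(rep$ce, 0)
})

test_that("vectorised tree gradients match finite differences", {
  set.seed(23)
  tree <- consensus_tree(2, 2)
  tree <- sijmri:::tree_jitter(tree, sd = 0.2)
  n <- 6
  P <- matrix(runif(2 * n), n, 2); P <- P / rowSums(P)
  labels <- lapply(setNames(nm = names(tree$nodes)), function(id) {
    sample(c(0L, 1L, NA), n, replace = TRUE)
  })
  lambda <- 0.7
  loss_of <- function(tree, P) {
    caches <- sijmri:::mr_tree_forward(P, tree)
    ce <- 0
    for (id in names(labels)) {
      y <- labels[[id]]; ok <- !is.na(y)
      ce <- ce + sum(-log(caches[[id]]$Q[cbind(which(ok), y[ok] + 1L)])) / n
    }
    ce + lambda * sijmri:::sum_trace(tree)
  }
  caches <- sijmri:::mr_tree_forward(P, tree)
  cg <- sijmri:::mr_ce_grads(caches, labels, n_eff = n)
  bw <- sijmri:::mr_tree_backward(caches, cg$dQs, tree, lambda)
  eps <- 1e-6
  for (id in names(tree$nodes)) {
    for (slot in c("a_raw", "b_raw")) {
      for (i in 1:2) {
        t2 <- tree; t2$nodes[[id]][[slot]][i] <-
          t2$nodes[[id]][[slot]][i] + eps
        t3 <- tree; t3$nodes[[id]][[slot]][i] <-
          t3$nodes[[id]][[slot]][i] - eps
        num <- (loss_of(t2, P) - loss_of(t3, P)) / (2 * eps)
        ana <- bw$node_grads[[id]][[paste0("d", slot)]][i]
        expect_equal(ana, num, tolerance = 1e-5)
      }
    }
  }
  # gradient wrt the base prediction matrix (probe a few entries, renormalise
  # not applied: probe along directions that keep rows on the simplex)
  for (i in 1:3) {
    dP <- matrix(0, n, 2); dP[i, ] <- c(eps, -eps)
    num <- (loss_of(tree, P + dP) - loss_of(tree, P - dP)) / (2 * eps)
    ana <- bw$dP[i, 1] - bw$dP[i, 2]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})
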