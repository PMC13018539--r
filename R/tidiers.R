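#' Tidiers for fitted pipeline objects
#'
#' `tidy()` returns per-component parameter summaries; `glance()` returns a
#' one-row model summary, in the broom idiom.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name sijmri-tidiers
NULL

#' @rdname sijmri-tidiers
#' @export
tidy.sij_delineator <- function(x, ...) x$history

#' @rdname sijmri-tidiers
#' @export
glance.sij_delineator <- function(x, ...) {
  tibble(mode = x$config$mode, input_size = x$config$input_size,
         depth = x$config$depth, width = x$config$width,
         steps = nrow(x$history),
         final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)]
         else NA_real_)
}

# one row per annotator node of one tree
tree_tidy <- function(tree, task_id = NA_character_) {
  dplyr::bind_rows(lapply(tree$nodes, function(nd) {
    a <- node_a(nd); b <- node_b(nd)
    tibble(task_id = task_id, node = nd$node_id, trace = sum(a * b),
           flip_01 = rank1_matrix(a, b)[2, 1],
           flip_10 = rank1_matrix(a, b)[1, 2])
  }))
}

#' @rdname sijmri-tidiers
#' @export
tidy.sij_classifier <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$trees), function(tid) {
    tree_tidy(x$trees[[tid]], tid)
  }))
}

#' @rdname sijmri-tidiers
#' @export
glance.sij_classifier <- function(x, ...) {
  tibble(tasks = nrow(x$tasks), input_size = x$config$input_size,
         depth = x$config$depth, steps = nrow(x$history),
         final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)]
         else NA_real_)
}

#' @rdname sijmri-tidiers
#' @export
tidy.sij_mr_fit <- function(x, ...) tree_tidy(x$tree)

#' @rdname sijmri-tidiers
#' @export
glance.sij_mr_fit <- function(x, ...) {
  tibble(steps = nrow(x$history),
         final_loss = x$history$loss[nrow(x$history)],
         lambda = x$lambda, readers = x$tree$readers,
         sessions = x$tree$sessions)
}
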