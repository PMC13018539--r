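#' Read and write image volumes
#'
#' Volumes travel as NIfTI (via the RNifti package); the in-plane pixel
#' spacing is taken from the header and defaults to 1 mm/px with a warning
#' when missing or non-positive. Slices are the third array dimension.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return A `sij_volume`: list with `data` (`H x W x n_slices`), `spacing`
#'   (mm/px), `sequence`, `patient_id`, `scan_id`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  img <- RNifti::readNifti(path)
  data <- unclass(img)
  if (length(dim(data)) == 2L) data <- array(data, c(dim(data), 1L))
  if (length(dim(data)) != 3L) abort("expected a 2D or 3D volume")
  pd <- RNifti::pixdim(img)
  spacing <- if (length(pd) >= 1L) pd[[1]] else NA_real_
  if (!is.finite(spacing) || spacing <= 0) {
    warn("pixel spacing missing; defaulting to 1 mm/px")
    spacing <- 1
  }
  structure(list(data = data, spacing = spacing,
                 sequence = "other",
                 patient_id = NA_character_, scan_id = NA_character_),
            class = "sij_volume")
}

#' @rdname read_volume
#' @param volume A `sij_volume` or plain array.
#' @param spacing In-plane spacing written to the header.
#' @export
write_volume <- function(volume, path, spacing = NULL) {
  data <- if (inherits(volume, "sij_volume")) volume$data else volume
  spacing <- spacing %||%
    (if (inherits(volume, "sij_volume")) volume$spacing else 1)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- rep(spacing, length(dim(data)))
  tmp <- paste0(path, ".tmp")
  RNifti::writeNifti(img, tmp)
  written <- if (file.exists(tmp)) tmp else {
    # writeNifti appends .nii.gz when the extension is unrecognised
    cand <- paste0(tmp, c(".nii.gz", ".nii"))
    cand[file.exists(cand)][1]
  }
  file.rename(written, path)  # atomic publish
  invisible(path)
}

#' Read and write contour annotations
#'
#' Annotations are JSON: per slice, per side, a list of `[x, y]` vertex
#' pairs in 0-based pixels, plus the in-plane spacing. The schema is
#' validated on read (sides `left`/`right`, 2 to 21 vertices per present
#' contour); writes are canonical (sorted keys, fixed precision) so files
#' diff cleanly.
#'
#' @param path JSON file path.
#' @return A list with `spacing` and `contours` (tibble `slice`, `side`,
#'   `present`, `contour`).
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$slices)) abort("annotation schema: missing field `slices`")
  spacing <- raw$spacing %||% 1
  rows <- list()
  for (i in seq_along(raw$slices)) {
    sl <- raw$slices[[i]]
    for (sd in names(sl)) {
      if (!sd %in% c("left", "right")) {
        abort(sprintf("annotation schema: invalid side `%s` (slice %d)", sd, i))
      }
      v <- sl[[sd]]
      if (length(v) == 0L) {
        rows[[length(rows) + 1L]] <- tibble(slice = i, side = sd,
                                            present = FALSE,
                                            contour = list(absent_polyline(sd)))
        next
      }
      if (length(v) < 2L || length(v) > 21L) {
        abort(sprintf(
          "annotation schema: side `%s` of slice %d has %d vertices (allowed: 2-21)",
          sd, i, length(v)))
      }
      x <- vapply(v, function(p) as.numeric(p[[1]]), numeric(1))
      y <- vapply(v, function(p) as.numeric(p[[2]]), numeric(1))
      rows[[length(rows) + 1L]] <- tibble(slice = i, side = sd, present = TRUE,
                                          contour = list(polyline(x, y, sd)))
    }
  }
  list(spacing = spacing, contours = dplyr::bind_rows(rows))
}

#' @rdname read_annotations
#' @param contours Contour tibble (`slice`, `side`, `present`, `contour`).
#' @param spacing In-plane spacing in mm/px.
#' @export
write_annotations <- function(contours, path, spacing = 1) {
  n_slices <- max(contours$slice)
  slices <- lapply(seq_len(n_slices), function(s) {
    out <- list()
    for (sd in c("left", "right")) {
      row <- contours[contours$slice == s & contours$side == sd, ]
      if (nrow(row) == 0L) next
      p <- row$contour[[1]]
      out[[sd]] <- if (p$present) {
        lapply(seq_along(p$x), function(k) c(round(p$x[k], 4), round(p$y[k], 4)))
      } else list()
    }
    out[sort(names(out))]
  })
  payload <- list(spacing = spacing, slices = slices)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  tmp <- paste0(path, ".tmp")
  writeLines(json, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read and write multi-reader label tables
#'
#' CSV with columns `sample_id`, `task_id`, `reader`, `session`, `label`;
#' missing labels are the literal token `missing`.
#'
#' @param path CSV file path.
#' @export
read_label_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(), task_id = readr::col_character(),
    reader = readr::col_integer(), session = readr::col_integer(),
    label = readr::col_character()))
  df$label <- as.numeric(ifelse(df$label == "missing", NA_character_,
                                df$label))
  df
}

#' @rdname read_label_table
#' @param labels Raw label tibble.
#' @export
write_label_table <- function(labels, path) {
  out <- labels
  out$label <- ifelse(is.na(out$label), "missing", format(out$label))
  tmp <- paste0(path, ".tmp")
  readr::write_csv(out, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run configuration files
#'
#' YAML round-trip of the nested stage configuration (delineator, walker,
#' classifier, trees, seeds, paths).
#' @param path YAML file path.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config Named list.
#' @export
write_run_config <- function(config, path) {
  tmp <- paste0(path, ".tmp")
  yaml::write_yaml(config, tmp)
  file.rename(tmp, path)
  invisible(path)
}
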