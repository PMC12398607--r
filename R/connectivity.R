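#' Canonical fronto-basal-ganglia-motor tract pairs
#'
#' The fixed list of 19 region pairs whose streamline counts are extracted
#' from each subject's averaged connectivity matrix: SMA and OFC projections
#' to M1 and to the five basal-ganglia nuclei, the BG-pallidal connections,
#' and the pallido-thalamo-cortical limb.
#'
#' @return Tibble with columns `region_a`, `region_b`, `feature`
#'   (the `A_B` column name used downstream), in the fixed reporting order.
#' @export
tract_pairs <- function() {
  pairs <- list(
    c("SMA", "M1"), c("SMA", "dCaudate"), c("SMA", "vCaudate"),
    c("SMA", "dlPutamen"), c("SMA", "vmPutamen"), c("SMA", "NAcc"),
    c("OFC", "M1"), c("OFC", "dCaudate"), c("OFC", "vCaudate"),
    c("OFC", "dlPutamen"), c("OFC", "vmPutamen"), c("OFC", "NAcc"),
    c("dCaudate", "GP"), c("vCaudate", "GP"), c("dlPutamen", "GP"),
    c("vmPutamen", "GP"), c("NAcc", "GP"), c("GP", "Thalamus"),
    c("Thalamus", "M1")
  )
  tibble(
    region_a = vapply(pairs, `[`, character(1), 1L),
    region_b = vapply(pairs, `[`, character(1), 2L)
  ) %>%
    mutate(feature = paste(.data$region_a, .data$region_b, sep = "_"))
}

#' The nine atlas regions spanned by the canonical tract pairs
#' @return Character vector of region labels.
#' @export
tract_regions <- function() {
  unique(c(tract_pairs()$region_a, tract_pairs()$region_b))
}

check_conn_matrix <- function(m, label = "matrix", tol = 0) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(paste0(label, " is not a square matrix"))
  }
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    abort(paste0(label, " must have identical row/column region labels"))
  }
  if (any(m < -tol)) abort(paste0(label, " has negative entries"))
  if (max(abs(m - t(m))) > tol) abort(paste0(label, " is not symmetric"))
  if (any(abs(diag(m)) > tol)) abort(paste0(label, " has a non-zero diagonal"))
  invisible(TRUE)
}

#' Average a stack of per-iteration connectivity matrices
#'
#' Entrywise arithmetic mean over tractography iterations; validates that
#' every matrix is square, symmetric, non-negative, zero-diagonal and shares
#' the same region labels.
#'
#' @param stack List of labelled square numeric matrices (one per iteration).
#' @return The mean matrix (same labels; symmetric, zero diagonal).
#' @export
average_connectivity <- function(stack) {
  if (length(stack) < 1L) abort("empty connectivity stack")
  labs <- rownames(stack[[1L]])
  for (k in seq_along(stack)) {
    check_conn_matrix(stack[[k]], label = paste0("iteration ", k))
    if (!identical(rownames(stack[[k]]), labs)) {
      abort(paste0("iteration ", k, " has mismatched region labels"))
    }
  }
  Reduce(`+`, stack) / length(stack)
}

#' Extract named tract-pair streamline counts from a mean matrix
#'
#' Label-based, orientation-insensitive lookup of each pair in `pairs`
#' (`(A, B)` reads the same entry as `(B, A)` in a symmetric matrix).
#'
#' @param mean_matrix Labelled square symmetric matrix (see
#'   [average_connectivity()]).
#' @param pairs Tibble of pairs as from [tract_pairs()] (the default).
#' @return Named numeric vector of length `nrow(pairs)`, in pair order.
#' @export
extract_tract_features <- function(mean_matrix, pairs = tract_pairs()) {
  check_conn_matrix(mean_matrix, label = "mean matrix", tol = 1e-8)
  labs <- rownames(mean_matrix)
  need <- unique(c(pairs$region_a, pairs$region_b))
  miss <- setdiff(need, labs)
  if (length(miss) > 0) {
    abort(paste0("regions missing from matrix labels: ",
                 paste(miss, collapse = ", ")))
  }
  vals <- mapply(function(a, b) mean_matrix[a, b], pairs$region_a, pairs$region_b)
  setNames(as.numeric(vals), pairs$feature)
}

#' Per-subject tract features from connectivity stacks
#'
#' @param stacks Named list (by subject id) of connectivity stacks (each a
#'   list of per-iteration matrices).
#' @inheritParams extract_tract_features
#' @return Tibble: `subject_id` plus one named column per tract pair.
#' @export
compute_tract_features <- function(stacks, pairs = tract_pairs()) {
  stopifnot(length(stacks) >= 1L, !is.null(names(stacks)))
  purrr::imap_dfr(stacks, function(stack, sid) {
    feats <- extract_tract_features(average_connectivity(stack), pairs)
    dplyr::bind_cols(tibble(subject_id = sid), as_tibble(as.list(feats)))
  })
}

#' Read a connectivity stack from labelled CSV matrices
#'
#' Reads `iter_<k>.csv` files from a directory: each file a square matrix
#' with a region-label header row and first column.
#'
#' @param dir Directory containing `iter_*.csv` files for one subject.
#' @return List of labelled matrices ordered by iteration number.
#' @export
read_connectivity_stack <- function(dir) {
  files <- list.files(dir, pattern = "^iter_\\d+\\.csv$", full.names = TRUE)
  if (length(files) == 0L) abort(paste0("no iter_*.csv files in ", dir))
  ord <- order(as.integer(gsub("\\D", "", basename(files))))
  lapply(files[ord], function(f) {
    df <- readr::read_csv(f, show_col_types = FALSE)
    m <- as.matrix(df[, -1L])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "double"
    m
  })
}

#' Write a connectivity stack as labelled CSV matrices
#'
#' @param stack List of labelled matrices.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_connectivity_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(stack), function(k) {
    m <- stack[[k]]
    df <- dplyr::bind_cols(tibble(region = rownames(m)), as_tibble(m))
    p <- file.path(dir, sprintf("iter_%d.csv", k))
    readr::write_csv(df, p)
    p
  }, character(1))
  invisible(paths)
}
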