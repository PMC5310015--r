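#' Coerce a data frame or matrix to a numeric view matrix
#'
#' A *view* is one of the two sample-aligned data blocks entering the
#' analysis: an `N x d` numeric matrix with one row per sample and one named
#' column per feature. Data frames (the natural tidyverse input) are coerced;
#' non-numeric columns are rejected rather than silently dropped.
#'
#' @param x A numeric matrix or a data frame of numeric columns.
#' @param label Optional label ("x" or "z") used in error messages and kernel
#'   metadata.
#' @return A numeric matrix with column names (auto-named `f1..fd` when the
#'   input has none).
#' @export
as_view_matrix <- function(x, label = "view") {
  if (is.data.frame(x)) {
    bad <- names(x)[!vapply(x, is.numeric, logical(1))]
    if (length(bad) > 0) {
      abort(sprintf("%s: non-numeric column(s): %s", label,
                    paste(bad, collapse = ", ")))
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("%s must be a numeric matrix or data frame", label))
  }
  if (nrow(x) < 2) {
    abort(sprintf("%s needs at least 2 samples, got %d", label, nrow(x)))
  }
  if (any(!is.finite(x))) {
    abort(sprintf("%s contains missing or non-finite values", label))
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  }
  x
}

check_aligned <- function(X, Z) {
  if (nrow(X) != nrow(Z)) {
    abort(sprintf(
      "views are not sample-aligned: X has %d rows, Z has %d rows",
      nrow(X), nrow(Z)))
  }
  invisible(TRUE)
}

#' Read a view matrix from delimited text
#'
#' Expects a header row of feature names and one sample per row. An optional
#' sample-ID column can be split off and kept for alignment checks.
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` read as tab, anything else as comma).
#' @param header Does the first row hold feature names? When `FALSE`,
#'   features are auto-named `f1..fd`.
#' @param id_col Optional name of a sample-ID column.
#' @return A numeric matrix; sample IDs, if present, become row names.
#' @export
read_view <- function(path, delim = NULL, header = TRUE, id_col = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  col_names <- isTRUE(header)
  df <- readr::read_delim(path, delim = delim, col_names = col_names,
                          show_col_types = FALSE, progress = FALSE)
  if (!col_names) names(df) <- paste0("f", seq_along(df))
  if (!is.null(id_col)) {
    if (!id_col %in% names(df)) {
      abort(sprintf("%s: no column named '%s'", path, id_col))
    }
    ids <- as.character(df[[id_col]])
    df[[id_col]] <- NULL
  } else {
    ids <- NULL
  }
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("%s: non-numeric column(s): %s", path,
                  paste(bad, collapse = ", ")))
  }
  m <- as.matrix(df)
  if (!is.null(ids)) rownames(m) <- ids
  m
}
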