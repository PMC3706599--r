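#' Sample-pair map
#'
#' Ordered pairing of invasive and angiogenic column labels; each pair is
#' later collapsed into a single log2-ratio column.
#'
#' @param invasive,angiogenic character vectors of equal length; no label may
#'   be reused.
#' @return data frame of class `pair_map` with columns `invasive`,
#'   `angiogenic`.
#' @export
pair_map <- function(invasive, angiogenic) {
  invasive <- as.character(invasive); angiogenic <- as.character(angiogenic)
  if (length(invasive) != length(angiogenic) || length(invasive) == 0L)
    stop("pair_map needs equal-length, non-empty label vectors")
  all_labels <- c(invasive, angiogenic)
  if (anyDuplicated(all_labels))
    stop("column label reused across pairs: '",
         all_labels[duplicated(all_labels)][1L], "'")
  structure(data.frame(invasive = invasive, angiogenic = angiogenic,
                       stringsAsFactors = FALSE),
            class = c("pair_map", "data.frame"))
}

#' Read a sample-pair map from a two-column TSV (invasive, angiogenic)
#' @param path file path; header optional via `header`.
#' @param header logical; does the file carry a header row?
#' @return a [pair_map()].
#' @export
read_pair_map <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          colClasses = "character")
  pair_map(df[[1L]], df[[2L]])
}

#' Quantile normalization of raw intensities
#'
#' Forces every column onto the common distribution given by the
#' across-column mean of sorted values (Bolstad's method, as implemented in
#' limma); tied values within a column receive the mean of the reference
#' quantiles they span. Applied to raw intensities before log transformation
#' and ratio formation.
#'
#' @param matrix an `expr_matrix` with `value_kind = "raw_intensity"` and no
#'   missing values.
#' @return an `expr_matrix` of normalized raw intensities.
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$value_kind != "raw_intensity")
    stop("quantile normalization expects raw intensities")
  if (anyNA(matrix$values))
    stop("missing values present: normalize before ratio formation only")
  norm <- limma::normalizeQuantiles(matrix$values, ties = TRUE)
  dimnames(norm) <- dimnames(matrix$values)
  expr_matrix(norm, matrix$platform, "raw_intensity")
}

#' Collapse sample pairs into log2-ratio columns
#'
#' Each (invasive, angiogenic) pair becomes one column
#' `log2(invasive) - log2(angiogenic)`, so positive values mean up in the
#' invasive phenotype. This sign convention is fixed package-wide.
#'
#' @param matrix an `expr_matrix` of strictly positive intensities.
#' @param pairs a [pair_map()]; all labels must exist in the matrix.
#' @return an `expr_matrix` with `value_kind = "log2_ratio"`, one column per
#'   pair named `invasive_vs_angiogenic`, in pair-map order.
#' @export
log2_pair_ratios <- function(matrix, pairs) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(pairs, "pair_map"))
  labels <- colnames(matrix$values)
  missing_lab <- setdiff(c(pairs$invasive, pairs$angiogenic), labels)
  if (length(missing_lab))
    stop("pair label not found in matrix: '", missing_lab[1L], "'")
  v <- matrix$values
  nonpos <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(nonpos) > 0L)
    stop(sprintf("non-positive intensity at entity '%s', column '%s'",
                 rownames(v)[nonpos[1L, 1L]], colnames(v)[nonpos[1L, 2L]]))
  out <- log2(v[, pairs$invasive, drop = FALSE]) -
    log2(v[, pairs$angiogenic, drop = FALSE])
  colnames(out) <- paste0(pairs$invasive, "_vs_", pairs$angiogenic)
  expr_matrix(out, matrix$platform, "log2_ratio")
}
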