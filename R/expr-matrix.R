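#' Expression matrix container
#'
#' Entity-by-column numeric table of expression values with a platform tag.
#' Rows are transcripts (probe IDs) or protein profiles; columns are per-pair
#' log2 ratios, or per-sample intensities before ratio formation. Missing
#' values are allowed (e.g. iTRAQ block missingness) but every entity must
#' carry at least one observed value.
#'
#' @param values numeric matrix with unique, non-empty rownames (entity IDs)
#'   and colnames (column labels).
#' @param platform `"transcriptomics"` or `"proteomics"`.
#' @param value_kind `"raw_intensity"`, `"log2_intensity"` or `"log2_ratio"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, platform, value_kind) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  ids <- rownames(values)
  labels <- colnames(values)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("entity IDs (rownames) must be present and non-empty")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate entity ID: '", dup, "'")
  }
  if (is.null(labels) || anyDuplicated(labels))
    stop("column labels must be present and unique")
  platform <- match.arg(platform, c("transcriptomics", "proteomics"))
  value_kind <- match.arg(value_kind,
                          c("raw_intensity", "log2_intensity", "log2_ratio"))
  all_missing <- rowSums(!is.na(values)) == 0L
  if (any(all_missing))
    stop("entity with no non-missing value: '", ids[all_missing][1L], "'")
  structure(list(values = values, platform = platform,
                 value_kind = value_kind),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Entity IDs of an expression matrix
#' @param x an `expr_matrix`.
#' @return character vector of entity IDs in row order.
#' @export
entity_ids <- function(x) rownames(x$values)

#' Subset an expression matrix by entity ID or row index
#' @param x an `expr_matrix`.
#' @param i row index or character vector of entity IDs.
#' @param ... ignored.
#' @return an `expr_matrix` with the selected rows.
#' @export
`[.expr_matrix` <- function(x, i, ...) {
  expr_matrix(x$values[i, , drop = FALSE], x$platform, x$value_kind)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s, %s: %d entities x %d columns (%d missing cells)\n",
              x$platform, x$value_kind, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' First column holds entity IDs, the header row holds column labels.
#' Cells equal to one of `missing_tokens` become `NA`; rows that are entirely
#' missing are dropped with a message giving the count.
#'
#' @param path file path.
#' @param platform,value_kind passed to [expr_matrix()].
#' @param missing_tokens character vector of cell values treated as missing
#'   (defaults accept both empty cells and `"NA"`, covering common export
#'   dialects).
#' @param sep field separator.
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(path, platform, value_kind = "log2_ratio",
                                   missing_tokens = c("", "NA"), sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "",
                          na.strings = character())
  if (ncol(df) < 2L) stop("expression matrix needs an ID column plus >=1 value column")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate entity ID: '", ids[duplicated(ids)][1L], "'")
  raw <- as.matrix(df[, -1L, drop = FALSE])
  is_missing <- matrix(raw %in% missing_tokens, nrow = nrow(raw))
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- is.na(num) & !is_missing
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at row %d (entity '%s'), column '%s'",
                 raw[w[1L], w[2L]], w[1L], ids[w[1L]], colnames(raw)[w[2L]]))
  }
  num[is_missing] <- NA_real_
  dimnames(num) <- list(ids, colnames(raw))
  all_missing <- rowSums(!is.na(num)) == 0L
  if (any(all_missing)) {
    message("dropped ", sum(all_missing), " all-missing row(s)")
    num <- num[!all_missing, , drop = FALSE]
  }
  expr_matrix(num, platform, value_kind)
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression_matrix()]: the first column is named `id`,
#' missing values are written as `NA`.
#'
#' @param x an `expr_matrix`.
#' @param path output file path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(id = entity_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
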