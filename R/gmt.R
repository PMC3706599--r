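#' Gene set
#'
#' A named collection of identifiers in a single target namespace.
#'
#' @param name set name.
#' @param members character vector of member IDs; duplicates are collapsed
#'   with a warning, empty strings rejected.
#' @param description free-text description.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, members, description = "") {
  members <- as.character(members)
  if (length(members) == 0L || any(members == "") || anyNA(members))
    stop("gene set '", name, "': members must be non-empty")
  if (anyDuplicated(members)) {
    warning("gene set '", name, "': duplicate members collapsed")
    members <- unique(members)
  }
  structure(list(name = name, members = members, description = description),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%d members)\n", x$name, length(x$members)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Broad GMT dialect: one set per line, `name TAB description TAB member...`.
#'
#' @param path file path.
#' @return list of [gene_set()] objects (empty list for an empty file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, ": expected >=3 tab-separated fields, got ",
           length(fields))
    out[[i]] <- gene_set(fields[1L], fields[-(1:2)], description = fields[2L])
  }
  out
}

#' Write gene sets to a GMT file
#' @param sets list of [gene_set()] objects.
#' @param path output file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
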