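#' Propagate annotations up the ontology (true-path rule)
#'
#' Each gene gains all ancestor terms of its annotations over `is_a` and
#' `part_of` edges. Idempotent.
#'
#' @param annotations an `annotation_map` (gene -> term IDs), already
#'   filtered to the ontology.
#' @param ontology an [parse_obo()] result.
#' @return propagated `annotation_map`.
#' @export
propagate_annotations <- function(annotations, ontology) {
  all_terms <- unique(unlist(annotations, use.names = FALSE))
  anc <- ontology_ancestors(ontology, all_terms)
  out <- lapply(annotations, function(terms) {
    unique(c(terms, unlist(anc[terms], use.names = FALSE)))
  })
  structure(out, class = "annotation_map")
}

#' Fisher's exact over-representation test for one term
#'
#' One-sided hypergeometric upper tail: with M reference genes of which K
#' carry the term, and a top list of n genes of which k carry it,
#' `p = P(X >= k)` for X hypergeometric(M, K, n). The enrichment ratio is
#' `(k/n) / (K/M)`.
#'
#' @param top character vector, the list of interest (must be a subset of
#'   `reference`).
#' @param reference character vector, the reference universe.
#' @param term_genes genes annotated with the term (intersected with the
#'   reference internally).
#' @return one-row data frame: `k`, `n`, `K`, `M`, `nominal_p`,
#'   `enrichment_ratio`.
#' @export
fisher_term_test <- function(top, reference, term_genes) {
  top <- unique(top); reference <- unique(reference)
  if (!all(top %in% reference))
    stop("top list is not a subset of the reference universe")
  term_ref <- intersect(term_genes, reference)
  M <- length(reference); K <- length(term_ref)
  n <- length(top); k <- length(intersect(top, term_ref))
  p <- stats::phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
  ratio <- if (K == 0L) NA_real_ else (k / n) / (K / M)
  # plain-list data.frame construction: this test runs hundreds of
  # thousands of times in exhaustive sweeps
  structure(list(k = k, n = n, K = K, M = M, nominal_p = p,
                 enrichment_ratio = ratio),
            class = "data.frame", row.names = c(NA, -1L))
}

#' GO term over-representation analysis of a top list
#'
#' Tests every term annotating at least one reference gene, with the
#' reference universe being the full dataset the differential-expression
#' analysis was performed on. Reported p-values are nominal (no
#' multiple-testing adjustment), matching the convention of the
#' over-representation analyses this package accompanies.
#'
#' @param top gene IDs of interest (subset of `reference`).
#' @param reference gene IDs of the analysis universe.
#' @param ontology an [parse_obo()] result.
#' @param annotations an `annotation_map`.
#' @param p_threshold rows with `nominal_p < p_threshold` are flagged
#'   `significant` (default 0.02).
#' @param propagate apply the true-path rule before testing (default TRUE).
#' @return data frame of class `ora_result`, one row per term, sorted
#'   ascending by `nominal_p`; columns `term`, `name`, `namespace`, counts,
#'   `nominal_p`, `enrichment_ratio`, `significant`.
#' @export
run_ora <- function(top, reference, ontology, annotations,
                    p_threshold = 0.02, propagate = TRUE) {
  top <- unique(top); reference <- unique(reference)
  if (length(top) == 0L || length(reference) == 0L)
    stop("top and reference must be non-empty")
  if (!all(top %in% reference))
    stop("top list is not a subset of the reference universe")
  if (propagate) annotations <- propagate_annotations(annotations, ontology)
  ann <- annotations[names(annotations) %in% reference]
  if (length(ann) == 0L) stop("no annotated genes in the reference universe")
  gene_term <- data.frame(
    gene = rep(names(ann), lengths(ann)),
    term = unlist(ann, use.names = FALSE), stringsAsFactors = FALSE)
  term_genes <- split(gene_term$gene, gene_term$term)
  rows <- lapply(names(term_genes), function(tm) {
    r <- fisher_term_test(top, reference, term_genes[[tm]])
    r$term <- tm
    r
  })
  out <- do.call(rbind, rows)
  ti <- match(out$term, ontology$terms$id)
  out$name <- ontology$terms$name[ti]
  out$namespace <- ontology$terms$namespace[ti]
  out <- out[order(out$nominal_p, out$term),
             c("term", "name", "namespace", "k", "n", "K", "M",
               "nominal_p", "enrichment_ratio")]
  out$significant <- out$nominal_p < p_threshold
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  attr(out, "p_threshold") <- p_threshold
  out
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("<ora_result> %d terms tested, %d with nominal p < %g\n",
              nrow(x), sum(x$significant), attr(x, "p_threshold")))
  print(utils::head(as.data.frame(x), 10L), row.names = FALSE, digits = 4)
  invisible(x)
}
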