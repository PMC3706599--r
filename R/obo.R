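#' Parse a Gene Ontology OBO 1.2 file
#'
#' Captures term IDs, names, namespaces and obsolete flags, plus directed
#' child-to-parent edges of type `is_a` and `part_of`. Other relationship
#' types (e.g. `regulates`) are ignored with a message. Obsolete terms are
#' flagged and excluded from the analysis universe by downstream steps.
#'
#' @param path OBO file path.
#' @return object of class `ontology`: `terms` data frame
#'   (`id`, `name`, `namespace`, `obsolete`), `edges` data frame
#'   (`child`, `parent`, `type`), and a `parents` adjacency list.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  in_term <- FALSE
  terms <- list(); edges <- list(); ignored <- 0L
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", ln)  # strip trailing comments
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list(name = NA_character_, namespace = NA_character_,
                               obsolete = FALSE)
      next
    }
    if (!in_term) next
    kv <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L) next
    key <- kv[2L]; val <- kv[3L]
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "is_a")
      edges[[length(edges) + 1L]] <- c(cur$id %||% NA, val, "is_a")
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[1L] == "part_of")
        edges[[length(edges) + 1L]] <- c(cur$id %||% NA, parts[2L], "part_of")
      else ignored <- ignored + 1L
    }
  }
  flush()
  if (ignored > 0L)
    message("ignored ", ignored, " relationship(s) of unsupported type")
  term_df <- do.call(rbind, lapply(terms, function(t)
    data.frame(id = t$id, name = t$name, namespace = t$namespace,
               obsolete = t$obsolete, stringsAsFactors = FALSE)))
  if (is.null(term_df))
    term_df <- data.frame(id = character(), name = character(),
                          namespace = character(), obsolete = logical(),
                          stringsAsFactors = FALSE)
  edge_df <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(child = m[, 1L], parent = m[, 2L], type = m[, 3L],
               stringsAsFactors = FALSE)
  } else data.frame(child = character(), parent = character(),
                    type = character(), stringsAsFactors = FALSE)
  unknown <- setdiff(c(edge_df$child, edge_df$parent), term_df$id)
  if (length(unknown))
    stop("edge endpoint is not a defined term: ", unknown[1L])
  check_acyclic_isa(edge_df)
  parents <- split(edge_df$parent, factor(edge_df$child, levels = term_df$id))
  structure(list(terms = term_df, edges = edge_df, parents = parents),
            class = "ontology")
}

# error listing a cycle if the is_a relation is not a DAG
check_acyclic_isa <- function(edge_df) {
  isa <- edge_df[edge_df$type == "is_a", , drop = FALSE]
  if (nrow(isa) == 0L) return(invisible(TRUE))
  adj <- split(isa$parent, isa$child)
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  visit <- function(node, stack) {
    s <- state[[node]] %||% 0L
    if (s == 1L) {
      cyc <- c(stack[which(stack == node):length(stack)], node)
      stop("cyclic is_a chain: ", paste(cyc, collapse = " -> "))
    }
    if (s == 2L) return(invisible(NULL))
    state[[node]] <- 1L
    for (p in adj[[node]] %||% character()) visit(p, c(stack, node))
    state[[node]] <- 2L
  }
  for (n in unique(isa$child)) visit(n, character())
  invisible(TRUE)
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms (%d obsolete), %d edges\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges)))
  invisible(x)
}

#' Ancestors of ontology terms
#'
#' Transitive closure over `is_a` and `part_of` edges (the true-path
#' relations), excluding the term itself.
#'
#' @param ontology an [parse_obo()] result.
#' @param ids term IDs to query; default all terms.
#' @return named list: term ID -> character vector of ancestor IDs.
#' @export
ontology_ancestors <- function(ontology, ids = ontology$terms$id) {
  cache <- new.env(parent = emptyenv())
  anc <- function(id) {
    hit <- cache[[id]]
    if (!is.null(hit)) return(hit)
    ps <- ontology$parents[[id]] %||% character()
    out <- unique(c(ps, unlist(lapply(unique(ps), anc), use.names = FALSE)))
    cache[[id]] <- out
    out
  }
  stats::setNames(lapply(ids, anc), ids)
}

#' Non-obsolete terms of an ontology
#' @param ontology an [parse_obo()] result.
#' @return character vector of term IDs forming the analysis universe.
#' @export
active_terms <- function(ontology) {
  ontology$terms$id[!ontology$terms$obsolete]
}

#' Read gene-to-GO-term annotations
#'
#' Two-column tab-delimited table (gene, term), no header. Associations to
#' terms absent from the ontology's non-obsolete universe are dropped and
#' counted; duplicate associations are collapsed.
#'
#' @param path file path.
#' @param ontology an [parse_obo()] result.
#' @return named list gene -> character vector of term IDs
#'   (class `annotation_map`).
#' @export
read_annotations <- function(path, ontology) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("annotation table needs two columns: gene, term")
  keep <- df[[2L]] %in% active_terms(ontology)
  dropped <- sum(!keep)
  if (dropped > 0L)
    message("dropped ", dropped, " association(s) to terms not in the ontology")
  df <- unique(df[keep, 1:2, drop = FALSE])
  if (nrow(df) == 0L) stop("no usable annotations after ontology filtering")
  ann <- split(df[[2L]], df[[1L]])
  structure(lapply(ann, unique), class = "annotation_map")
}
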