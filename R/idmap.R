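#' Read a cross-platform identifier mapping table
#'
#' Tab-delimited with header columns `source_id`, `source_ns`, `target_id`,
#' `target_ns`, `link_path`, `species_origin`. Each row records one link of
#' one named path (e.g. `swissprot->rat_entrez`); many-to-many links are
#' permitted and duplicates are collapsed. All mapping is table-driven from
#' local files; no network services are consulted.
#'
#' @param path file path.
#' @return data frame of class `mapping_table`.
#' @export
read_mapping_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  mapping_table(df)
}

#' Construct/validate a mapping table
#' @param df data frame with columns `source_id`, `source_ns`, `target_id`,
#'   `target_ns`, `link_path`, `species_origin`.
#' @return data frame of class `mapping_table` with duplicates collapsed.
#' @export
mapping_table <- function(df) {
  need <- c("source_id", "source_ns", "target_id", "target_ns",
            "link_path", "species_origin")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mapping table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, need]
  if (any(df$source_id == "" | df$target_id == "" |
          is.na(df$source_id) | is.na(df$target_id)))
    stop("mapping record with empty source or target ID")
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("mapping_table", "data.frame")
  df
}

#' Map identifiers through chained link paths
#'
#' For every input ID (order preserved), collects the union of target IDs
#' reachable through each chain, where a chain is a sequence of `link_path`
#' labels followed hop by hop (e.g.
#' `c("swissprot->rat_entrez", "rat_entrez->human_entrez")` for the
#' rat-homolog route). IDs with no complete path are flagged unmapped, never
#' dropped.
#'
#' @param ids ordered character vector of source IDs.
#' @param table a [mapping_table()].
#' @param chains a character vector (single chain) or list of character
#'   vectors (several alternative chains, results unioned).
#' @return object of class `mapped_top_list`: `source_id`, list-column
#'   `targets`, logical `unmapped`; plus an `n_unmapped` attribute.
#' @export
map_identifiers <- function(ids, table, chains) {
  stopifnot(inherits(table, "mapping_table"))
  if (!is.list(chains)) chains <- list(chains)
  if (length(chains) == 0L || any(lengths(chains) == 0L))
    stop("chain must be non-empty")
  known <- unique(table$link_path)
  bad <- setdiff(unique(unlist(chains)), known)
  if (length(bad)) stop("unknown link_path in chain: '", bad[1L], "'")
  by_path <- split(table[, c("source_id", "target_id")], table$link_path)
  targets <- lapply(ids, function(id) {
    hits <- lapply(chains, function(chain) {
      cur <- id
      for (lp in chain) {
        seg <- by_path[[lp]]
        cur <- unique(seg$target_id[seg$source_id %in% cur])
        if (length(cur) == 0L) break
      }
      cur
    })
    unique(unlist(hits, use.names = FALSE))
  })
  unmapped <- lengths(targets) == 0L
  out <- data.frame(source_id = ids, stringsAsFactors = FALSE)
  out$targets <- targets
  out$unmapped <- unmapped
  attr(out, "n_unmapped") <- sum(unmapped)
  class(out) <- c("mapped_top_list", "data.frame")
  out
}

#' @export
print.mapped_top_list <- function(x, ...) {
  cat(sprintf("<mapped_top_list> %d source IDs, %d unmapped\n",
              nrow(x), attr(x, "n_unmapped")))
  invisible(x)
}

#' Build a gene set from a mapped top list
#'
#' Members are the deduplicated union of all mapped targets; unmapped
#' sources are excluded.
#'
#' @param mapped a [map_identifiers()] result.
#' @param name gene-set name.
#' @param description optional description.
#' @return a [gene_set()].
#' @export
build_gene_set <- function(mapped, name, description = "") {
  members <- unique(unlist(mapped$targets, use.names = FALSE))
  if (length(members) == 0L) stop("no mapped targets: cannot build gene set")
  gene_set(name, members, description)
}

#' Matched 1:1 cross-platform subsets
#'
#' Reduces two expression matrices to the entities participating in a unique
#' one-to-one correspondence through a shared gene namespace: an entity pair
#' (a, b) is retained iff a maps to exactly one gene g, b maps to exactly
#' one gene g, and g is reached by exactly one entity in each layer.
#' Ambiguous (many-to-many) entities are excluded and logged.
#'
#' @param a,b `expr_matrix` objects for the two layers.
#' @param table a [mapping_table()].
#' @param chains_a,chains_b link-path chains mapping each layer's entity IDs
#'   into the shared namespace.
#' @return list with the reduced matrices `a` and `b` and the bijective
#'   `pairing` data frame (`id_a`, `id_b`, `gene`).
#' @export
matched_subsets <- function(a, b, table, chains_a, chains_b) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  ga <- map_identifiers(entity_ids(a), table, chains_a)
  gb <- map_identifiers(entity_ids(b), table, chains_b)
  uniq <- function(m) {
    ok <- lengths(m$targets) == 1L
    data.frame(id = m$source_id[ok],
               gene = vapply(m$targets[ok], `[`, character(1L), 1L),
               stringsAsFactors = FALSE)
  }
  ua <- uniq(ga); ub <- uniq(gb)
  # genes reached by exactly one entity per layer
  ua <- ua[ua$gene %in% names(which(table(ua$gene) == 1L)), , drop = FALSE]
  ub <- ub[ub$gene %in% names(which(table(ub$gene) == 1L)), , drop = FALSE]
  common <- intersect(ua$gene, ub$gene)
  if (length(common) == 0L)
    stop("no 1:1 cross-platform correspondence found")
  n_excl <- (nrow(a$values) - length(common)) + (nrow(b$values) - length(common))
  message("matched ", length(common), " 1:1 pairs; excluded ", n_excl,
          " ambiguous or unmatched entities")
  pairing <- data.frame(
    id_a = ua$id[match(common, ua$gene)],
    id_b = ub$id[match(common, ub$gene)],
    gene = common, stringsAsFactors = FALSE)
  list(a = a[pairing$id_a], b = b[pairing$id_b], pairing = pairing)
}

#' Count distinct non-empty key values in a table
#'
#' @param records data frame.
#' @param key_column column name to count over.
#' @return integer count of distinct non-empty values.
#' @export
count_unique_entities <- function(records, key_column) {
  if (!key_column %in% names(records))
    stop("no such column: '", key_column, "'")
  vals <- as.character(records[[key_column]])
  vals <- vals[!is.na(vals) & vals != ""]
  length(unique(vals))
}
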