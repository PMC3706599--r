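#' Pipeline configuration for the integrated analysis
#'
#' @param q_threshold Rank Product q-value cut-off defining the top list
#'   (default 0.5; 0.3 is the stricter published alternative).
#' @param n_permutations permutations for both the Rank Product pfp and the
#'   GSEA null (default 1000).
#' @param min_size,max_size GSEA gene-set size bounds (defaults 10, 500).
#' @param weight_p GSEA weight exponent (default 1).
#' @param seed integer seed governing every random draw in the pipeline.
#' @param tr_chains,pr_chains identifier-mapping chains (see
#'   [map_identifiers()]) taking transcript and protein-profile IDs into the
#'   shared gene namespace; defaults match [generate_cross_omics()] tables
#'   (probe IDs map directly, SwissProt accessions map directly for human
#'   origin or through a rat-homolog hop).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(q_threshold = 0.5, n_permutations = 1000,
                            min_size = 10, max_size = 500, weight_p = 1,
                            seed = NULL,
                            tr_chains = list("probe->human_entrez"),
                            pr_chains = list("swissprot->human_entrez",
                                             c("swissprot->rat_entrez",
                                               "rat_entrez->human_entrez"))) {
  stopifnot(q_threshold > 0, q_threshold <= 1)
  structure(list(q_threshold = q_threshold, n_permutations = n_permutations,
                 min_size = min_size, max_size = max_size,
                 weight_p = weight_p, seed = seed,
                 tr_chains = tr_chains, pr_chains = pr_chains),
            class = "pipeline_config")
}

chains_for <- function(platform, cfg) {
  if (platform == "transcriptomics") cfg$tr_chains else cfg$pr_chains
}

#' Cross-platform gene-set evaluation of one layer's top list in the other
#'
#' The headline integration procedure. The source layer's mapped entities
#' are ranked by Rank Product in the requested phenotype direction; the top
#' list at `q_threshold` is mapped into the shared gene namespace and
#' becomes a gene set; that set is evaluated by GSEA against the full target
#' matrix ranked by the log-fold metric (membership of a target entity is
#' decided through its mapped gene, so several protein profiles of one gene
#' each count); the leading edge is extracted and joined with mapping
#' provenance.
#'
#' @param source,target `expr_matrix` objects (source supplies the top
#'   list, target is screened by GSEA).
#' @param table a [mapping_table()] covering both layers.
#' @param direction `"up_in_invasive"` or `"up_in_angiogenic"`.
#' @param cfg a [pipeline_config()].
#' @return object of class `integration_report`: the Rank Product fit, top
#'   list, gene set, `gsea` object, and a leading-edge table with mapping
#'   provenance.
#' @export
integrated_enrichment <- function(source, target, table, direction,
                                  cfg = pipeline_config()) {
  stopifnot(inherits(source, "expr_matrix"), inherits(target, "expr_matrix"))
  direction <- match.arg(direction, c("up_in_invasive", "up_in_angiogenic"))
  src_chains <- chains_for(source$platform, cfg)
  tgt_chains <- chains_for(target$platform, cfg)

  tmap <- map_identifiers(entity_ids(target), table, tgt_chains)
  target_universe <- unique(unlist(tmap$targets, use.names = FALSE))
  smap <- map_identifiers(entity_ids(source), table, src_chains)
  reach <- vapply(smap$targets, function(tg) any(tg %in% target_universe),
                  logical(1L))
  if (!any(reach)) stop("no source entity maps into the target layer")
  mapped_src <- source[smap$source_id[reach]]

  rt <- rank_columns(mapped_src, direction)
  rp <- rank_product(rt)
  rp <- estimate_pfp(rp, rt, n_permutations = cfg$n_permutations,
                     seed = cfg$seed)
  top <- top_list(rp, cfg$q_threshold)
  if (length(top) == 0L)
    stop("empty top list at q = ", cfg$q_threshold,
         "; consider a higher q_threshold")

  top_map <- smap[match(top, smap$source_id), , drop = FALSE]
  members <- intersect(unique(unlist(top_map$targets, use.names = FALSE)),
                       target_universe)
  if (length(members) == 0L)
    stop("top list maps to no gene present in the target layer")
  set_name <- sprintf("%s_top_%s", source$platform, direction)
  gset <- gene_set(set_name, members,
                   description = sprintf("RP top list (q <= %g) mapped from %s",
                                         cfg$q_threshold, source$platform))
  # translate gene membership to target entities through their mapped genes
  in_set <- vapply(tmap$targets, function(tg) any(tg %in% members), logical(1L))
  entity_members <- tmap$source_id[in_set]

  tgt <- target
  if (direction == "up_in_angiogenic") tgt$values <- -tgt$values
  ranked <- rank_by_logfold(tgt)
  gs <- run_gsea(ranked, gene_set(set_name, entity_members),
                 gsea_params(weight_p = cfg$weight_p,
                             n_permutations = cfg$n_permutations,
                             min_size = cfg$min_size, max_size = cfg$max_size,
                             seed = cfg$seed))

  le <- gs$leading_edges[[1L]]
  le_rows <- lapply(le, function(ent) {
    genes <- intersect(tmap$targets[[match(ent, tmap$source_id)]], members)
    src_ent <- top[vapply(top_map$targets, function(tg) any(tg %in% genes),
                          logical(1L))]
    prov <- table[table$source_id == ent, , drop = FALSE]
    data.frame(target_entity = ent,
               rank = match(ent, ranked$ids),
               metric = ranked$metric[match(ent, ranked$ids)],
               genes = paste(genes, collapse = ";"),
               source_entities = paste(src_ent, collapse = ";"),
               species_origin = paste(unique(prov$species_origin),
                                      collapse = ";"),
               stringsAsFactors = FALSE)
  })
  le_table <- if (length(le_rows)) do.call(rbind, le_rows)
              else data.frame(target_entity = character(), rank = integer(),
                              metric = numeric(), genes = character(),
                              source_entities = character(),
                              species_origin = character())
  structure(list(direction = direction,
                 source_platform = source$platform,
                 target_platform = target$platform,
                 n_mapped_source = sum(reach),
                 rp = rp, top = top, gene_set = gset,
                 entity_set_size = gs$results$effective_size[1L],
                 gsea = gs, leading_edge = le_table,
                 cfg = cfg,
                 instance = attr(source, "instance") %||%
                   attr(target, "instance")),
            class = "integration_report")
}

#' @export
print.integration_report <- function(x, ...) {
  r <- x$gsea$results
  cat(sprintf("<integration_report> %s -> %s, %s\n", x$source_platform,
              x$target_platform, x$direction))
  cat(sprintf("  RP top list: %d of %d mapped entities (q <= %g)\n",
              length(x$top), x$n_mapped_source, x$cfg$q_threshold))
  cat(sprintf("  gene set: %d genes -> %d target entities\n",
              length(x$gene_set$members), x$entity_set_size))
  cat(sprintf("  GSEA: ES = %.3f, NES = %.3f, nominal p = %.4g, FDR q = %.4g, leading edge = %d\n",
              r$es, r$nes, r$nominal_p, r$fdr_q, r$n_leading_edge))
  invisible(x)
}

#' @export
summary.integration_report <- function(object, ...) {
  print(object)
  cat("\nLeading edge (top rows):\n")
  print(utils::head(object$leading_edge, 10L), row.names = FALSE, digits = 3)
  invisible(object$leading_edge)
}

#' Reciprocal integrated analysis in all four directions
#'
#' Runs [integrated_enrichment()] transcriptomics-to-proteomics and
#' proteomics-to-transcriptomics, each for both phenotype directions, and
#' summarizes which directions reach significance.
#'
#' @param tr,pr transcriptomics and proteomics `expr_matrix` objects.
#' @param table a [mapping_table()].
#' @param cfg a [pipeline_config()].
#' @return list of class `reciprocal_analysis` with the four
#'   `integration_report`s and a `summary` data frame.
#' @export
run_reciprocal_analysis <- function(tr, pr, table, cfg = pipeline_config()) {
  runs <- list(
    tr_to_pr_invasive = list(tr, pr, "up_in_invasive"),
    tr_to_pr_angiogenic = list(tr, pr, "up_in_angiogenic"),
    pr_to_tr_invasive = list(pr, tr, "up_in_invasive"),
    pr_to_tr_angiogenic = list(pr, tr, "up_in_angiogenic"))
  reports <- lapply(runs, function(r)
    integrated_enrichment(r[[1L]], r[[2L]], table, r[[3L]], cfg))
  summary_df <- do.call(rbind, lapply(names(reports), function(nm) {
    g <- reports[[nm]]$gsea$results
    data.frame(run = nm, direction = reports[[nm]]$direction,
               es = g$es, nes = g$nes, nominal_p = g$nominal_p,
               fdr_q = g$fdr_q, stringsAsFactors = FALSE)
  }))
  structure(list(reports = reports, summary = summary_df),
            class = "reciprocal_analysis")
}

#' @export
print.reciprocal_analysis <- function(x, ...) {
  cat("<reciprocal_analysis>\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rank Product meta-analysis comparator
#'
#' The straightforward alternative to the gene-set integration: restrict
#' both layers to their matched 1:1 subsets, rank each by Rank Product, and
#' feed the two rank lists to a second Rank Product step
#' ([meta_rank_product()]), reporting the top pairs per direction.
#'
#' @param tr,pr the two `expr_matrix` layers.
#' @param table a [mapping_table()].
#' @param cfg a [pipeline_config()].
#' @param top_k pairs reported per direction (default 20); truncated with a
#'   warning if fewer pairs exist.
#' @return list of class `meta_comparator` with per-direction top-pair
#'   tables and the pairing.
#' @export
rp_meta_comparator <- function(tr, pr, table, cfg = pipeline_config(),
                               top_k = 20) {
  ms <- matched_subsets(tr, pr, table, cfg$tr_chains, cfg$pr_chains)
  n_pairs <- nrow(ms$pairing)
  if (top_k > n_pairs) {
    warning("top_k = ", top_k, " exceeds ", n_pairs, " pairs; truncating")
    top_k <- n_pairs
  }
  per_direction <- lapply(
    stats::setNames(nm = c("up_in_invasive", "up_in_angiogenic")),
    function(d) {
      rp_a <- rank_product(rank_columns(ms$a, d))
      rp_b <- rank_product(rank_columns(ms$b, d))
      meta <- meta_rank_product(rp_a, rp_b, ms$pairing,
                                n_permutations = cfg$n_permutations,
                                seed = cfg$seed)
      meta[order(meta$meta_rank), ][seq_len(top_k), ]
    })
  structure(list(top_pairs = per_direction, pairing = ms$pairing,
                 n_pairs = n_pairs),
            class = "meta_comparator")
}

#' @export
print.meta_comparator <- function(x, ...) {
  cat(sprintf("<meta_comparator> %d matched pairs\n", x$n_pairs))
  for (d in names(x$top_pairs)) {
    tp <- x$top_pairs[[d]]
    cat(sprintf("  %s: q at rank %d = %.3f\n", d, nrow(tp),
                tp$q_monotone[nrow(tp)]))
  }
  invisible(x)
}

#' Expression-threshold gene sets (one per column)
#'
#' For validation-style analyses: per column, the set of entities whose raw
#' (or log2) intensity is at least `min_value` (missing values excluded;
#' the bound is inclusive). Columns yielding empty sets are logged and
#' skipped.
#'
#' @param matrix an `expr_matrix` with `value_kind` of `"raw_intensity"` or
#'   `"log2_intensity"`.
#' @param min_value inclusive lower bound.
#' @param label prefix for the set names (suffixed with the column label).
#' @return list of [gene_set()] objects.
#' @export
expression_threshold_sets <- function(matrix, min_value, label) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (!matrix$value_kind %in% c("raw_intensity", "log2_intensity"))
    stop("expects raw or log2 intensities")
  v <- matrix$values
  out <- list()
  for (j in seq_len(ncol(v))) {
    members <- rownames(v)[!is.na(v[, j]) & v[, j] >= min_value]
    nm <- paste0(label, "_", colnames(v)[j])
    if (length(members) == 0L) {
      message("column '", colnames(v)[j], "': empty set at threshold ",
              min_value, "; skipped")
    } else {
      out[[nm]] <- gene_set(nm, members,
                            description = sprintf("expressed >= %g", min_value))
    }
  }
  out
}
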