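#' Configuration for the synthetic dual-omics generator
#'
#' Defaults emulate the study design this package targets: four microarray
#' sample pairs summarized as log2-ratio columns, a protein-profile layer
#' quantified in three separate iTRAQ experiments (block missingness,
#' several profiles per gene, mixed human/rat origin), a partial
#' many-to-many mapping between the layers, and a planted set of
#' concordantly differentially expressed genes in the invasive direction.
#'
#' @param n_transcripts number of transcripts (one gene each).
#' @param n_protein_profiles number of protein profiles.
#' @param n_tr_pairs log2-ratio columns in the transcript layer (default 4).
#' @param n_pr_columns ratio columns in the protein layer (default 3, with
#'   each profile observed in one two-column experiment block).
#' @param overlap_fraction fraction of protein-layer genes shared with the
#'   transcript layer.
#' @param n_de planted differentially expressed genes per phenotype
#'   direction per layer.
#' @param concordant_fraction named fractions of `n_de` planted with the
#'   same sign in both layers, per direction; the default plants 50
#'   concordant genes (of 2000) in the invasive direction and none in the
#'   angiogenic direction.
#' @param effect_size_mu mean log2-ratio shift of planted entities.
#' @param noise_sd standard deviation of the log2-ratio noise.
#' @param profiles_per_gene named probability vector over profile counts per
#'   protein-layer gene.
#' @param decoy_fraction fraction of profiles receiving an extra decoy
#'   mapping target (exercises many-to-many exclusion logic).
#' @param noise `"gaussian"` or `"t3"` (scaled Student t, df = 3, to
#'   stress-test the rank statistics under heavy tails).
#' @param seed integer seed or `NULL`.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_transcripts = 2000,
                             n_protein_profiles = 2000,
                             n_tr_pairs = 4,
                             n_pr_columns = 3,
                             overlap_fraction = 0.6,
                             n_de = 100,
                             concordant_fraction = c(up_in_invasive = 0.5,
                                                     up_in_angiogenic = 0),
                             effect_size_mu = 1.0,
                             noise_sd = 0.5,
                             profiles_per_gene = c(`1` = 0.6, `2` = 0.3,
                                                   `3` = 0.1),
                             decoy_fraction = 0.05,
                             noise = c("gaussian", "t3"),
                             seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(n_transcripts > 0, n_protein_profiles > 0, n_tr_pairs > 0,
            n_pr_columns > 0, n_de > 0,
            overlap_fraction >= 0, overlap_fraction <= 1,
            all(concordant_fraction >= 0), all(concordant_fraction <= 1),
            effect_size_mu >= 0, noise_sd > 0,
            decoy_fraction >= 0, decoy_fraction <= 1)
  dirs <- c("up_in_invasive", "up_in_angiogenic")
  cf <- stats::setNames(rep(0, 2L), dirs)
  cf[names(concordant_fraction)] <- concordant_fraction
  structure(list(n_transcripts = n_transcripts,
                 n_protein_profiles = n_protein_profiles,
                 n_tr_pairs = n_tr_pairs, n_pr_columns = n_pr_columns,
                 overlap_fraction = overlap_fraction, n_de = n_de,
                 concordant_fraction = cf, effect_size_mu = effect_size_mu,
                 noise_sd = noise_sd, profiles_per_gene = profiles_per_gene,
                 decoy_fraction = decoy_fraction, noise = noise, seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic dual-omics dataset with planted concordance
#'
#' Null entities draw iid noise per log2-ratio column; planted entities draw
#' the same noise around `+effect_size_mu` (up in invasive) or
#' `-effect_size_mu` (up in angiogenic). Concordant genes are planted with
#' the same sign in both layers; the remaining planted genes are
#' layer-specific. Protein profiles replicate their gene's status with
#' independent noise and are each observed in one experiment block of
#' columns. Fully reproducible given the seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `cross_omics_sim`: `tr` and `pr` (`expr_matrix`),
#'   `table` ([mapping_table()]), `truth` (planted entity and gene lists per
#'   direction, concordant subsets, profile-to-gene ground truth, instance
#'   label) and `cfg`.
#' @export
generate_cross_omics <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dirs <- c("up_in_invasive", "up_in_angiogenic")
  with_seed(cfg$seed, {
    rnoise <- function(n) {
      if (cfg$noise == "gaussian") stats::rnorm(n, 0, cfg$noise_sd)
      else stats::rt(n, df = 3) / sqrt(3) * cfg$noise_sd
    }
    genes <- sprintf("HS%05d", seq_len(cfg$n_transcripts))
    transcripts <- sprintf("TR%05d", seq_len(cfg$n_transcripts))
    tr_gene <- stats::setNames(genes, transcripts)

    # protein-layer gene pool: draw profile counts until the profile budget
    # is met, trimming the last gene
    counts_raw <- sample(as.integer(names(cfg$profiles_per_gene)),
                         cfg$n_protein_profiles, replace = TRUE,
                         prob = cfg$profiles_per_gene)
    cum <- cumsum(counts_raw)
    n_pr_genes <- which(cum >= cfg$n_protein_profiles)[1L]
    counts <- counts_raw[seq_len(n_pr_genes)]
    counts[n_pr_genes] <- counts[n_pr_genes] -
      (cum[n_pr_genes] - cfg$n_protein_profiles)
    n_overlap <- round(cfg$overlap_fraction * n_pr_genes)
    overlap_genes <- sort(sample(genes, n_overlap))
    pr_only <- sprintf("PO%05d", seq_len(n_pr_genes - n_overlap))
    pr_genes <- c(overlap_genes, pr_only)[sample.int(n_pr_genes)]

    profiles <- sprintf("PRF%05d", seq_len(cfg$n_protein_profiles))
    profile_gene <- rep(pr_genes, counts)
    profile_origin <- sample(c("human", "rat"), cfg$n_protein_profiles,
                             replace = TRUE)

    # planted genes: concordant ones from the overlap, layer-specific extras
    # from genes absent in the other layer; a zero effect size is the null
    # limit and plants nothing
    n_de_eff <- if (cfg$effect_size_mu == 0) 0L else cfg$n_de
    n_conc <- round(n_de_eff * cfg$concordant_fraction)
    if (sum(n_conc) > n_overlap)
      stop("not enough overlap genes for the requested concordant counts")
    conc_pool <- sample(overlap_genes)
    conc <- list(); used <- 0L
    for (d in dirs) {
      conc[[d]] <- conc_pool[seq_len(n_conc[[d]]) + used]
      used <- used + n_conc[[d]]
    }
    # non-concordant extras are drawn layer-wise from the whole gene universe
    # of that layer (minus anything concordant or planted in the other layer),
    # so overlap genes can be discordantly DE -- present in the mapped subset
    # of both layers but shifted in only one, as in real paired-platform data
    need_tr <- n_de_eff - n_conc; need_pr <- n_de_eff - n_conc
    all_conc <- unlist(conc, use.names = FALSE)
    tr_extra_pool <- sample(setdiff(genes, all_conc))
    if (sum(need_tr) > length(tr_extra_pool))
      stop("n_de too large for the transcript gene pool")
    tr_de_genes <- list(); ut <- 0L
    for (d in dirs) {
      tr_de_genes[[d]] <- c(conc[[d]], tr_extra_pool[seq_len(need_tr[[d]]) + ut])
      ut <- ut + need_tr[[d]]
    }
    tr_extras <- tr_extra_pool[seq_len(ut)]
    pr_extra_pool <- sample(setdiff(pr_genes, c(all_conc, tr_extras)))
    if (sum(need_pr) > length(pr_extra_pool))
      stop("n_de too large for the protein gene pool")
    pr_de_genes <- list(); up <- 0L
    for (d in dirs) {
      pr_de_genes[[d]] <- c(conc[[d]], pr_extra_pool[seq_len(need_pr[[d]]) + up])
      up <- up + need_pr[[d]]
    }

    shift <- c(up_in_invasive = cfg$effect_size_mu,
               up_in_angiogenic = -cfg$effect_size_mu)
    tr_vals <- matrix(rnoise(cfg$n_transcripts * cfg$n_tr_pairs),
                      cfg$n_transcripts, cfg$n_tr_pairs,
                      dimnames = list(transcripts,
                                      sprintf("pair_%d", seq_len(cfg$n_tr_pairs))))
    for (d in dirs) {
      rows <- transcripts[tr_gene %in% tr_de_genes[[d]]]
      tr_vals[rows, ] <- tr_vals[rows, ] + shift[[d]]
    }

    # each profile sits in one experiment block covering two adjacent columns
    block <- sample.int(cfg$n_pr_columns, cfg$n_protein_profiles, replace = TRUE)
    block_cols <- function(b) {
      if (cfg$n_pr_columns == 1L) 1L
      else unique(c(b, b %% cfg$n_pr_columns + 1L))
    }
    pr_vals <- matrix(NA_real_, cfg$n_protein_profiles, cfg$n_pr_columns,
                      dimnames = list(profiles,
                                      sprintf("itraq_%d", seq_len(cfg$n_pr_columns))))
    gene_shift <- stats::setNames(rep(0, length(pr_genes)), pr_genes)
    for (d in dirs) gene_shift[pr_de_genes[[d]]] <- shift[[d]]
    for (i in seq_len(cfg$n_protein_profiles)) {
      cols <- block_cols(block[i])
      pr_vals[i, cols] <- rnoise(length(cols)) + gene_shift[[profile_gene[i]]]
    }

    tr <- expr_matrix(tr_vals, "transcriptomics", "log2_ratio")
    pr <- expr_matrix(pr_vals, "proteomics", "log2_ratio")

    # mapping table: probe->human_entrez for transcripts; profiles map
    # directly (human origin) or through a rat homolog hop (rat origin)
    rows <- list(data.frame(source_id = transcripts, source_ns = "probe",
                            target_id = unname(tr_gene), target_ns = "human_entrez",
                            link_path = "probe->human_entrez",
                            species_origin = "human", stringsAsFactors = FALSE))
    human_p <- profile_origin == "human"
    rows[[2]] <- data.frame(source_id = profiles[human_p], source_ns = "swissprot",
                            target_id = profile_gene[human_p],
                            target_ns = "human_entrez",
                            link_path = "swissprot->human_entrez",
                            species_origin = "human", stringsAsFactors = FALSE)
    rat_gene <- function(g) paste0("RN_", g)
    rows[[3]] <- data.frame(source_id = profiles[!human_p], source_ns = "swissprot",
                            target_id = rat_gene(profile_gene[!human_p]),
                            target_ns = "rat_entrez",
                            link_path = "swissprot->rat_entrez",
                            species_origin = "rat", stringsAsFactors = FALSE)
    rows[[4]] <- data.frame(source_id = rat_gene(profile_gene[!human_p]),
                            source_ns = "rat_entrez",
                            target_id = profile_gene[!human_p],
                            target_ns = "human_entrez",
                            link_path = "rat_entrez->human_entrez",
                            species_origin = "rat", stringsAsFactors = FALSE)
    # decoy many-to-many records: extra random target for some profiles
    n_decoy <- round(cfg$decoy_fraction * cfg$n_protein_profiles)
    if (n_decoy > 0L) {
      di <- sample.int(cfg$n_protein_profiles, n_decoy)
      decoy_target <- sample(genes, n_decoy, replace = TRUE)
      rows[[5]] <- data.frame(source_id = profiles[di], source_ns = "swissprot",
                              target_id = decoy_target, target_ns = "human_entrez",
                              link_path = "swissprot->human_entrez",
                              species_origin = "human", stringsAsFactors = FALSE)
    }
    table <- mapping_table(do.call(rbind, rows))

    instance <- sprintf("sim_%d_%d_%s", cfg$n_transcripts,
                        cfg$n_protein_profiles,
                        if (is.null(cfg$seed)) "unseeded" else cfg$seed)
    truth <- list(
      tr_de_entities = lapply(tr_de_genes, function(g)
        transcripts[tr_gene %in% g]),
      pr_de_entities = lapply(pr_de_genes, function(g)
        profiles[profile_gene %in% g]),
      tr_de_genes = tr_de_genes, pr_de_genes = pr_de_genes,
      concordant_genes = conc,
      profile_gene = data.frame(profile = profiles, gene = profile_gene,
                                origin = profile_origin, block = block,
                                stringsAsFactors = FALSE),
      transcript_gene = data.frame(transcript = transcripts,
                                   gene = unname(tr_gene),
                                   stringsAsFactors = FALSE),
      instance = instance)
    attr(tr, "instance") <- instance
    attr(pr, "instance") <- instance
    structure(list(tr = tr, pr = pr, table = table, truth = truth, cfg = cfg),
              class = "cross_omics_sim")
  })
}

#' @export
print.cross_omics_sim <- function(x, ...) {
  cat(sprintf("<cross_omics_sim> %s: %d transcripts x %d pairs, %d profiles x %d columns\n",
              x$truth$instance, nrow(x$tr$values), ncol(x$tr$values),
              nrow(x$pr$values), ncol(x$pr$values)))
  cat(sprintf("  planted: %d DE genes/direction/layer; concordant %s\n",
              x$cfg$n_de,
              paste(names(x$truth$concordant_genes),
                    lengths(x$truth$concordant_genes),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Recovery metrics of a pipeline run against the simulation ground truth
#'
#' Reports precision and recall of the source-layer Rank Product top list
#' against the planted entities, and the leading-edge recall of the planted
#' concordant genes. A null instance (no concordant genes in the evaluated
#' direction) yields `NA` leading-edge recall, flagged in the output.
#'
#' @param truth the `truth` element of a [generate_cross_omics()] result (or
#'   the simulation object itself).
#' @param report an [integrated_enrichment()] report computed on the same
#'   generated instance.
#' @return one-row data frame of recovery metrics.
#' @export
recovery_report <- function(truth, report) {
  if (inherits(truth, "cross_omics_sim")) truth <- truth$truth
  stopifnot(inherits(report, "integration_report"))
  if (!identical(truth$instance, report$instance))
    stop("report was not computed on this generated instance (label mismatch)")
  d <- report$direction
  src_truth <- if (report$source_platform == "transcriptomics")
    truth$tr_de_entities[[d]] else truth$pr_de_entities[[d]]
  top <- report$top
  precision <- if (length(top)) mean(top %in% src_truth) else NA_real_
  recall <- if (length(src_truth)) mean(src_truth %in% top) else NA_real_
  conc <- truth$concordant_genes[[d]]
  ent_gene <- if (report$target_platform == "proteomics")
    stats::setNames(truth$profile_gene$gene, truth$profile_gene$profile)
  else stats::setNames(truth$transcript_gene$gene,
                       truth$transcript_gene$transcript)
  le_genes <- unique(unname(ent_gene[report$leading_edge$target_entity]))
  le_recall <- if (length(conc)) mean(conc %in% le_genes) else NA_real_
  data.frame(direction = d, source = report$source_platform,
             top_size = length(top), rp_precision = precision,
             rp_recall = recall,
             n_concordant = length(conc),
             leading_edge_recall = le_recall,
             null_instance = length(conc) == 0L,
             stringsAsFactors = FALSE)
}
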