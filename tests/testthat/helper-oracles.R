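# Independent oracles and tiny fixture builders used across the suite.

# literal walk of the weighted running sum; stays independent of the
# cumsum-based implementation path
brute_force_es <- function(ids, metric, members, weight_p = 1) {
  N <- length(ids)
  hit <- ids %in% members
  n_h <- sum(hit)
  n_r <- sum(abs(metric[hit])^weight_p)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) cur + abs(metric[i])^weight_p / n_r
           else cur - 1 / (N - n_h)
    run[i] <- cur
  }
  peak <- which.max(abs(run))
  list(es = run[peak], profile = run, peak_index = peak)
}

# all permutations of 1..n as rows
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# exhaustive permutation distribution of the Rank Product for n entities
# over k columns (tie-free integer ranks): returns, per entity, the exact
# mean and sd of the per-permutation count #{permuted rp <= observed rp}
exhaustive_rp_pfp <- function(obs_rp, n, k) {
  perm <- all_perms(n)
  idx <- as.matrix(expand.grid(rep(list(seq_len(nrow(perm))), k)))
  counts <- matrix(0, nrow(idx), length(obs_rp))
  thr <- obs_rp * (1 + 1e-9)
  for (b in seq_len(nrow(idx))) {
    ranks <- sapply(seq_len(k), function(j) perm[idx[b, j], ])
    rp_b <- apply(ranks, 1L, function(r) prod(r)^(1 / k))
    counts[b, ] <- vapply(thr, function(t) sum(rp_b <= t), numeric(1L))
  }
  list(mean = colMeans(counts), sd = apply(counts, 2L, stats::sd),
       n_perm = nrow(idx))
}

# tiny OBO writer: takes a character vector of stanza lines
write_tiny_obo <- function(lines, path = tempfile(fileext = ".obo")) {
  writeLines(c("format-version: 1.2", "", lines), path)
  path
}

obo_term <- function(id, name = id, namespace = "biological_process",
                     is_a = character(), part_of = character(),
                     obsolete = FALSE) {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    paste0("namespace: ", namespace),
    if (length(is_a)) paste0("is_a: ", is_a),
    if (length(part_of)) paste0("relationship: part_of ", part_of),
    if (obsolete) "is_obsolete: true", "")
}

# small expr_matrix from a plain matrix
em <- function(values, platform = "transcriptomics",
               value_kind = "log2_ratio") {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("e", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  expr_matrix(values, platform, value_kind)
}

# a scaled-down simulated study used by several pipeline tests
small_sim <- function(seed, n = 400, n_de = 30, effect = 1, conc_inv = 0.5,
                      conc_ang = 0) {
  generate_cross_omics(synthetic_config(
    n_transcripts = n, n_protein_profiles = n, n_de = n_de,
    effect_size_mu = effect,
    concordant_fraction = c(up_in_invasive = conc_inv,
                            up_in_angiogenic = conc_ang),
    seed = seed))
}
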