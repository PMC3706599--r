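#' Ranked list for enrichment analysis
#'
#' @param ids entity IDs, ordered by descending metric (stable tie order).
#' @param metric the ranking metric values, same length and order.
#' @return object of class `ranked_list` with fields `ids`, `metric`, `N`.
#' @export
ranked_list <- function(ids, metric) {
  ids <- as.character(ids)
  if (length(ids) < 2L) stop("ranked list needs N >= 2")
  if (anyDuplicated(ids)) stop("ranked list IDs must be unique")
  if (length(metric) != length(ids)) stop("ids/metric length mismatch")
  if (is.unsorted(rev(metric))) stop("metric must be non-increasing")
  structure(list(ids = ids, metric = as.numeric(metric), N = length(ids)),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list> N = %d, metric range [%.3g, %.3g]\n",
              x$N, min(x$metric), max(x$metric)))
  invisible(x)
}

#' Rank entities by the log-fold metric
#'
#' The metric for paired single-class data is the arithmetic mean of an
#' entity's non-missing log2-ratio columns (`summary = "median"` offers the
#' more robust alternative). Entities are sorted descending; ties keep input
#' order.
#'
#' @param matrix an `expr_matrix` with `value_kind = "log2_ratio"`.
#' @param summary `"mean"` (default) or `"median"`.
#' @return a [ranked_list()].
#' @export
rank_by_logfold <- function(matrix, summary = c("mean", "median")) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$value_kind != "log2_ratio") stop("expects log2 ratios")
  summary <- match.arg(summary)
  v <- matrix$values
  metric <- if (summary == "mean") rowMeans(v, na.rm = TRUE)
            else apply(v, 1L, stats::median, na.rm = TRUE)
  if (anyNA(metric))
    stop("entity with no non-missing values: '", names(metric)[is.na(metric)][1L], "'")
  o <- order(-metric)  # stable: ties keep input order
  ranked_list(rownames(v)[o], metric[o])
}

#' GSEA parameters
#'
#' @param weight_p exponent on |metric| in the running sum (default 1, the
#'   standard weighted scheme).
#' @param n_permutations size of the gene-permutation null sample.
#' @param min_size,max_size gene-set size bounds after intersection with the
#'   ranked list (defaults 10 and 500).
#' @param seed integer seed or `NULL`.
#' @return list of class `gsea_params`.
#' @export
gsea_params <- function(weight_p = 1, n_permutations = 1000,
                        min_size = 10, max_size = 500, seed = NULL) {
  stopifnot(weight_p >= 0, min_size <= max_size, n_permutations >= 1)
  structure(list(weight_p = weight_p, n_permutations = n_permutations,
                 min_size = min_size, max_size = max_size, seed = seed),
            class = "gsea_params")
}

#' Enrichment score and running-sum profile
#'
#' Walking the ranked list, member hits increment the running sum by
#' `|r_j|^p / N_R` (N_R the sum of those weights over all hits) and misses
#' decrement by `1 / (N - N_H)`. The enrichment score is the signed value of
#' the running sum at its maximum absolute deviation from zero; the profile
#' telescopes back to 0 at the end of the list.
#'
#' @param ranked a [ranked_list()].
#' @param members character vector of member IDs; must intersect the ranked
#'   list and be a strict subset of it.
#' @param weight_p exponent on the absolute metric.
#' @return list with `es`, `running_profile` (length N), `peak_index` and the
#'   member `hit_positions`.
#' @export
enrichment_score <- function(ranked, members, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  hit <- ranked$ids %in% members
  n_h <- sum(hit)
  if (n_h == 0L) stop("gene set does not intersect the ranked list")
  if (n_h == ranked$N) stop("gene set covers the whole ranked list")
  w <- abs(ranked$metric)^weight_p
  n_r <- sum(w[hit])
  if (n_r == 0) stop("all member weights are zero (N_R = 0)")
  steps <- ifelse(hit, w / n_r, -1 / (ranked$N - n_h))
  profile <- cumsum(steps)
  peak_index <- which.max(abs(profile))
  list(es = profile[peak_index], running_profile = unname(profile),
       peak_index = peak_index, hit_positions = which(hit))
}

# enrichment score from sorted hit positions only (no full profile);
# used for the permutation null. pos must be sorted ascending.
es_from_positions <- function(pos, w_all, N) {
  n_h <- length(pos)
  w <- w_all[pos]
  n_r <- sum(w)
  if (n_r == 0) return(0)
  d <- 1 / (N - n_h)
  cw <- cumsum(w) / n_r
  gaps <- (pos - seq_len(n_h)) * d      # miss decrement accumulated before hit i
  at_hit <- cw - gaps                   # value just after hit i
  before_hit <- c(0, cw[-n_h]) - gaps   # value just before hit i
  top <- max(at_hit)
  bot <- min(before_hit, 0)
  if (top >= -bot) top else bot
}

#' Gene-permutation null sample of enrichment scores
#'
#' Each permutation draws a uniform random member set of `effective_size`
#' positions from the ranked list (without replacement) and records its
#' enrichment score; equivalent to permuting gene labels. Chosen over
#' sample-label permutation because 3-4 ratio columns make the latter
#' degenerate.
#'
#' @param ranked a [ranked_list()].
#' @param effective_size member count to draw; must be strictly inside
#'   (0, N - 1].
#' @param params a [gsea_params()].
#' @return numeric vector of `n_permutations` null enrichment scores.
#' @export
gene_permutation_null <- function(ranked, effective_size, params = gsea_params()) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (effective_size < 1L || effective_size >= ranked$N)
    stop("effective_size must be in [1, N - 1)")
  w_all <- abs(ranked$metric)^params$weight_p
  with_seed(params$seed, {
    vapply(seq_len(params$n_permutations), function(b) {
      es_from_positions(sort(sample.int(ranked$N, effective_size)),
                        w_all, ranked$N)
    }, numeric(1L))
  })
}

#' Leading-edge members of a gene set
#'
#' The subset of members that contributes to the enrichment score: for
#' positive ES the members at positions up to and including the running-sum
#' peak; for negative ES the members strictly after the peak through the end
#' of the list. Order follows the ranked list.
#'
#' @param ranked a [ranked_list()].
#' @param members member IDs.
#' @param running_profile,peak_index from [enrichment_score()].
#' @param es_sign sign of the enrichment score (+1 or -1).
#' @return character vector of leading-edge member IDs in ranked order.
#' @export
leading_edge <- function(ranked, members, running_profile, peak_index, es_sign) {
  if (es_sign == 0) stop("leading edge undefined for ES = 0")
  pos <- which(ranked$ids %in% members)
  keep <- if (es_sign > 0) pos <= peak_index else pos > peak_index
  ranked$ids[pos[keep]]
}

#' Run GSEA over a collection of gene sets
#'
#' Sets falling outside `[min_size, max_size]` after intersection with the
#' ranked list are excluded (logged). For each surviving set the observed
#' enrichment score is compared with a gene-permutation null:
#' `nominal_p` is the fraction of same-signed null scores at least as
#' extreme; `NES = ES / mean(|same-signed null ES|)`; `fdr_q` follows the
#' standard GSEA ratio of permuted-vs-observed tail fractions over
#' same-signed NES, clipped to [0, 1]. With a single tested set,
#' `fdr_q = nominal_p`.
#'
#' @param ranked a [ranked_list()].
#' @param sets list of [gene_set()] objects.
#' @param params a [gsea_params()].
#' @return object of class `gsea`: `results` data frame (one row per set),
#'   plus `leading_edges`, `profiles`, `null_es`, `excluded`, `params`,
#'   `ranked`.
#' @export
run_gsea <- function(ranked, sets, params = gsea_params()) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (inherits(sets, "gene_set")) sets <- list(sets)
  eff <- vapply(sets, function(s) sum(ranked$ids %in% s$members), integer(1L))
  names(eff) <- vapply(sets, `[[`, character(1L), "name")
  keep <- eff >= params$min_size & eff <= params$max_size & eff < ranked$N
  if (any(!keep))
    message("excluded ", sum(!keep), " gene set(s) outside size bounds: ",
            paste(names(eff)[!keep], collapse = ", "))
  if (!any(keep))
    stop("no gene set survives size filtering [", params$min_size, ", ",
         params$max_size, "]; excluded: ",
         paste(sprintf("%s (n=%d)", names(eff), eff), collapse = ", "))
  sets <- sets[keep]; eff <- eff[keep]
  w_all <- abs(ranked$metric)^params$weight_p

  res <- vector("list", length(sets))
  les <- profiles <- nulls <- vector("list", length(sets))
  with_seed(params$seed, {
    for (i in seq_along(sets)) {
      s <- sets[[i]]
      sc <- enrichment_score(ranked, s$members, params$weight_p)
      null_es <- vapply(seq_len(params$n_permutations), function(b) {
        es_from_positions(sort(sample.int(ranked$N, eff[i])), w_all, ranked$N)
      }, numeric(1L))
      same <- null_es[sign(null_es) == sign(sc$es)]
      nominal_p <- if (length(same)) mean(abs(same) >= abs(sc$es))
                   else 1 / (params$n_permutations + 1)
      denom <- mean(abs(same))
      nes <- if (length(same) && denom > 0) sc$es / denom else NA_real_
      le <- leading_edge(ranked, s$members, sc$running_profile,
                         sc$peak_index, sign(sc$es))
      res[[i]] <- data.frame(set = s$name, effective_size = eff[i],
                             es = sc$es, nes = nes, nominal_p = nominal_p,
                             peak_index = sc$peak_index,
                             n_leading_edge = length(le),
                             stringsAsFactors = FALSE)
      les[[i]] <- le
      profiles[[i]] <- sc$running_profile
      nulls[[i]] <- null_es
    }
  })
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  results$fdr_q <- gsea_fdr(results$nes, nulls, results$nominal_p)
  names(les) <- names(profiles) <- names(nulls) <- results$set
  structure(list(results = results, leading_edges = les, profiles = profiles,
                 null_es = nulls, excluded = names(keep)[!keep],
                 params = params, ranked = ranked),
            class = "gsea")
}

# FDR q per the standard GSEA procedure: per-set nulls are normalized by the
# mean absolute same-signed null, pooled, and compared tail-to-tail with the
# observed NES of the same sign. Single tested set falls back to nominal p.
gsea_fdr <- function(nes_obs, nulls, nominal_p) {
  n_sets <- length(nes_obs)
  if (n_sets == 1L) return(pmin(nominal_p, 1))
  null_nes <- unlist(lapply(nulls, function(ne) {
    pos <- ne[ne > 0]; neg <- ne[ne < 0]
    c(if (length(pos)) pos / mean(pos),
      if (length(neg)) neg / abs(mean(neg)))
  }), use.names = FALSE)
  q <- vapply(seq_len(n_sets), function(i) {
    s <- nes_obs[i]
    if (is.na(s)) return(NA_real_)
    same_null <- null_nes[sign(null_nes) == sign(s)]
    same_obs <- nes_obs[!is.na(nes_obs) & sign(nes_obs) == sign(s)]
    num <- if (length(same_null)) mean(abs(same_null) >= abs(s)) else 0
    den <- mean(abs(same_obs) >= abs(s))
    if (den == 0) 0 else num / den
  }, numeric(1L))
  pmin(pmax(q, 0), 1)
}

#' @export
print.gsea <- function(x, ...) {
  cat(sprintf("<gsea> %d set(s) tested on a ranked list of N = %d (%d permutations)\n",
              nrow(x$results), x$ranked$N, x$params$n_permutations))
  print(x$results[order(x$results$nominal_p),
                  c("set", "effective_size", "es", "nes", "nominal_p", "fdr_q")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.gsea <- function(object, fdr_threshold = 0.25, ...) {
  r <- object$results
  cat(sprintf("%d / %d set(s) at FDR q <= %.2f\n",
              sum(r$fdr_q <= fdr_threshold, na.rm = TRUE), nrow(r),
              fdr_threshold))
  invisible(r)
}

#' Enrichment plot (running-sum profile with member positions)
#'
#' @param x a `gsea` object.
#' @param set set name or index to plot.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.gsea <- function(x, set = 1L, ...) {
  if (is.character(set)) set <- match(set, x$results$set)
  profile <- x$profiles[[set]]
  pos <- which(x$ranked$ids %in% x$leading_edges[[set]])
  graphics::plot(seq_along(profile), profile, type = "l",
                 xlab = "rank in list", ylab = "running enrichment score",
                 main = x$results$set[set], ...)
  graphics::abline(h = 0, lty = 3)
  graphics::rug(pos)
  invisible(x)
}
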