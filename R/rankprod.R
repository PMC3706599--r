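#' Per-column differential-expression ranks
#'
#' Within each log2-ratio column, non-missing entities are ranked 1..m with
#' rank 1 the most extreme in the requested direction: descending log-ratio
#' for `up_in_invasive`, ascending for `up_in_angiogenic`. Ties receive
#' average ranks; missing entries carry no rank.
#'
#' @param matrix an `expr_matrix` with `value_kind = "log2_ratio"`.
#' @param direction `"up_in_invasive"` or `"up_in_angiogenic"`.
#' @return numeric matrix of ranks (NA where the value was missing) with a
#'   `direction` attribute.
#' @export
rank_columns <- function(matrix, direction) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$value_kind != "log2_ratio")
    stop("rank_columns expects log2 ratios")
  direction <- match.arg(direction, c("up_in_invasive", "up_in_angiogenic"))
  sgn <- if (direction == "up_in_invasive") -1 else 1
  v <- matrix$values
  rt <- v
  for (j in seq_len(ncol(v))) {
    ok <- !is.na(v[, j])
    if (sum(ok) < 2L)
      stop("column '", colnames(v)[j], "' has fewer than 2 non-missing values")
    rt[ok, j] <- rank(sgn * v[ok, j], ties.method = "average")
  }
  attr(rt, "direction") <- direction
  rt
}

#' Rank Product statistic
#'
#' The Rank Product of an entity is the geometric mean of its available
#' per-column ranks, `(prod r_i)^(1/k_g)` over the k_g columns where it was
#' observed; small values indicate consistent extreme ranking. Entities are
#' then ordered ascending by Rank Product (stable, input order breaks ties).
#'
#' @param rank_table a matrix from [rank_columns()].
#' @return data frame of class `rp_result` with columns `entity`, `rp_value`,
#'   `k_columns`, `overall_rank`; significance fields are added by
#'   [estimate_pfp()].
#' @export
rank_product <- function(rank_table) {
  k_g <- rowSums(!is.na(rank_table))
  if (any(k_g == 0L))
    stop("entity with no ranked column: '",
         rownames(rank_table)[k_g == 0L][1L], "'")
  rp <- exp(rowSums(log(rank_table), na.rm = TRUE) / k_g)
  overall <- integer(length(rp))
  overall[order(rp)] <- seq_along(rp)  # order() is stable: ties keep row order
  out <- data.frame(entity = rownames(rank_table), rp_value = unname(rp),
                    k_columns = unname(k_g), overall_rank = overall,
                    stringsAsFactors = FALSE)
  attr(out, "direction") <- attr(rank_table, "direction")
  class(out) <- c("rp_result", "data.frame")
  out
}

#' Permutation estimate of the percentage of false prediction (pfp)
#'
#' For each of `n_permutations` permutations, ranks are redrawn uniformly at
#' random within each column over that column's non-missing entities
#' (preserving the missingness pattern, tie-free integer ranks) and the
#' permuted Rank Products are computed identically. The expected false
#' positive count at entity g is the mean number of permuted Rank Products at
#' or below g's observed value, and `pfp = expected_count / overall_rank`
#' (may exceed 1). A monotonized companion `q_monotone` (running minimum from
#' the bottom of the RP ranking, clipped at 1) is reported for thresholding.
#'
#' @param rp an [rank_product()] result.
#' @param rank_table the rank matrix the result was computed from.
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed for reproducibility, or `NULL`.
#' @return the `rp_result` with columns `expected_count`, `pfp`, `q_monotone`
#'   and a `direction`-aware column `direction` added.
#' @export
estimate_pfp <- function(rp, rank_table, n_permutations = 1000, seed = NULL) {
  stopifnot(inherits(rp, "rp_result"), n_permutations >= 1)
  miss <- is.na(rank_table)
  n <- nrow(rank_table); k <- ncol(rank_table)
  m_j <- colSums(!miss)
  k_g <- rowSums(!miss)
  obs <- rp$rp_value
  # tolerance absorbs float noise in exp(mean(log(ranks))) at exact ties
  thr <- obs * (1 + 1e-9)
  counts <- numeric(n)
  nonmiss_idx <- lapply(seq_len(k), function(j) which(!miss[, j]))
  with_seed(seed, {
    lg <- matrix(0, n, k)
    for (b in seq_len(n_permutations)) {
      lg[] <- 0
      for (j in seq_len(k)) {
        idx <- nonmiss_idx[[j]]
        lg[idx, j] <- log(sample.int(m_j[j]))
      }
      rp_b <- exp(rowSums(lg) / k_g)
      counts <- counts + findInterval(thr, sort(rp_b))
    }
  })
  rp$expected_count <- counts / n_permutations
  rp$pfp <- rp$expected_count / rp$overall_rank
  ord <- order(rp$overall_rank)
  q <- monotonize_pfp(rp$pfp[ord])
  rp$q_monotone <- numeric(n)
  rp$q_monotone[ord] <- q
  rp$direction <- attr(rp, "direction") %||% NA_character_
  rp
}

#' @export
print.rp_result <- function(x, ...) {
  cat(sprintf("<rp_result> %d entities%s%s\n", nrow(x),
              if (!is.null(attr(x, "direction")))
                paste0(", direction ", attr(x, "direction")) else "",
              if ("pfp" %in% names(x)) "" else " (no significance fields yet)"))
  print(utils::head(as.data.frame(x)[order(x$overall_rank), ], 5L))
  invisible(x)
}

#' @export
summary.rp_result <- function(object, q_thresholds = c(0.3, 0.5), ...) {
  if (!"pfp" %in% names(object))
    stop("run estimate_pfp() first")
  counts <- vapply(q_thresholds,
                   function(q) length(top_list(object, q)), integer(1L))
  out <- data.frame(q_threshold = q_thresholds, n_entities = counts)
  cat("Rank Product top-list sizes (monotonized q):\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' Significant top list at a q-value threshold
#'
#' Entities whose q-value does not exceed the threshold, ordered by overall
#' Rank Product rank. Thresholding uses the monotonized pfp by default (so
#' the selected list is always a prefix of the RP ranking); set
#' `monotone = FALSE` to threshold the raw pfp.
#'
#' @param rp an `rp_result` with significance fields.
#' @param q_threshold q-value cut-off (a fraction; e.g. 0.5 for q = 50%).
#' @param monotone use `q_monotone` (default) or raw `pfp`.
#' @return character vector of entity IDs (possibly empty).
#' @export
top_list <- function(rp, q_threshold, monotone = TRUE) {
  if (!"pfp" %in% names(rp)) stop("run estimate_pfp() first")
  q <- if (monotone) rp$q_monotone else rp$pfp
  sel <- rp[q <= q_threshold, , drop = FALSE]
  sel$entity[order(sel$overall_rank)]
}

#' Two-step Rank Product meta-analysis
#'
#' Given per-layer Rank Product results and a 1:1 pairing of entities across
#' layers, the two overall ranks of each pair (re-densified to 1..M within
#' the matched subset) feed a second Rank Product step:
#' `meta_rp = sqrt(rank_a * rank_b)`, with significance from the same
#' permutation scheme over the two rank columns. Identifies pairs highly
#' ranked in both layers.
#'
#' @param result_a,result_b `rp_result` objects for the two layers.
#' @param pairing data frame with columns `id_a`, `id_b` (injective).
#' @param n_permutations,seed passed to the permutation step.
#' @return data frame of class `meta_rp_result` with per-pair `rank_a`,
#'   `rank_b`, `meta_rp`, `meta_rank`, `expected_count`, `meta_pfp`,
#'   `q_monotone`.
#' @export
meta_rank_product <- function(result_a, result_b, pairing,
                              n_permutations = 1000, seed = NULL) {
  stopifnot(inherits(result_a, "rp_result"), inherits(result_b, "rp_result"))
  if (anyDuplicated(pairing$id_a) || anyDuplicated(pairing$id_b))
    stop("pairing must be injective")
  ia <- match(pairing$id_a, result_a$entity)
  ib <- match(pairing$id_b, result_b$entity)
  if (anyNA(ia)) stop("pairing references unknown entity: '",
                      pairing$id_a[is.na(ia)][1L], "'")
  if (anyNA(ib)) stop("pairing references unknown entity: '",
                      pairing$id_b[is.na(ib)][1L], "'")
  ra <- rank(result_a$overall_rank[ia])  # re-densify to 1..M
  rb <- rank(result_b$overall_rank[ib])
  rt <- cbind(rank_a = ra, rank_b = rb)
  rownames(rt) <- paste(pairing$id_a, pairing$id_b, sep = "|")
  meta <- rank_product(rt)
  meta <- estimate_pfp(meta, rt, n_permutations = n_permutations, seed = seed)
  out <- data.frame(id_a = pairing$id_a, id_b = pairing$id_b,
                    rank_a = ra, rank_b = rb,
                    meta_rp = meta$rp_value, meta_rank = meta$overall_rank,
                    expected_count = meta$expected_count,
                    meta_pfp = meta$pfp, q_monotone = meta$q_monotone,
                    stringsAsFactors = FALSE)
  class(out) <- c("meta_rp_result", "data.frame")
  out
}
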