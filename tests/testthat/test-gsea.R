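test_that("log-fold ranking averages available columns with stable ties", {
  m <- em(rbind(A = c(2, 0), B = c(1, 1), C = c(-1, -1)))
  r <- rank_by_logfold(m)
  expect_equal(r$ids, c("A", "B", "C"))  # tie at 1 keeps input order
  expect_equal(r$metric, c(1, 1, -1))

  single <- em(cbind(x = c(0.3, -0.2, 1.5)))
  expect_equal(rank_by_logfold(single)$ids, c("e3", "e1", "e2"))

  neg <- em(rbind(A = c(2, 0), B = c(1, 1), C = c(-1, -1)) * -1)
  expect_equal(rank_by_logfold(neg)$ids, c("C", "A", "B"))  # stable tie at -1
})

test_that("negating the matrix reverses the log-fold order exactly", {
  set.seed(21)
  v <- matrix(rnorm(40), 10, 4)
  v[sample(40, 5)] <- NA
  v <- v[rowSums(!is.na(v)) > 0, ]
  r1 <- rank_by_logfold(em(v))
  r2 <- rank_by_logfold(em(-v))
  # distinct metrics almost surely: reversal is exact
  expect_equal(r2$ids, rev(r1$ids))
})

test_that("enrichment score reproduces hand-computed running sums", {
  # N = 5, equal weights, members at positions 1 and 3
  r <- ranked_list(paste0("g", 1:5), c(1, 1, 1, 1, 1) * 2)
  sc <- enrichment_score(r, c("g1", "g3"), weight_p = 1)
  expect_equal(sc$running_profile, c(1/2, 1/6, 2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(sc$es, 2/3, tolerance = 1e-12)
  expect_equal(sc$peak_index, 3L)

  # single member at rank 1: maximal enrichment
  sc1 <- enrichment_score(r, "g1")
  expect_equal(sc1$es, 1.0)

  # single member at rank N with equal weights: ES = -1 just before the hit
  r4 <- ranked_list(paste0("g", 1:4), rep(1, 4))
  sc4 <- enrichment_score(r4, "g4")
  expect_equal(sc4$running_profile, c(-1/3, -2/3, -1, 0), tolerance = 1e-12)
  expect_equal(sc4$es, -1.0)
  expect_equal(sc4$peak_index, 3L)
})

test_that("running sum telescopes to zero and ES guards hold", {
  set.seed(31)
  r <- ranked_list(paste0("g", 1:50), sort(rnorm(50), decreasing = TRUE))
  sc <- enrichment_score(r, sample(r$ids, 12))
  expect_equal(sc$running_profile[50], 0, tolerance = 1e-9)
  expect_equal(abs(sc$es), max(abs(sc$running_profile)))

  expect_error(enrichment_score(r, "absent"), "does not intersect")
  expect_error(enrichment_score(r, r$ids), "whole ranked list")
  rz <- ranked_list(c("a", "b", "c"), c(0, 0, 0))
  expect_error(enrichment_score(rz, "a"), "N_R = 0")
})

test_that("enrichment score equals the brute-force oracle and the KS statistic", {
  set.seed(101)
  for (i in 1:40) {
    N <- sample(10:60, 1)
    ids <- paste0("g", seq_len(N))
    metric <- sort(rnorm(N), decreasing = TRUE)
    members <- sample(ids, sample(2:(N - 2), 1))
    r <- ranked_list(ids, metric)
    sc <- enrichment_score(r, members, weight_p = 1)
    bf <- brute_force_es(ids, metric, members, weight_p = 1)
    expect_equal(sc$es, bf$es, tolerance = 1e-12)
    expect_equal(sc$running_profile, bf$profile, tolerance = 1e-12)

    # weight 0 reduces to the two-sample KS statistic of hit vs miss positions
    sc0 <- enrichment_score(r, members, weight_p = 0)
    pos <- which(ids %in% members)
    ks <- suppressWarnings(
      stats::ks.test(pos, setdiff(seq_len(N), pos))$statistic)
    expect_equal(abs(sc0$es), unname(ks), tolerance = 1e-12)
  }
})

test_that("ES is invariant under positive rescaling of the metric", {
  set.seed(41)
  r1 <- ranked_list(paste0("g", 1:30), sort(rnorm(30), decreasing = TRUE))
  r2 <- ranked_list(r1$ids, 7.3 * r1$metric)
  members <- sample(r1$ids, 8)
  expect_equal(enrichment_score(r1, members)$es,
               enrichment_score(r2, members)$es, tolerance = 1e-12)
})

test_that("reversing a symmetric instance negates the ES", {
  # equal weights and a set placed symmetrically about the centre
  r <- ranked_list(paste0("g", 1:10), rep(1, 10))
  members <- c("g1", "g2")
  fwd <- enrichment_score(r, members)
  rrev <- ranked_list(rev(r$ids), rep(1, 10))
  bwd <- enrichment_score(rrev, members)
  expect_equal(bwd$es, -fwd$es, tolerance = 1e-12)
})

test_that("leading edge follows the peak on either side", {
  r <- ranked_list(paste0("g", 1:5), rep(2, 5))
  sc <- enrichment_score(r, c("g1", "g3"))
  expect_equal(leading_edge(r, c("g1", "g3"), sc$running_profile,
                            sc$peak_index, sign(sc$es)),
               c("g1", "g3"))
  sc1 <- enrichment_score(r, "g1")
  expect_equal(leading_edge(r, "g1", sc1$running_profile, sc1$peak_index, 1),
               "g1")
  r4 <- ranked_list(paste0("g", 1:4), rep(1, 4))
  sc4 <- enrichment_score(r4, "g4")
  expect_equal(leading_edge(r4, "g4", sc4$running_profile, sc4$peak_index,
                            sign(sc4$es)),
               "g4")
})

test_that("gene-permutation null is seeded, centred and guarded", {
  set.seed(51)
  r <- ranked_list(paste0("g", 1:200), sort(rnorm(200), decreasing = TRUE))
  p <- gsea_params(n_permutations = 400, seed = 7)
  null1 <- gene_permutation_null(r, 25, p)
  null2 <- gene_permutation_null(r, 25, p)
  expect_identical(null1, null2)
  expect_lt(abs(mean(null1)), 0.1)  # symmetric metric: null ES near 0
  expect_error(gene_permutation_null(r, 200, p), "effective_size")
})

test_that("run_gsea filters by size, finds planted sets and is deterministic", {
  set.seed(61)
  N <- 300
  metric <- sort(rnorm(N), decreasing = TRUE)
  r <- ranked_list(paste0("g", seq_len(N)), metric)
  planted <- r$ids[1:25]             # top of the list by construction
  random_set <- sample(r$ids, 25)
  sets <- list(gene_set("planted", planted),
               gene_set("random", random_set),
               gene_set("tiny", r$ids[c(2, 9)]))
  p <- gsea_params(n_permutations = 300, seed = 17)
  expect_message(g <- run_gsea(r, sets, p), "excluded 1")
  expect_equal(nrow(g$results), 2L)
  planted_row <- g$results[g$results$set == "planted", ]
  expect_gt(planted_row$es, 0)
  expect_lt(planted_row$fdr_q, 0.05)
  expect_equal(g$leading_edges$planted,
               leading_edge(r, planted, g$profiles$planted,
                            planted_row$peak_index, 1))

  g2 <- suppressMessages(run_gsea(r, sets, p))
  expect_identical(g$results, g2$results)

  expect_error(suppressMessages(
    run_gsea(r, list(gene_set("tiny", r$ids[c(2, 9)])), p)),
    "no gene set survives")

  # single tested set: fdr_q equals nominal p
  g1 <- run_gsea(r, list(gene_set("planted", planted)), p)
  expect_equal(g1$results$fdr_q, g1$results$nominal_p)
})

test_that("implementation agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(71)
  for (i in 1:10) {
    N <- sample(50:150, 1)
    metric <- sort(rnorm(N), decreasing = TRUE)
    ids <- paste0("g", seq_len(N))
    members <- sample(ids, sample(5:20, 1))
    r <- ranked_list(ids, metric)
    mine <- enrichment_score(r, members, weight_p = 1)$es
    stats_named <- stats::setNames(metric, ids)
    ref <- fgsea::calcGseaStat(stats_named,
                               selectedStats = which(ids %in% members),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})
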