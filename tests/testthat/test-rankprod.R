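test_that("per-column ranking honours direction, average ties and missingness", {
  m <- em(cbind(r1 = c(2.0, 1.0, 0.5)))
  expect_equal(unname(rank_columns(m, "up_in_invasive")[, 1]), c(1, 2, 3))
  expect_equal(unname(rank_columns(m, "up_in_angiogenic")[, 1]), c(3, 2, 1))

  tied <- em(cbind(r1 = c(1.0, 1.0, 0.5)))
  expect_equal(unname(rank_columns(tied, "up_in_invasive")[, 1]),
               c(1.5, 1.5, 3))

  holes <- em(cbind(r1 = c(1, NA, 2), r2 = c(NA, 1, 0)))
  rt <- rank_columns(holes, "up_in_invasive")
  expect_true(is.na(rt[2, 1]) && is.na(rt[1, 2]))

  thin <- em(cbind(r1 = c(1, NA, NA), r2 = c(1, 2, 3)))
  expect_error(rank_columns(thin, "up_in_invasive"), "fewer than 2")
})

test_that("rank product is the geometric mean of available ranks, stably ordered", {
  rt <- rbind(A = c(1, 2), B = c(2, 1), C = c(3, 3))
  attr(rt, "direction") <- "up_in_invasive"
  rp <- rank_product(rt)
  expect_equal(rp$rp_value, c(sqrt(2), sqrt(2), 3), tolerance = 1e-12)
  expect_equal(rp$overall_rank, c(1L, 2L, 3L))  # stable tie: input order

  best <- rank_product(rbind(A = c(1, 1, 1), B = c(2, 3, 2)))
  expect_equal(best$rp_value[1], 1.0)

  single <- rank_product(rbind(A = c(5, NA), B = c(1, 1)))
  expect_equal(single$rp_value[1], 5.0)
  expect_equal(single$k_columns, c(1L, 2L))
})

test_that("rank product depends only on ranks (monotone-transform invariance)", {
  set.seed(11)
  v <- matrix(rnorm(40), 10, 4)
  m1 <- em(v)
  m2 <- em(sign(v) * abs(v)^3 + 2 * v)  # strictly increasing transform
  rp1 <- rank_product(rank_columns(m1, "up_in_invasive"))
  rp2 <- rank_product(rank_columns(m2, "up_in_invasive"))
  expect_equal(rp1$rp_value, rp2$rp_value)
})

test_that("negating all log ratios swaps the two direction results", {
  set.seed(12)
  v <- matrix(rnorm(30), 10, 3)
  up <- rank_product(rank_columns(em(v), "up_in_invasive"))
  down <- rank_product(rank_columns(em(-v), "up_in_angiogenic"))
  expect_equal(up$rp_value, down$rp_value)
  expect_equal(up$overall_rank, down$overall_rank)
})

test_that("pfp estimation is seed-reproducible and internally consistent", {
  set.seed(5)
  m <- em(matrix(rnorm(60), 20, 3))
  rt <- rank_columns(m, "up_in_invasive")
  rp <- rank_product(rt)
  a <- estimate_pfp(rp, rt, n_permutations = 50, seed = 99)
  b <- estimate_pfp(rp, rt, n_permutations = 50, seed = 99)
  expect_identical(a$pfp, b$pfp)
  expect_equal(a$pfp, a$expected_count / a$overall_rank)
  # monotone companion is non-increasing down the RP ranking and capped at 1
  ord <- order(a$overall_rank)
  expect_true(all(diff(a$q_monotone[ord]) >= 0 - 1e-12) ||
              !is.unsorted(a$q_monotone[ord]))
  expect_true(all(a$q_monotone <= 1))
})

test_that("top_list filters by q threshold in rank order", {
  rp <- structure(data.frame(entity = c("a", "b", "c"),
                             rp_value = c(1, 2, 3), k_columns = 2L,
                             overall_rank = 1:3,
                             expected_count = c(0.1, 0.8, 1.8),
                             pfp = c(0.1, 0.4, 0.6),
                             q_monotone = c(0.1, 0.4, 0.6)),
                  class = c("rp_result", "data.frame"))
  expect_equal(top_list(rp, 0.5), c("a", "b"))
  expect_equal(top_list(rp, 0), character())
  expect_equal(top_list(rp, 1e9), c("a", "b", "c"))
})

test_that("meta rank product matches its closed forms and validates pairing", {
  rp_a <- rank_product(rbind(x1 = c(1, 1), x2 = c(2, 2), x3 = c(3, 3),
                             x4 = c(4, 4), x5 = c(5, 5), x6 = c(6, 6),
                             x7 = c(7, 7), x8 = c(8, 8)))
  rp_b <- rank_product(rbind(y1 = c(1, 1), y2 = c(8, 8), y3 = c(2, 2),
                             y4 = c(3, 3), y5 = c(4, 4), y6 = c(5, 5),
                             y7 = c(6, 6), y8 = c(7, 7)))
  pairing <- data.frame(id_a = paste0("x", 1:8), id_b = paste0("y", 1:8))
  meta <- meta_rank_product(rp_a, rp_b, pairing, n_permutations = 10, seed = 1)
  # pair ranked (1,1) -> meta_rp 1; pair ranked (2,8) -> sqrt(16) = 4
  expect_equal(meta$meta_rp[1], 1.0)
  expect_equal(meta$meta_rp[2], 4.0)
  expect_true(all(meta$meta_rp >= 1))

  bad <- data.frame(id_a = "nope", id_b = "y1")
  expect_error(meta_rank_product(rp_a, rp_b, bad, 10, 1), "unknown entity")
  dup <- data.frame(id_a = c("x1", "x1"), id_b = c("y1", "y2"))
  expect_error(meta_rank_product(rp_a, rp_b, dup, 10, 1), "injective")
})
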