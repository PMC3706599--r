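mini_table <- function() {
  mapping_table(data.frame(
    source_id = c("MBP", "RN_24547", "P001", "P002", "P002", "T1", "T2", "T3"),
    source_ns = c("swissprot", "rat_entrez", rep("swissprot", 3),
                  rep("probe", 3)),
    target_id = c("RN_24547", "4155", "100", "200", "300", "100", "200", "400"),
    target_ns = c("rat_entrez", rep("human_entrez", 7)),
    link_path = c("swissprot->rat_entrez", "rat_entrez->human_entrez",
                  rep("swissprot->human_entrez", 3),
                  rep("probe->human_entrez", 3)),
    species_origin = c("rat", "rat", rep("human", 6)),
    stringsAsFactors = FALSE))
}

test_that("identifier mapping follows chained link paths (rat homolog route)", {
  tbl <- mini_table()
  m <- map_identifiers("MBP", tbl,
                       c("swissprot->rat_entrez", "rat_entrez->human_entrez"))
  expect_equal(m$targets[[1]], "4155")
  expect_false(m$unmapped[1])
})

test_that("mapping preserves order/length, flags unmapped, unions targets", {
  tbl <- mini_table()
  ids <- c("P002", "GHOST", "P001")
  m <- map_identifiers(ids, tbl, "swissprot->human_entrez")
  expect_equal(m$source_id, ids)
  expect_setequal(m$targets[[1]], c("200", "300"))  # many-to-many kept
  expect_true(m$unmapped[2])
  expect_equal(attr(m, "n_unmapped"), 1L)
  expect_equal(nrow(m), 3L)

  expect_error(map_identifiers("P001", tbl, "no->such"), "unknown link_path")
  expect_error(map_identifiers("P001", tbl, character()), "non-empty")
})

test_that("build_gene_set deduplicates targets and rejects empty maps", {
  tbl <- mini_table()
  m <- map_identifiers(c("T1", "T2", "P001"), tbl,
                       list("probe->human_entrez", "swissprot->human_entrez"))
  gs <- build_gene_set(m, "combined")
  expect_setequal(gs$members, c("100", "200"))  # 100 appears twice, kept once

  all_unmapped <- map_identifiers(c("zz", "yy"), tbl, "probe->human_entrez")
  expect_error(build_gene_set(all_unmapped, "none"), "no mapped targets")
})

test_that("matched subsets keep only unique 1:1 correspondences", {
  tbl <- mapping_table(data.frame(
    source_id = c("T1", "T2", "T3", "P1", "P2", "P2", "P3"),
    source_ns = c(rep("probe", 3), rep("swissprot", 4)),
    target_id = c("G1", "G2", "G4", "G1", "G2", "G3", "G4"),
    target_ns = "human_entrez",
    link_path = c(rep("probe->human_entrez", 3),
                  rep("swissprot->human_entrez", 4)),
    species_origin = "human", stringsAsFactors = FALSE))
  a <- em(matrix(rnorm(12), 3, 4, dimnames = list(c("T1", "T2", "T3"), NULL)))
  b <- em(matrix(rnorm(12), 3, 4,
                 dimnames = list(c("P1", "P2", "P3"), NULL)),
          platform = "proteomics")
  ms <- suppressMessages(matched_subsets(a, b, tbl, "probe->human_entrez",
                                         "swissprot->human_entrez"))
  # P2 maps to two genes and is excluded together with its transcript T2
  expect_equal(sort(ms$pairing$gene), c("G1", "G4"))
  expect_equal(nrow(ms$pairing), 2L)
  expect_false(anyDuplicated(ms$pairing$id_a) > 0)
  expect_equal(entity_ids(ms$a), ms$pairing$id_a)

  # identical namespaces and IDs: full pairing
  idt <- mapping_table(data.frame(
    source_id = c("X1", "X2"), source_ns = "probe",
    target_id = c("X1", "X2"), target_ns = "probe",
    link_path = "identity", species_origin = "human",
    stringsAsFactors = FALSE))
  x <- em(matrix(rnorm(8), 2, 4, dimnames = list(c("X1", "X2"), NULL)))
  ms2 <- suppressMessages(matched_subsets(x, x, idt, "identity", "identity"))
  expect_equal(nrow(ms2$pairing), 2L)

  # disjoint universes
  y <- em(matrix(rnorm(8), 2, 4, dimnames = list(c("Z1", "Z2"), NULL)))
  expect_error(suppressMessages(
    matched_subsets(y, x, idt, "identity", "identity")),
    "no 1:1")
})

test_that("count_unique_entities counts distinct non-empty keys", {
  df <- data.frame(k = c("a", "a", "", "b", NA), stringsAsFactors = FALSE)
  expect_equal(count_unique_entities(df, "k"), 2L)
  expect_equal(count_unique_entities(data.frame(k = character()), "k"), 0L)
  expect_equal(count_unique_entities(data.frame(k = rep("x", 5)), "k"), 1L)
  expect_error(count_unique_entities(df, "missing"), "no such column")
})

test_that("mapping table validation rejects empty IDs and missing columns", {
  expect_error(mapping_table(data.frame(source_id = "a")), "lacks column")
  bad <- data.frame(source_id = "", source_ns = "x", target_id = "t",
                    target_ns = "y", link_path = "x->y",
                    species_origin = "human", stringsAsFactors = FALSE)
  expect_error(mapping_table(bad), "empty source or target")
})
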