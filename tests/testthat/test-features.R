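hyd <- ctd_groupings()$hydrophobicity

test_that("amino-acid composition counts occurrences over length", {
  v <- aa_composition("AAAA")
  expect_equal(v[["A"]], 1)
  expect_equal(sum(v), 1)
  expect_equal(unname(aa_composition(paste(AA_ALPHABET20, collapse = ""))),
               rep(0.05, 20))
  v <- aa_composition("AAC")
  expect_equal(unname(v[c("A", "C")]), c(2 / 3, 1 / 3))
  expect_equal(sum(v[setdiff(AA_ALPHABET20, c("A", "C"))]), 0)
})

test_that("group content is the per-group residue fraction", {
  expect_equal(group_content("CCVV", hyd), c(0, 0, 1))
  expect_equal(group_content("RRGG", hyd), c(0.5, 0.5, 0))
  expect_equal(group_content("RGC", hyd), rep(1 / 3, 3))
})

test_that("distribution uses first/quartile/last positions over length", {
  expect_equal(group_distribution("R", hyd),
               c(1, 1, 1, 1, 1, rep(0, 10)))
  expect_equal(group_distribution("GRRRR", hyd)[1:5],
               c(0.4, 0.4, 0.6, 0.8, 1.0))
  # group 3 absent -> five zeros
  expect_equal(group_distribution("GRRRR", hyd)[11:15], rep(0, 5))
})

test_that("dipeptide block counts cross-group adjacent pairs", {
  expect_equal(group_dipeptide("RRRR", hyd), c(0, 0, 0))
  expect_equal(group_dipeptide("RC", hyd), c(0, 0.5, 0))
  expect_equal(group_dipeptide("RGC", hyd), c(1 / 3, 0, 1 / 3))
  expect_equal(group_dipeptide("R", hyd), c(0, 0, 0))
  # optional normalization by the number of pairs L - 1
  expect_equal(group_dipeptide("RC", hyd, normalizer = "pairs"),
               c(0, 1, 0))
})

test_that("the full feature vector has the documented 188-value layout", {
  v <- extract_features("AAAA")
  expect_length(v, 188L)
  expect_identical(names(v), feature_names())
  # composition block: all mass on A
  expect_equal(unname(v[1:20]), c(1, rep(0, 19)))
  # in every grouping A's group gets content 1 and the 1/25/50/75/100%
  # positions of an all-A length-4 sequence; dipeptide blocks all 0
  expected_distr <- c(0.25, 0.25, 0.5, 0.75, 1.0)
  for (g in ctd_groupings()) {
    i <- which(vapply(g$groups, function(gr) "A" %in% gr, TRUE))
    block <- v[grepl(paste0("^", g$name, "_"), names(v))]
    expect_length(block, 21L)
    expect_equal(unname(block[i]), 1)                      # content
    expect_equal(unname(block[3 + (i - 1) * 5 + 1:5]), expected_distr)
    expect_equal(unname(block[19:21]), c(0, 0, 0))         # dipeptide
  }
})

test_that("caller-supplied groupings change the output dimension", {
  v <- extract_features("ACDEFG", groupings = ctd_groupings()[1:2])
  expect_length(v, 20 + 2 * 21)
})

test_that("extractor matches the brute-force oracle on random sequences", {
  set.seed(2024)
  lens <- sample(1:500, 200, replace = TRUE)
  for (L in lens) {
    s <- random_sequence(L)
    expect_equal(unname(extract_features(s)), oracle_features(s),
                 tolerance = 1e-12)
  }
  # both normalizers agree with the oracle
  s <- random_sequence(37)
  expect_equal(unname(extract_features(s, dipeptide_norm = "pairs")),
               oracle_features(s, dipeptide_norm = "pairs"),
               tolerance = 1e-12)
})

test_that("feature vectors satisfy the structural invariants", {
  set.seed(7)
  for (L in sample(1:400, 50)) {
    v <- unname(extract_features(random_sequence(L)))
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(sum(v[1:20]), 1, tolerance = 1e-9)
    for (k in 0:7) {
      block <- v[20 + k * 21 + 1:21]
      expect_equal(sum(block[1:3]), 1, tolerance = 1e-9)   # content
      for (i in 1:3)                                       # distribution
        expect_true(all(diff(block[3 + (i - 1) * 5 + 1:5]) >= 0))
      expect_lte(sum(block[19:21]), (L - 1) / L + 1e-12)   # dipeptide
    }
  }
})

test_that("composition/content are permutation-invariant, distribution/dipeptide are not", {
  a <- "RRRGGGCCC"
  b <- "RGCRGCRGC"   # same multiset of residues, different order
  va <- extract_features(a)
  vb <- extract_features(b)
  expect_equal(va[1:20], vb[1:20])
  content_idx <- grepl("_content", names(va))
  expect_equal(va[content_idx], vb[content_idx])
  expect_false(isTRUE(all.equal(va, vb)))
})

test_that("feature tables carry ids, optional labels, and round-trip", {
  set.seed(11)
  rec <- protein_records(paste0("r", 1:3),
                         vapply(c(30, 40, 50), random_sequence, ""))
  tab <- features_to_table(rec)
  expect_equal(dim(tab), c(3L, 1L + 188L))
  tab2 <- features_to_table(rec, labels = c(1, -1, 1))
  expect_equal(dim(tab2), c(3L, 2L + 188L))
  expect_error(features_to_table(rec, labels = c(1, -1)), "match")

  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(format(tab2, digits = 15), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  back <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(as.matrix(back[, -(1:2)]), as.matrix(tab2[, -(1:2)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
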