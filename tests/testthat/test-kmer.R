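test_that("kmers decomposes tokens into overlapping 3-mers", {
  expect_equal(kmers("abnormal"), c("abn", "bno", "nor", "orm", "rma", "mal"))
  expect_equal(kmers("abnrmal"), c("abn", "bnr", "nrm", "rma", "mal"))
  expect_equal(kmers("actions"), c("act", "cti", "tio", "ion", "ons"))
  expect_equal(kmers("act"), "act")
  expect_error(kmers("ab"), "shorter than k")

  set.seed(3)
  for (i in 1:25) {
    tk <- random_token(sample(3:15, 1))
    expect_length(kmers(tk), nchar(tk) - 2L)
    expect_identical(kmers(tk), oracle_kmers(tk))
  }
})

test_that("pair_transitions aligns by index with the three length scenarios", {
  pt <- pair_transitions("abnormal", "abnrmal")
  expect_equal(pt$transitions$source,
               c("abn", "bno", "nor", "orm", "rma", "mal"))
  expect_equal(pt$transitions$target,
               c("abn", "bnr", "nrm", "rma", "mal", NA))
  expect_equal(pt$transitions$position, 0:5)
  expect_length(pt$unmatched_targets, 0L)

  pt <- pair_transitions("tar", "tar")
  expect_equal(pt$transitions,
               data.frame(position = 0L, source = "tar", target = "tar"))

  pt <- pair_transitions("short", "shorter")
  expect_equal(sum(!is.na(pt$transitions$target)), 3L)
  expect_equal(pt$unmatched_targets, c("rte", "ter"))
})

test_that("classify_transition reproduces the published category examples", {
  expect_equal(classify_transition("met", "ame"), "SHIFT")
  expect_equal(classify_transition("met", "eta"), "SHIFT")
  expect_equal(classify_transition("tar", "atr"), "INVERSION")
  expect_equal(classify_transition("tar", "tra"), "INVERSION")
  expect_equal(classify_transition("tar", "tbr"), "SINGLE_REPLACEMENT")
  expect_equal(classify_transition("tar", "tbc"), "DOUBLE_REPLACEMENT")
  expect_equal(classify_transition("tar", "tba"), "GAP_SHIFT")  # t_a
  expect_equal(classify_transition("tar", "abr"), "GAP_SHIFT")  # a_r
  expect_equal(classify_transition("bno", "atr"), "OTHER")
  expect_equal(classify_transition("tar", "tar"), "IDENTITY")
  expect_error(classify_transition("ta", "tar"), "3-character")
})

test_that("classification is total, single-valued, and matches the oracle", {
  # property over random pairs from a 5-letter alphabet (the full
  # 125 x 125 sweep lives in the acceptance suite)
  set.seed(9)
  alpha <- letters[1:5]
  for (i in 1:300) {
    s <- paste(sample(alpha, 3, replace = TRUE), collapse = "")
    t <- paste(sample(alpha, 3, replace = TRUE), collapse = "")
    got <- classify_transition(s, t)
    expect_length(got, 1L)
    expect_true(got %in% error_categories())
    expect_identical(got, oracle_classify(s, t))
  }
  # symmetry holds for IDENTITY and INVERSION
  expect_equal(classify_transition("atr", "tar"), "INVERSION")
  expect_equal(classify_transition("tra", "tar"), "INVERSION")
})

test_that("profile_errors recovers category frequencies", {
  # duplicated-letter edit: downstream transitions are shifts; the two
  # 3-mers spanning the edit site (abn->abb, bno->bbn) match the gap-shift
  # insertion pattern, which precedes SHIFT in the classification order,
  # so SHIFT is dominant but not 1.0
  corp <- data.frame(canonical = "abnormal", typo = "abbnormal")
  prof <- profile_errors(corp)
  expect_equal(prof[["SHIFT"]], 4 / 6)
  expect_equal(prof[["GAP_SHIFT"]], 2 / 6)
  expect_equal(names(which.max(prof)), "SHIFT")
  expect_equal(sum(prof), 1, tolerance = 1e-9)
  expect_true(all(prof >= 0))

  # single adjacent swap somewhere mid-token -> inversion present
  prof <- profile_errors(data.frame(canonical = "tarsal", typo = "trasal"))
  expect_gt(prof[["INVERSION"]], 0)

  expect_error(profile_errors(data.frame(canonical = "tar", typo = "tar")),
               "non-identity")
  expect_error(profile_errors(data.frame(canonical = character(0),
                                         typo = character(0))), "empty")

  # known 50/50 shift/inversion mix, recovered within a few points
  set.seed(14)
  toks <- vapply(1:60, function(i) random_token(8, letters), "")
  rows <- lapply(toks, function(tk) {
    data.frame(
      canonical = tk,
      typo = c(vapply(1:8, function(j) make_typo(tk, "SHIFT"), ""),
               vapply(1:8, function(j) make_typo(tk, "INVERSION"), "")),
      stringsAsFactors = FALSE)
  })
  prof <- profile_errors(do.call(rbind, rows))
  # each shift edit (duplication) produces a run of SHIFT transitions;
  # an inversion edit yields one INVERSION plus neighboring disturbed
  # 3-mers, so SHIFT dominates but both categories are clearly present
  expect_gt(prof[["SHIFT"]], 0.25)
  expect_gt(prof[["INVERSION"]], 0.05)
})

test_that("read_pair_corpus accepts both row dialects", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "abnormal\tabnrmal",
               "actions\ttactions,actons , acions"), path)
  corp <- read_pair_corpus(path)
  expect_equal(nrow(corp), 4L)
  expect_equal(corp$canonical, c("abnormal", rep("actions", 3)))
  expect_equal(corp$typo[2:4], c("tactions", "actons", "acions"))

  writeLines("one_column_only", path)
  expect_error(read_pair_corpus(path), "line 1")
})
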