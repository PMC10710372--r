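test_that("score space endpoints and size match the exact enumeration", {
  m <- worked_example_matrix()
  sp <- build_score_space("abnormal", m)
  expect_equal(sp$method, "EXACT_ENUM")
  expect_equal(sp$min, 0.06)
  expect_equal(sp$max, 2.3)
  expect_length(sp$scores, 7L * 9L * 9L * 8L * 9L * 9L)  # multiset, no dedup
  expect_equal(min(sp$scores), sp$min)
  expect_equal(max(sp$scores), sp$max)
})

test_that("single-position and degenerate spaces", {
  m <- transition_matrix(list(tok = c(a = 0.5, b = 0.3)))
  sp <- build_score_space("tok", m)
  expect_equal(sort(sp$scores), c(0.3, 0.5))
  expect_false(sp$degenerate)

  sp0 <- build_score_space("zzzz", m)
  expect_true(sp0$degenerate)
  expect_equal(c(sp0$min, sp0$max), c(0, 0))
  expect_error(percentile_of(0.1, sp0), "degenerate")
})

test_that("enumeration equals the nested-loop oracle on random toy instances", {
  set.seed(55)
  for (i in 1:10) {
    srcs <- unique(replicate(6, random_token(3)))
    m <- random_toy_matrix(srcs, n_targets = 3)
    tok <- random_token(sample(4:7, 1))
    sp <- build_score_space(tok, m)
    expect_equal(sp$scores, oracle_score_space(tok, m), tolerance = 1e-12)
  }
})

test_that("SAMPLED mode keeps exact endpoints and is seed-deterministic", {
  set.seed(77)
  tok <- random_token(12, letters)
  # rows for the token's own 3-mers so the combination count is large
  m <- random_toy_matrix(unique(kmers(tok)), n_targets = 8,
                         alphabet = letters)
  sp1 <- build_score_space(tok, m, limit = 500)
  expect_equal(sp1$method, "SAMPLED")
  expect_length(sp1$scores, 502L)
  expect_equal(min(sp1$scores), sp1$min)
  expect_equal(max(sp1$scores), sp1$max)
  sp2 <- build_score_space(tok, m, limit = 500)
  expect_identical(sp1$scores, sp2$scores)
})

test_that("percentile_of is the monotone empirical step function", {
  m <- worked_example_matrix()
  sp <- build_score_space("abnormal", m)
  expect_equal(percentile_of(sp$max, sp), 100)
  expect_equal(percentile_of(sp$min - 0.01, sp), 0)
  xs <- seq(sp$min, sp$max, length.out = 40)
  ps <- vapply(xs, percentile_of, 1, space = sp)
  expect_true(all(diff(ps) >= 0))

  two <- transition_matrix(list(tok = c(a = 0.5, b = 0.3)))
  sp2 <- build_score_space("tok", two)
  expect_equal(percentile_of(0.3, sp2), 50)
  expect_equal(percentile_of(0.5, sp2), 100)
})

test_that("cutoff_score honors the policy and its edge percentiles", {
  m <- worked_example_matrix()
  sp <- build_score_space("abnormal", m)
  pol <- cutoff_policy(bands = c("8" = 70))
  cut <- cutoff_score("abnormal", sp, pol)
  # the smallest enumerated sum at or above the 70th percentile
  expect_gte(percentile_of(cut, sp), 70)
  smaller <- max(sp$scores[sp$scores < cut])
  expect_lt(percentile_of(smaller, sp), 70)

  expect_equal(cutoff_score("abnormal", sp, cutoff_policy(c("8" = 100))),
               sp$max)
  expect_equal(cutoff_score("abnormal", sp, cutoff_policy(c("8" = 1e-9))),
               sp$min)

  # non-decreasing in the policy percentile
  cuts <- vapply(c(10, 40, 70, 90), function(p) {
    cutoff_score("abnormal", sp, cutoff_policy(c("8" = p)))
  }, 1)
  expect_true(all(diff(cuts) >= 0))
})

test_that("default policy bands: exact-only below 5, 40/55/70 with length", {
  pol <- cutoff_policy()
  expect_true(is.na(policy_percentile(pol, 3)))
  expect_true(is.na(policy_percentile(pol, 4)))
  expect_equal(policy_percentile(pol, 5), 40)
  expect_equal(policy_percentile(pol, 8), 40)
  expect_equal(policy_percentile(pol, 9), 55)
  expect_equal(policy_percentile(pol, 10), 70)
  expect_equal(policy_percentile(pol, 23), 70)

  path <- withr::local_tempfile(fileext = ".json")
  save_policy(pol, path)
  pol2 <- load_policy(path)
  for (len in 3:12) {
    expect_identical(policy_percentile(pol2, len),
                     policy_percentile(pol, len))
  }
})

test_that("score-space cache round-trips through the quantile grid", {
  m <- worked_example_matrix()
  lex <- toy_lex()
  spaces <- list(abnormal = build_score_space("abnormal", m))
  path <- withr::local_tempfile(fileext = ".tsv")
  save_score_cache(spaces, path, matrix_checksum = "abc123")
  back <- load_score_cache(path, matrix_checksum = "abc123")
  sp <- back[["abnormal"]]
  expect_equal(sp$min, 0.06)
  expect_equal(sp$max, 2.3)
  expect_length(sp$scores, 101L)
  # grid percentiles approximate the full-space percentiles
  expect_lt(abs(percentile_of(1.0, sp) -
                percentile_of(1.0, spaces[["abnormal"]])), 3)
  expect_error(load_score_cache(path, matrix_checksum = "other"),
               "checksum")
})

test_that("policy validation rejects out-of-range percentiles", {
  expect_error(cutoff_policy(bands = c("5" = 0)))
  expect_error(cutoff_policy(bands = c("5" = 101)))
  expect_error(cutoff_policy(default_ge10 = 0))
})
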