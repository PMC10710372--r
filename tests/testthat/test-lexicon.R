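test_that("the toy ontology loads with consistent indexes", {
  lex <- load_ontology(toy_ontology_path())
  # obsolete term dropped, all others kept (no root filter here)
  expect_false("TOY:0000051" %in% names(lex$concepts))
  expect_true("TOY:0000050" %in% names(lex$concepts))

  # every indexed token appears in >= 1 label/synonym token set
  all_label_tokens <- unique(unlist(lapply(lex$concepts, function(cpt) {
    unlist(cpt$token_sets)
  })))
  expect_setequal(names(lex$token_index), all_label_tokens)

  # trigram index covers exactly the token-index keys (all >= 3 chars here)
  indexed <- unique(unlist(lex$trigram_index))
  expect_setequal(indexed, names(lex$token_index))

  # synonyms are tokenized: 'lens opacity' reaches the cataract concept
  expect_true("TOY:0000002" %in% lex$token_index[["opacity"]])
  # alt_id resolves to the primary id
  expect_equal(resolve_alt_id("TOY:0000999", lex), "TOY:0000008")
  expect_equal(resolve_alt_id("TOY:0000008", lex), "TOY:0000008")
})

test_that("root filter restricts concepts to is_a descendants", {
  lex <- load_ontology(toy_ontology_path(), root_filter = "TOY:0000001")
  expect_false("TOY:0000050" %in% names(lex$concepts))  # outside the root
  expect_true("TOY:0000003" %in% names(lex$concepts))   # two levels down
  expect_true(all(vapply(names(lex$concepts), function(id) {
    id == "TOY:0000001" ||
      any(c("TOY:0000001", "TOY:0000012") %in% lex$parents[[id]])
  }, TRUE)))

  lex2 <- load_ontology(toy_ontology_path(), root_filter = "TOY:0000012")
  expect_setequal(names(lex2$concepts),
                  c("TOY:0000012", "TOY:0000003", "TOY:0000006",
                    "TOY:0000009", "TOY:0000011"))

  expect_error(load_ontology(toy_ontology_path(), root_filter = "TOY:9999999"),
               "not found")
})

test_that("empty or unusable ontologies error", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines("format-version: 1.2", path)
  expect_error(load_ontology(path), "no terms")
})

test_that("OBO-graph JSON loads equivalently to OBO", {
  obo <- load_ontology(toy_ontology_path(), root_filter = "TOY:0000001")
  # hand-build the OBO-graph JSON for a subset of the same concepts
  g <- list(graphs = list(list(
    nodes = list(
      list(id = "http://example.org/TOY_0000001",
           lbl = "Phenotypic abnormality", type = "CLASS"),
      list(id = "http://example.org/TOY_0000002", lbl = "Cataract",
           type = "CLASS",
           meta = list(synonyms = list(
             list(pred = "hasExactSynonym", val = "Lens opacity"),
             list(pred = "hasRelatedSynonym", val = "cloudy lens")))),
      list(id = "http://example.org/TOY_0000008", lbl = "Seizure",
           type = "CLASS",
           meta = list(basicPropertyValues = list(
             list(pred = "http://www.geneontology.org/formats/oboInOwl#hasAlternativeId",
                  val = "http://example.org/TOY_0000999"))))),
    edges = list(
      list(sub = "http://example.org/TOY_0000002", pred = "is_a",
           obj = "http://example.org/TOY_0000001"),
      list(sub = "http://example.org/TOY_0000008", pred = "is_a",
           obj = "http://example.org/TOY_0000001")))))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(g, path, auto_unbox = TRUE)
  lex <- load_ontology(path, root_filter = "TOY:0000001")
  expect_setequal(names(lex$concepts),
                  c("TOY:0000001", "TOY:0000002", "TOY:0000008"))
  expect_true("opacity" %in% names(lex$token_index))
  expect_false("cloudy" %in% names(lex$token_index))  # related synonym excluded
  expect_equal(resolve_alt_id("TOY:0000999", lex), "TOY:0000008")
})

test_that("candidates_for matches the brute-force scan and its invariants", {
  lex <- toy_lex()
  vocab <- names(lex$token_index)

  got <- candidates_for("abnrmal", lex, min_shared = 2)
  expect_true("abnormal" %in% got)   # shares abn, rma, mal

  # exact vocabulary token is retrieved for itself, ranked first
  got <- candidates_for("cataract", lex)
  expect_equal(got[[1]], "cataract")

  expect_length(candidates_for("qqqqq", lex), 0L)

  set.seed(88)
  for (i in 1:100) {
    q <- if (i %% 3 == 0) {
      sample(vocab, 1)                        # an indexed token verbatim
    } else if (i %% 3 == 1) {
      make_typo(sample(vocab[nchar(vocab) >= 5], 1),
                sample(c("SHIFT", "SINGLE_REPLACEMENT", "INVERSION"), 1))
    } else {
      random_token(sample(3:10, 1), letters)  # unrelated noise
    }
    ms <- sample(1:3, 1)
    want <- oracle_candidates(q, vocab, ms)
    got <- candidates_for(q, lex, min_shared = ms)
    if (length(want) == 0L) {
      expect_length(got, 0L)
      next
    }
    expect_setequal(as.character(got), names(want))
    if (length(got) > 0) {
      shared <- attr(got, "shared")
      expect_equal(shared, unname(want[got]))
      expect_true(all(diff(shared) <= 0))   # ranked descending
    }
    # superset relation across min_shared
    expect_true(all(candidates_for(q, lex, min_shared = 2) %in%
                    candidates_for(q, lex, min_shared = 1)))
  }
})
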