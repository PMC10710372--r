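# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no transition_value / kmers vectorization tricks): plain
# loops over plain data structures.

# 3-mers by explicit substring loop
oracle_kmers <- function(token) {
  n <- nchar(token)
  out <- character(0)
  for (i in 1:(n - 2)) out <- c(out, substr(token, i, i + 2))
  out
}

# alignment score by explicit position loop
oracle_align <- function(candidate, query, m, profile) {
  sk <- oracle_kmers(candidate)
  qk <- oracle_kmers(query)
  ids <- c()
  for (s in names(m$entries)) {
    if (s %in% names(m$entries[[s]])) ids <- c(ids, m$entries[[s]][[s]])
  }
  mean_id <- if (length(ids)) mean(ids) else 0
  total <- 0
  covered <- 0
  for (i in seq_along(sk)) {
    if (i > length(qk)) next
    row <- m$entries[[sk[i]]]
    if (!is.null(row) && qk[i] %in% names(row)) {
      total <- total + row[[qk[i]]]
      covered <- covered + 1
    } else {
      cat_i <- oracle_classify(sk[i], qk[i])
      f <- if (cat_i == "IDENTITY") 1 else profile[[cat_i]]
      id_i <- if (!is.null(row) && sk[i] %in% names(row)) {
        row[[sk[i]]]
      } else mean_id
      total <- total + f * id_i
    }
  }
  list(value = total, covered = covered)
}

# full score-space enumeration via expand.grid
oracle_score_space <- function(token, m) {
  rows <- list()
  for (s in oracle_kmers(token)) {
    r <- m$entries[[s]]
    rows[[length(rows) + 1]] <- if (is.null(r)) 0 else unname(r)
  }
  grid <- do.call(expand.grid, rows)
  sort(rowSums(as.matrix(grid)))
}

# transition classification by literal predicate re-statement
oracle_classify <- function(s, t) {
  sc <- strsplit(s, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  if (s == t) return("IDENTITY")
  swaps <- c(paste0(sc[2], sc[1], sc[3]),
             paste0(sc[1], sc[3], sc[2]),
             paste0(sc[3], sc[2], sc[1]))
  if (t %in% swaps) return("INVERSION")
  if ((tc[1] == sc[1] && tc[3] == sc[2]) ||
      (tc[1] == sc[2] && tc[3] == sc[3])) return("GAP_SHIFT")
  if ((tc[2] == sc[1] && tc[3] == sc[2]) ||
      (tc[1] == sc[2] && tc[2] == sc[3])) return("SHIFT")
  d <- sum(sc != tc)
  if (d == 1) return("SINGLE_REPLACEMENT")
  if (d == 2) return("DOUBLE_REPLACEMENT")
  "OTHER"
}

# shared distinct 3-mer counts by whole-vocabulary scan
oracle_candidates <- function(query, vocab, min_shared) {
  qk <- unique(oracle_kmers(query))
  counts <- integer(0)
  for (v in vocab) {
    n <- length(intersect(qk, unique(oracle_kmers(v))))
    if (n >= min_shared) counts[v] <- n
  }
  counts
}

# random toy matrix over a small alphabet; rows normalized then optionally
# truncated (mimics a pruned matrix without using build_matrix)
random_toy_matrix <- function(sources, n_targets = 4, alphabet = letters[1:6]) {
  rows <- list()
  for (s in sources) {
    tg <- unique(c(s, replicate(n_targets, paste(sample(alphabet, 3,
                                                        replace = TRUE),
                                                 collapse = ""))))
    p <- runif(length(tg), 0.05, 1)
    p <- p / sum(p)
    names(p) <- tg
    rows[[s]] <- p
  }
  transition_matrix(rows, prune_threshold = 0)
}

random_token <- function(len, alphabet = letters[1:6]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# shared toy-lexicon substrate, built once per test session
toy_lex <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- load_ontology(toy_ontology_path(),
                              root_filter = "TOY:0000001")
    }
    cache
  }
})

# pair corpus of generated typo variants over the toy vocabulary, plus the
# matrix and profile trained from it
toy_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lex <- toy_lex()
      toks <- names(lex$token_index)
      toks <- toks[nchar(toks) >= 5]
      pairs <- do.call(rbind, lapply(toks, function(tk) {
        vs <- gen_typo_errors(tk, typo_spec(seed = 11), n_variants = 25)
        data.frame(canonical = tk, typo = vs, stringsAsFactors = FALSE)
      }))
      m <- build_matrix(pairs)
      cache <<- list(pairs = pairs, matrix = m,
                     profile = profile_errors(pairs),
                     spaces = precompute_score_spaces(lex, m,
                                                     limit = 20000))
    }
    cache
  }
})
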