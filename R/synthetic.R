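#' Introduce a single typographical error of a requested category
#'
#' Edits, by category:
#' \describe{
#'   \item{SHIFT}{duplicate an interior character, shifting the remainder
#'     (e.g. `abnormal -> abbnormal`).}
#'   \item{SINGLE_REPLACEMENT}{replace one character with a different
#'     letter (e.g. `abnormal -> annormal`).}
#'   \item{DOUBLE_REPLACEMENT}{replace two adjacent characters
#'     (e.g. `abnormal -> andnormal`).}
#'   \item{GAP_SHIFT}{insert a random letter at an interior position
#'     (e.g. `abnormal -> abdnormal`).}
#'   \item{INVERSION}{swap two adjacent characters
#'     (e.g. `abnormal -> anbormal`).}
#' }
#' The result always differs from the input, and at least one aligned 3-mer
#' transition of (token, result) classifies to the requested category
#' (verified; a bounded number of redraws guards against precedence
#' reclassification).
#'
#' @param token Lowercase token of length >= 4.
#' @param category One of `SHIFT`, `SINGLE_REPLACEMENT`,
#'   `DOUBLE_REPLACEMENT`, `GAP_SHIFT`, `INVERSION`.
#' @param pos Optional 1-based edit position; drawn at random when `NULL`.
#'   Uses the current RNG stream — `set.seed()` before calling for
#'   reproducibility.
#' @return The perturbed token.
#' @export
make_typo <- function(token, category, pos = NULL) {
  stopifnot(is.character(token), length(token) == 1L)
  token <- tolower(token)
  n <- nchar(token)
  if (n < 4L) stop("token too short to host an edit", call. = FALSE)
  valid <- c("SHIFT", "SINGLE_REPLACEMENT", "DOUBLE_REPLACEMENT",
             "GAP_SHIFT", "INVERSION")
  if (!category %in% valid) {
    stop("category must be one of ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  for (attempt in 1:50) {
    out <- apply_edit(token, category, pos)
    if (is.null(out) || out == token) next
    tr <- pair_transitions(token, out)$transitions
    ok <- !is.na(tr$target)
    cats <- classify_transition(tr$source[ok], tr$target[ok])
    if (category %in% cats) return(out)
  }
  stop("could not realize a ", category, " edit in '", token, "'",
       call. = FALSE)
}

apply_edit <- function(token, category, pos = NULL) {
  n <- nchar(token)
  ch <- strsplit(token, "", fixed = TRUE)[[1L]]
  rnd <- function(exclude) sample(setdiff(letters, exclude), 1L)
  switch(category,
    SHIFT = {
      # duplicate the character at pos; the remainder shifts right, so a
      # downstream 3-mer must exist for a SHIFT transition: pos <= n - 3
      hi <- n - 3L
      if (hi < 1L) return(NULL)
      i <- if (is.null(pos)) sample.int(hi, 1L) else pos
      paste0(substr(token, 1L, i), ch[i], substr(token, i + 1L, n))
    },
    SINGLE_REPLACEMENT = {
      i <- if (is.null(pos)) sample(seq_len(n), 1L) else pos
      ch[i] <- rnd(ch[i])
      paste(ch, collapse = "")
    },
    DOUBLE_REPLACEMENT = {
      i <- if (is.null(pos)) sample(seq_len(n - 1L), 1L) else pos
      ch[i] <- rnd(ch[i])
      ch[i + 1L] <- rnd(ch[i + 1L])
      paste(ch, collapse = "")
    },
    GAP_SHIFT = {                   # insert random letter mid-token
      i <- if (is.null(pos)) sample(2:(n - 1L), 1L) else pos
      paste0(substr(token, 1L, i), rnd(character(0)),
             substr(token, i + 1L, n))
    },
    INVERSION = {                   # adjacent swap
      cand <- which(ch[-n] != ch[-1L])
      if (length(cand) == 0L) return(NULL)
      i <- if (is.null(pos)) cand[sample.int(length(cand), 1L)] else pos
      tmp <- ch[i]; ch[i] <- ch[i + 1L]; ch[i + 1L] <- tmp
      paste(ch, collapse = "")
    })
}

#' Specification for synthetic typo generation
#'
#' @param categories Named non-negative weights over edit categories,
#'   normalized to sum to 1. Default: uniform over shift, single
#'   replacement and inversion — the three categories used when
#'   systematically perturbing ontology labels.
#' @param seed Integer seed.
#' @return A `typo_spec`.
#' @export
typo_spec <- function(categories = c(SHIFT = 1, SINGLE_REPLACEMENT = 1,
                                     INVERSION = 1),
                      seed = 42L) {
  stopifnot(all(categories >= 0), sum(categories) > 0)
  structure(list(categories = categories / sum(categories),
                 seed = as.integer(seed)),
            class = "typo_spec")
}

#' Number of edits per variant for a token length
#'
#' The length-banded rule used when generating typo corpora from ontology
#' labels: 1 error for lengths below 10, 3 for lengths 10-17, 4 for
#' lengths 18 and above.
#'
#' @param len Token length (vectorized).
#' @return Integer edit counts.
#' @export
errors_for_length <- function(len) {
  ifelse(len < 10L, 1L, ifelse(len <= 17L, 3L, 4L))
}

#' Generate typo variants of a token
#'
#' Each variant carries exactly [errors_for_length()] single edits, applied
#' at distinct non-adjacent positions (right-to-left, so earlier edits do
#' not displace later ones), with categories drawn from `spec`. Seed
#' deterministic.
#'
#' @param token Lowercase token of length >= 4.
#' @param spec A `typo_spec`.
#' @param n_variants Number of distinct variants requested (fewer are
#'   returned when the token is too short to host enough distinct edits).
#' @return Character vector of unique variants, none equal to `token`.
#' @export
gen_typo_errors <- function(token, spec = typo_spec(), n_variants = 5L) {
  stopifnot(inherits(spec, "typo_spec"), nchar(token) >= 4L)
  token <- tolower(token)
  n_edits <- errors_for_length(nchar(token))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((spec$seed + sum(utf8ToInt(token))) %% .Machine$integer.max)
  variants <- character(0)
  for (v in seq_len(n_variants * 4L)) {     # oversample, then unique()
    out <- try(one_variant(token, n_edits, spec), silent = TRUE)
    if (inherits(out, "try-error") || is.null(out)) next
    variants <- c(variants, out)
    if (length(unique(variants)) >= n_variants) break
  }
  out <- setdiff(unique(variants), token)
  attr(out, "n_edits") <- n_edits
  out
}

one_variant <- function(token, n_edits, spec) {
  n <- nchar(token)
  # distinct non-adjacent interior positions, applied right-to-left
  avail <- 2:(n - 1L)
  pos <- integer(0)
  for (e in seq_len(n_edits)) {
    ok <- setdiff(avail, c(pos, pos - 1L, pos + 1L))
    if (length(ok) == 0L) return(NULL)
    pos <- c(pos, if (length(ok) == 1L) ok else sample(ok, 1L))
  }
  pos <- sort(pos, decreasing = TRUE)
  cats <- sample(names(spec$categories), n_edits, replace = TRUE,
                 prob = spec$categories)
  out <- token
  for (e in seq_len(n_edits)) {
    nxt <- apply_edit(out, cats[e], pos[e])
    # an inversion of equal characters is a no-op: every edit must change
    # the string so a variant carries exactly n_edits real edits
    if (is.null(nxt) || identical(nxt, out)) {
      nxt <- apply_edit(out, "SINGLE_REPLACEMENT", pos[e])
    }
    out <- nxt
  }
  if (identical(out, token)) NULL else out
}

#' Generate a token-pair corpus with known transition probabilities
#'
#' Oracle generator for matrix-recovery tests. Operates on single-3-mer
#' tokens (length 3) so that each (canonical, typo) pair realizes exactly
#' one transition, drawn i.i.d. from the source's row in
#' `transition_probs` — with longer tokens, overlapping 3-mers would couple
#' the draws and no string could realize arbitrary per-position targets.
#' Rows must place no mass on the identity target: identical pairs are
#' excluded from matrix building, so identity mass could not be recovered.
#'
#' @param vocab Character vector of distinct length-3 source tokens.
#' @param transition_probs Named list: source 3-mer -> named numeric vector
#'   of target probabilities (each row sums to 1; no identity target).
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @return A pair corpus data frame (`canonical`, `typo`) with the
#'   generator parameters attached as attribute `params`.
#' @export
gen_pair_corpus <- function(vocab, transition_probs, n, seed = 1L) {
  stopifnot(n >= 1)
  vocab <- tolower(vocab)
  if (length(vocab) == 0L) stop("empty vocabulary", call. = FALSE)
  if (any(nchar(vocab) != 3L)) {
    stop("gen_pair_corpus vocabulary must consist of length-3 tokens",
         call. = FALSE)
  }
  if (!all(vocab %in% names(transition_probs))) {
    stop("every vocabulary token needs a row in transition_probs",
         call. = FALSE)
  }
  for (s in vocab) {
    row <- transition_probs[[s]]
    if (abs(sum(row) - 1) > 1e-9) {
      stop("row '", s, "' does not sum to 1", call. = FALSE)
    }
    if (s %in% names(row) && row[s] > 0) {
      if (row[s] >= 1) {
        stop("row '", s, "' places all mass on the identity target: no ",
             "non-identical pair can realize it", call. = FALSE)
      }
      stop("row '", s, "' places mass on the identity target; identity ",
           "pairs are excluded from matrix building and cannot be recovered",
           call. = FALSE)
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  canonical <- sample(vocab, n, replace = TRUE)
  typo <- vapply(canonical, function(s) {
    row <- transition_probs[[s]]
    sample(names(row), 1L, prob = row)
  }, "", USE.NAMES = FALSE)
  corpus <- data.frame(canonical = canonical, typo = typo,
                       stringsAsFactors = FALSE)
  attr(corpus, "params") <- list(transition_probs = transition_probs,
                                 n = n, seed = seed)
  corpus
}

#' Systematically replace canonical tokens in annotated documents
#'
#' Every occurrence of a mapped canonical token *inside an annotated span*
#' is replaced by its typo; character offsets of all annotations in the
#' document are recomputed. Replacements never cross span boundaries.
#'
#' @param docs A list of documents, each a list with `doc_id`, `text`, and
#'   `annotations` (data frame: `start`, `end`, `concept_id`; 0-based
#'   half-open).
#' @param typo_map Named character vector: canonical token -> typo.
#' @return The perturbed documents in the same structure.
#' @export
perturb_corpus <- function(docs, typo_map) {
  stopifnot(is.list(docs))
  if (length(typo_map) == 0L) return(docs)
  names(typo_map) <- tolower(names(typo_map))
  lapply(docs, function(doc) {
    text <- doc$text
    anns <- doc$annotations
    ord <- order(anns$start)
    anns <- anns[ord, , drop = FALSE]
    shift <- 0L
    new_text <- text
    for (i in seq_len(nrow(anns))) {
      s <- anns$start[i] + shift
      e <- anns$end[i] + shift
      span <- substring(new_text, s + 1L, e)
      toks <- tokenize(span)
      delta_span <- 0L
      for (j in seq_len(nrow(toks))) {
        repl <- typo_map[toks$surface[j]]
        if (is.na(repl)) next
        t0 <- s + toks$start[j] + delta_span
        t1 <- s + toks$end[j] + delta_span
        new_text <- paste0(substring(new_text, 1L, t0), repl,
                           substring(new_text, t1 + 1L))
        delta_span <- delta_span + nchar(repl) - (t1 - t0)
      }
      anns$start[i] <- s
      anns$end[i] <- e + delta_span
      shift <- shift + delta_span
    }
    anns <- anns[order(ord), , drop = FALSE]
    rownames(anns) <- NULL
    list(doc_id = doc$doc_id, text = new_text, annotations = anns)
  })
}

#' Path to the packaged synthetic toy ontology
#'
#' A small hand-authored OBO fixture (14 concepts under a phenotype root,
#' with multiword labels, an exact synonym, an alt_id, a long biochemical
#' token, and one concept outside the root) standing in for a full
#' phenotype ontology in tests and examples. Entirely synthetic.
#'
#' @return File path of the `.obo` fixture.
#' @export
toy_ontology_path <- function() {
  system.file("extdata", "toy_phenotype_synthetic.obo", package = "tblat",
              mustWork = TRUE)
}
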