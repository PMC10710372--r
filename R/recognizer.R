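#' Link a candidate text span to its best-matching ontology concept
#'
#' Implements entity linkage for a pre-delimited span. The span is reduced
#' to content tokens; each token is resolved to an ontology token — by
#' exact string equality first, otherwise (for tokens of length 5 and more)
#' by fuzzy 3-mer alignment: candidates are seeded through the trigram
#' index, scored with [align_score()], interpreted as percentiles of each
#' candidate's own score space, and kept only when the score clears the
#' length-indexed percentile cut-off. Tokens of length 3-4 resolve exactly
#' only. A concept is returned iff the full content-token multiset of at
#' least one of its labels/synonyms is covered by distinct resolved span
#' tokens, order-insensitive. The concept score is the mean percentile of
#' its matched tokens (100 for exact resolutions); ties prefer the
#' label/synonym with more content tokens, then the smallest concept ID.
#'
#' @param span_text The candidate span (non-empty string).
#' @param lex A `tblat_lexicon`.
#' @param m A `tblat_matrix`.
#' @param spaces Optional named list of precomputed `score_space`s keyed by
#'   ontology token (see [precompute_score_spaces()]); missing spaces are
#'   built on demand.
#' @param policy A `cutoff_policy`; default [cutoff_policy()].
#' @param profile Penalty weights; default [default_error_profile()].
#' @param stoplist Stop words; default packaged list.
#' @return A one-row annotation data frame (`start`, `end`, `concept_id`,
#'   `match_type`, `score`, `matched_text`) or `NULL` when no concept
#'   matches.
#' @export
link_span <- function(span_text, lex, m, spaces = NULL,
                      policy = cutoff_policy(),
                      profile = default_error_profile(),
                      stoplist = load_stopwords()) {
  stopifnot(is.character(span_text), length(span_text) == 1L,
            nzchar(span_text), inherits(lex, "tblat_lexicon"))
  toks <- content_tokens(span_text, min_len = 3L, stoplist = stoplist)
  if (nrow(toks) == 0L) return(NULL)
  res <- resolve_tokens(toks$surface, lex, m, spaces, policy, profile)
  pick_concept(res, toks, lex)
}

# Resolve each span token to (ontology token, percentile, exact flag) or NA.
resolve_tokens <- function(surfaces, lex, m, spaces, policy, profile) {
  out <- data.frame(surface = surfaces,
                    resolved = NA_character_,
                    percentile = NA_real_,
                    exact = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(surfaces)) {
    tok <- surfaces[i]
    if (!is.null(lex$token_index[[tok]])) {
      out$resolved[i] <- tok
      out$percentile[i] <- 100
      out$exact[i] <- TRUE
      next
    }
    if (nchar(tok) < 5L || is.na(policy_percentile(policy, nchar(tok)))) {
      next                       # exact-only lengths: unresolved
    }
    cands <- candidates_for(tok, lex)
    best_tok <- NA_character_
    best_pct <- -Inf
    for (cand in cands) {
      if (is.na(policy_percentile(policy, nchar(cand)))) next
      sp <- spaces[[cand]]
      if (is.null(sp)) sp <- build_score_space(cand, m)
      if (sp$degenerate) next
      sc <- align_score(cand, tok, m, profile)
      cut <- cutoff_score(cand, sp, policy)
      if (is.na(cut) || sc$value < cut) next
      pct <- percentile_of(sc, sp)
      if (pct > best_pct || (pct == best_pct && cand < best_tok)) {
        best_pct <- pct
        best_tok <- cand
      }
    }
    if (!is.na(best_tok)) {
      out$resolved[i] <- best_tok
      out$percentile[i] <- best_pct
    }
  }
  out
}

# Concept decision: some label/synonym's full content-token multiset must be
# covered by distinct resolved span tokens (order-insensitive).
pick_concept <- function(res, toks, lex) {
  resolved <- res$resolved[!is.na(res$resolved)]
  if (length(resolved) == 0L) return(NULL)
  cand_ids <- unique(unlist(lex$token_index[unique(resolved)]))
  best <- NULL
  for (id in sort(cand_ids)) {
    cpt <- lex$concepts[[id]]
    for (ts in cpt$token_sets) {
      cover <- multiset_cover(ts, res)
      if (is.null(cover)) next
      score <- mean(res$percentile[cover])
      exact_all <- all(res$exact[cover])
      key <- list(score = score, ntok = length(ts), id = id)
      if (is.null(best) ||
          score > best$score ||
          (score == best$score && length(ts) > best$ntok) ||
          (score == best$score && length(ts) == best$ntok && id < best$id)) {
        best <- list(score = score, ntok = length(ts), id = id,
                     exact = exact_all, cover = cover)
      }
    }
  }
  if (is.null(best)) return(NULL)
  span_start <- min(toks$start[best$cover])
  span_end <- max(toks$end[best$cover])
  data.frame(start = span_start, end = span_end,
             concept_id = best$id,
             match_type = if (best$exact) "EXACT" else "FUZZY",
             score = best$score,
             matched_text = NA_character_,
             stringsAsFactors = FALSE)
}

# Match every token of `label_tokens` (with multiplicity) to a distinct
# span-token row whose resolution equals it; returns the row indices used,
# or NULL when the multiset is not covered. Greedy matching preferring
# exact resolutions, then higher percentiles.
multiset_cover <- function(label_tokens, res) {
  avail <- which(!is.na(res$resolved))
  ord <- avail[order(-res$exact[avail], -res$percentile[avail])]
  used <- integer(0)
  for (lt in label_tokens) {
    hit <- ord[!(ord %in% used) & res$resolved[ord] == lt]
    if (length(hit) == 0L) return(NULL)
    used <- c(used, hit[1L])
  }
  sort(used)
}

#' Exact-matching baseline linker
#'
#' As [link_span()] but tokens resolve by string equality only (after the
#' same lowercasing/cleansing/stop-word pipeline): the baseline against
#' which fuzzy alignment is compared. A single-character typo in a required
#' token makes the concept unreachable.
#'
#' @inheritParams link_span
#' @return A one-row annotation data frame or `NULL`.
#' @export
exact_match <- function(span_text, lex, stoplist = load_stopwords()) {
  stopifnot(is.character(span_text), length(span_text) == 1L,
            inherits(lex, "tblat_lexicon"))
  if (!nzchar(span_text)) return(NULL)
  toks <- content_tokens(span_text, min_len = 3L, stoplist = stoplist)
  if (nrow(toks) == 0L) return(NULL)
  res <- data.frame(surface = toks$surface, resolved = NA_character_,
                    percentile = NA_real_, exact = FALSE,
                    stringsAsFactors = FALSE)
  known <- toks$surface %in% names(lex$token_index)
  res$resolved[known] <- toks$surface[known]
  res$percentile[known] <- 100
  res$exact[known] <- TRUE
  pick_concept(res, toks, lex)
}

#' Annotate free text with ontology concepts
#'
#' Plumbing convenience around [link_span()]: sentences are split on
#' terminal punctuation and newlines, content tokens located, and every
#' window of 1..`window` contiguous content tokens is offered to the
#' linker. Overlapping hits are resolved longest-match-first (then by
#' score). Boundary detection is heuristic; linkage quality is what the
#' method targets.
#'
#' @inheritParams link_span
#' @param text Document text.
#' @param doc_id Identifier recorded in the output.
#' @param window Maximum window width in content tokens (default 6).
#' @return Annotation data frame: `doc_id`, `start`, `end`, `matched_text`,
#'   `concept_id`, `match_type`, `score` (zero rows when nothing matches).
#' @export
annotate <- function(text, lex, m, spaces = NULL, policy = cutoff_policy(),
                     profile = default_error_profile(),
                     stoplist = load_stopwords(), doc_id = "doc1",
                     window = 6L) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(doc_id = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0),
                      concept_id = character(0), match_type = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  sentences <- locate_sentences(text)
  hits <- list()
  for (si in seq_len(nrow(sentences))) {
    s0 <- sentences$start[si]
    stext <- substring(text, s0 + 1L, sentences$end[si])
    toks <- content_tokens(stext, min_len = 3L, stoplist = stoplist)
    if (nrow(toks) == 0L) next
    n <- nrow(toks)
    for (i in seq_len(n)) {
      for (w in seq_len(min(window, n - i + 1L))) {
        j <- i + w - 1L
        w_start <- toks$start[i]
        w_end <- toks$end[j]
        ann <- link_span(substring(stext, w_start + 1L, w_end),
                         lex, m, spaces, policy, profile, stoplist)
        if (is.null(ann)) next
        ann$start <- s0 + w_start + ann$start
        ann$end <- s0 + w_start + ann$end
        hits[[length(hits) + 1L]] <- ann
      }
    }
  }
  if (length(hits) == 0L) return(empty)
  anns <- do.call(rbind, hits)
  anns <- anns[!duplicated(anns[, c("start", "end", "concept_id")]), ,
               drop = FALSE]
  # longest-match-first, then score, then position
  ord <- order(-(anns$end - anns$start), -anns$score, anns$start)
  anns <- anns[ord, , drop = FALSE]
  taken <- logical(nrow(anns))
  occupied <- rep(FALSE, nchar(text))
  for (i in seq_len(nrow(anns))) {
    idx <- (anns$start[i] + 1L):anns$end[i]
    if (!any(occupied[idx])) {
      taken[i] <- TRUE
      occupied[idx] <- TRUE
    }
  }
  anns <- anns[taken, , drop = FALSE]
  anns <- anns[order(anns$start), , drop = FALSE]
  anns$matched_text <- substring(text, anns$start + 1L, anns$end)
  anns$doc_id <- doc_id
  rownames(anns) <- NULL
  anns[, c("doc_id", "start", "end", "matched_text", "concept_id",
           "match_type", "score")]
}

# Sentence spans (0-based half-open) split on ., !, ?, newlines.
locate_sentences <- function(text) {
  n <- nchar(text)
  brk <- gregexpr("[.!?\n]+", text)[[1L]]
  starts <- 0L
  ends <- integer(0)
  if (brk[1L] != -1L) {
    for (k in seq_along(brk)) {
      e <- as.integer(brk[k]) - 1L
      ends <- c(ends, e)
      starts <- c(starts, e + attr(brk, "match.length")[k])
    }
  }
  ends <- c(ends, n)
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

#' Link pre-delimited spans from a TSV file
#'
#' Reads spans as `doc_id<TAB>start<TAB>end<TAB>text` and links each with
#' [link_span()], the span-linkage evaluation mode.
#'
#' @param spans Data frame with columns `doc_id`, `start`, `end`, `text`,
#'   or a path to such a TSV (with header).
#' @inheritParams link_span
#' @return Annotation data frame (one row per linked span; unlinked spans
#'   are absent).
#' @export
link_spans <- function(spans, lex, m, spaces = NULL,
                       policy = cutoff_policy(),
                       profile = default_error_profile(),
                       stoplist = load_stopwords()) {
  if (is.character(spans)) {
    spans <- utils::read.delim(spans, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("doc_id", "start", "end", "text") %in% names(spans)))
  out <- list()
  for (i in seq_len(nrow(spans))) {
    ann <- link_span(spans$text[i], lex, m, spaces, policy, profile,
                     stoplist)
    if (is.null(ann)) next
    ann$doc_id <- spans$doc_id[i]
    ann$start <- spans$start[i]
    ann$end <- spans$end[i]
    ann$matched_text <- spans$text[i]
    out[[length(out) + 1L]] <- ann
  }
  if (length(out) == 0L) {
    return(data.frame(doc_id = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0),
                      concept_id = character(0), match_type = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  anns <- do.call(rbind, out)
  rownames(anns) <- NULL
  anns[, c("doc_id", "start", "end", "matched_text", "concept_id",
           "match_type", "score")]
}
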