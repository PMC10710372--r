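#' Load an ontology into a lexicon for concept recognition
#'
#' Reads an OBO 1.4 file or an OBO-graph JSON file and builds the lookup
#' structures used by the recognizer: for each non-obsolete concept, its
#' label and exact synonyms are tokenized (lowercased, cleansed, stop words
#' removed) into content-token multisets; a token index maps each unique
#' content token to the concepts using it; and a trigram index maps every
#' 3-mer to the unique tokens containing it, for BLAST-style candidate
#' seeding. `alt_id`s are recorded so retired IDs resolve to their primary
#' concept. With `root_filter` set, only the filter concept and its `is_a`
#' descendants are kept.
#'
#' @param path Path to an `.obo` or OBO-graph `.json` file.
#' @param root_filter Optional concept ID restricting the lexicon to that
#'   concept's `is_a` descendants (inclusive).
#' @param min_len Minimum content-token length kept (default 3, the 3-mer
#'   floor).
#' @param stoplist Stop words removed from labels/synonyms.
#' @return A `tblat_lexicon`: list with `concepts` (named list: concept ID
#'   -> list of `strings` and `token_sets`), `token_index`, `trigram_index`,
#'   `alt_ids` (named character: alt -> primary), `parents` (named list),
#'   `root_filter`.
#' @export
load_ontology <- function(path, root_filter = NULL, min_len = 3L,
                          stoplist = load_stopwords()) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    parse_obograph_json(path)
  } else {
    parse_obo(path)
  }
  if (length(raw$terms) == 0L) {
    stop("ontology at '", path, "' contains no terms", call. = FALSE)
  }
  build_lexicon(raw, root_filter, min_len, stoplist)
}

# Minimal OBO 1.4 stanza reader: id, name, synonym (EXACT only), alt_id,
# is_a, is_obsolete. Deliberately not a general OBO parser.
parse_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[cur$id]] <- cur
    }
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(synonyms = character(0), alt_ids = character(0),
                  parents = character(0))
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {        # [Typedef] etc.
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "name:")) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "alt_id:")) {
      cur$alt_ids <- c(cur$alt_ids, trimws(sub("^alt_id:", "", ln)))
    } else if (startsWith(ln, "is_a:")) {
      id <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, id)
    } else if (startsWith(ln, "synonym:")) {
      m <- regmatches(ln, regexec("^synonym:\\s*\"(.*)\"\\s+EXACT\\b", ln))[[1L]]
      if (length(m) == 2L) cur$synonyms <- c(cur$synonyms, m[2L])
    } else if (startsWith(ln, "is_obsolete:")) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    }
  }
  terms <- flush(cur, terms)
  list(terms = terms)
}

parse_obograph_json <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$graphs) || length(g$graphs) == 0L) {
    stop("not an OBO-graph JSON file: no 'graphs' element", call. = FALSE)
  }
  graph <- g$graphs[[1L]]
  shorten <- function(iri) {
    sub("_", ":", basename(as.character(iri)), fixed = TRUE)
  }
  terms <- list()
  for (node in graph$nodes) {
    if (!is.null(node$type) && node$type != "CLASS") next
    meta <- node$meta
    if (isTRUE(meta$deprecated)) next
    id <- shorten(node$id)
    syns <- character(0)
    alt <- character(0)
    if (!is.null(meta$synonyms)) {
      for (sy in meta$synonyms) {
        if (identical(sy$pred, "hasExactSynonym")) {
          syns <- c(syns, as.character(sy$val))
        }
      }
    }
    if (!is.null(meta$basicPropertyValues)) {
      for (bp in meta$basicPropertyValues) {
        if (grepl("hasAlternativeId", as.character(bp$pred))) {
          alt <- c(alt, shorten(bp$val))
        }
      }
    }
    terms[[id]] <- list(id = id, name = as.character(node$lbl),
                        synonyms = syns, alt_ids = alt,
                        parents = character(0))
  }
  for (edge in graph$edges) {
    if (!identical(edge$pred, "is_a")) next
    sid <- shorten(edge$sub)
    if (!is.null(terms[[sid]])) {
      terms[[sid]]$parents <- c(terms[[sid]]$parents, shorten(edge$obj))
    }
  }
  list(terms = terms)
}

build_lexicon <- function(raw, root_filter, min_len, stoplist) {
  terms <- raw$terms
  parents <- lapply(terms, `[[`, "parents")
  if (!is.null(root_filter)) {
    if (is.null(terms[[root_filter]])) {
      stop("root_filter concept '", root_filter, "' not found in ontology",
           call. = FALSE)
    }
    keep <- descendants_of(root_filter, parents)
    terms <- terms[names(terms) %in% keep]
  }
  alt_ids <- character(0)
  concepts <- list()
  token_index <- list()
  for (id in names(terms)) {
    tm <- terms[[id]]
    strings <- unique(c(tm$name, tm$synonyms))
    strings <- strings[!is.na(strings) & nzchar(strings)]
    token_sets <- lapply(strings, function(s) {
      content_tokens(s, min_len = min_len, stoplist = stoplist)$surface
    })
    nonempty <- vapply(token_sets, length, 1L) > 0L
    strings <- strings[nonempty]
    token_sets <- token_sets[nonempty]
    if (length(strings) == 0L) next
    concepts[[id]] <- list(strings = strings, token_sets = token_sets)
    for (tok in unique(unlist(token_sets))) {
      token_index[[tok]] <- c(token_index[[tok]], id)
    }
    if (length(tm$alt_ids) > 0L) {
      alt_ids[tm$alt_ids] <- id
    }
  }
  if (length(concepts) == 0L) {
    stop("ontology yields no usable concept labels", call. = FALSE)
  }
  token_index <- lapply(token_index, unique)
  trigram_index <- list()
  for (tok in names(token_index)) {
    if (nchar(tok) < 3L) next
    for (g in unique(kmers(tok))) {
      trigram_index[[g]] <- c(trigram_index[[g]], tok)
    }
  }
  structure(list(concepts = concepts, token_index = token_index,
                 trigram_index = trigram_index, alt_ids = alt_ids,
                 parents = parents, root_filter = root_filter),
            class = "tblat_lexicon")
}

# All ids whose is_a closure reaches `root`, including root itself.
descendants_of <- function(root, parents) {
  children <- list()
  for (id in names(parents)) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  seen <- character(0)
  frontier <- root
  while (length(frontier) > 0L) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(children[frontier]))
    frontier <- setdiff(nxt, seen)
  }
  unique(seen)
}

#' @export
print.tblat_lexicon <- function(x, ...) {
  cat("tblat lexicon: ", length(x$concepts), " concepts, ",
      length(x$token_index), " unique tokens, ",
      length(x$trigram_index), " trigrams",
      if (!is.null(x$root_filter)) paste0(" (root ", x$root_filter, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Resolve a (possibly retired) concept ID to its primary ID
#'
#' @param id Concept ID (vectorized).
#' @param lex A `tblat_lexicon`.
#' @return Primary IDs; unknown IDs pass through unchanged.
#' @export
resolve_alt_id <- function(id, lex) {
  stopifnot(inherits(lex, "tblat_lexicon"))
  hit <- id %in% names(lex$alt_ids)
  id[hit] <- unname(lex$alt_ids[id[hit]])
  id
}

#' Candidate ontology tokens sharing 3-mers with a query
#'
#' BLAST-style seeding: ontology tokens sharing at least `min_shared`
#' distinct 3-mers with the query, ranked by shared-3-mer count descending
#' (ties broken alphabetically for determinism).
#'
#' @param query_token Query token, length >= 3.
#' @param lex A `tblat_lexicon`.
#' @param min_shared Minimum shared distinct 3-mers. Default: 1 when the
#'   query has at most four 3-mers, else 2 — keeps recall on short tokens
#'   without flooding the candidate set for long ones.
#' @return Character vector of candidate tokens (possibly empty), with the
#'   shared counts as the `shared` attribute.
#' @export
candidates_for <- function(query_token, lex, min_shared = NULL) {
  stopifnot(inherits(lex, "tblat_lexicon"))
  query_token <- tolower(query_token)
  qk <- unique(kmers(query_token))
  if (is.null(min_shared)) min_shared <- if (length(qk) <= 4L) 1L else 2L
  hits <- unlist(lex$trigram_index[qk], use.names = FALSE)
  if (length(hits) == 0L) return(character(0))
  counts <- table(hits)
  counts <- counts[counts >= min_shared]
  if (length(counts) == 0L) return(character(0))
  ord <- order(-as.numeric(counts), names(counts))
  out <- names(counts)[ord]
  attr(out, "shared") <- as.integer(counts)[ord]
  out
}
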