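#' Tokenize text into lowercase word tokens with character spans
#'
#' Splits on non-alphanumeric boundaries: a token is a maximal run of
#' alphanumeric characters. Surfaces are lowercase; spans are 0-based,
#' half-open character offsets into the original text, so
#' `substr(text, start + 1, end)` (lowercased) equals the surface.
#'
#' This regex tokenizer is the self-contained default; any tokenizer that
#' returns a data frame with columns `surface`, `start`, `end` can be used
#' in its place by downstream functions.
#'
#' @param text A character scalar (may be empty).
#' @return A data frame with columns `surface` (character), `start`, `end`
#'   (integer, 0-based half-open), one row per token in document order.
#' @examples
#' tokenize("Dysplastic hip joints.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(empty_tokens())
  m <- gregexpr("[[:alnum:]]+", text)[[1L]]
  if (m[1L] == -1L) return(empty_tokens())
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  surface <- tolower(substring(text, m, m + len - 1L))
  data.frame(surface = surface, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

empty_tokens <- function() {
  data.frame(surface = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Cleanse a token sequence
#'
#' Applies the corpus-preparation rules: leading/trailing punctuation is
#' stripped from a surface (spans adjusted accordingly), tokens still
#' containing embedded special characters (e.g. `@`, `+`) are dropped
#' wholly, and tokens shorter than `min_len` characters are removed.
#' Order is preserved and the operation is idempotent.
#'
#' @param tokens A token data frame as returned by [tokenize()].
#' @param min_len Minimum surface length kept (default 4, the corpus rule;
#'   use 3 when preparing tokens for 3-mer alignment).
#' @return A token data frame.
#' @export
cleanse <- function(tokens, min_len = 4L) {
  stopifnot(is.data.frame(tokens), min_len >= 1L)
  if (nrow(tokens) == 0L) return(tokens)
  surf <- tokens$surface
  lead <- nchar(surf) - nchar(sub("^[[:punct:]]+", "", surf))
  trail <- nchar(surf) - nchar(sub("[[:punct:]]+$", "", surf))
  core <- substring(surf, lead + 1L, nchar(surf) - trail)
  tokens$surface <- core
  tokens$start <- tokens$start + lead
  tokens$end <- tokens$end - trail
  keep <- nzchar(core) &
    !grepl("[^[:alnum:]]", core) &
    nchar(core) >= min_len
  out <- tokens[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a stop word list
#'
#' Reads a one-word-per-line UTF-8 file and returns a lowercase character
#' vector. With no argument, the packaged default English list is used.
#'
#' @param path Path to a stop word file, or `NULL` for the packaged default.
#' @return Character vector of lowercase stop words.
#' @export
load_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "tblat",
                        mustWork = TRUE)
  }
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- tolower(trimws(words))
  unique(words[nzchar(words) & !startsWith(words, "#")])
}

#' Remove stop words from a token sequence
#'
#' @param tokens A token data frame.
#' @param stoplist Character vector of lowercase stop words (exact
#'   membership test); defaults to the packaged English list.
#' @return The token data frame without stop-word rows, order preserved.
#' @export
remove_stopwords <- function(tokens, stoplist = load_stopwords()) {
  stopifnot(is.data.frame(tokens))
  out <- tokens[!(tokens$surface %in% stoplist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-call text preparation for recognition
#'
#' tokenize + cleanse + stop-word removal, the pipeline every consumer of
#' free text in this package uses.
#'
#' @inheritParams tokenize
#' @inheritParams cleanse
#' @inheritParams remove_stopwords
#' @return A token data frame of content tokens.
#' @export
content_tokens <- function(text, min_len = 3L, stoplist = load_stopwords()) {
  remove_stopwords(cleanse(tokenize(text), min_len = min_len), stoplist)
}
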