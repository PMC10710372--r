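#' Score predicted annotations against gold annotations
#'
#' Micro-averaged precision, recall and F1. In `MENTION` mode a true
#' positive is a predicted (doc_id, start, end, concept_id) quadruple
#' matching a gold mention exactly; in `DOCUMENT_SET` mode per-document
#' concept-ID sets are compared and spans ignored. Concept IDs are resolved
#' through `lex`'s alt_id table when a lexicon is supplied, and both sides
#' are restricted to the lexicon's root-filter descendants when one is
#' configured.
#'
#' Definitions: precision = tp / (tp + fp), recall = tp / (tp + fn),
#' F1 = 2PR / (P + R), each 0 when its denominator is 0.
#'
#' @param pred,gold Annotation data frames with columns `doc_id`, `start`,
#'   `end`, `concept_id` (`start`/`end` ignored in `DOCUMENT_SET` mode).
#' @param mode `"MENTION"` (default) or `"DOCUMENT_SET"`.
#' @param lex Optional `tblat_lexicon` for alt_id resolution and root
#'   filtering.
#' @param doc_ids Optional character vector of the evaluated document
#'   universe; predictions for documents outside `gold`'s documents and
#'   this universe raise an error.
#' @return An `eval_report`: list with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1` (proportions in `[0, 1]`).
#' @export
evaluate <- function(pred, gold, mode = c("MENTION", "DOCUMENT_SET"),
                     lex = NULL, doc_ids = NULL) {
  mode <- match.arg(mode)
  pred <- as_annotations(pred, mode)
  gold <- as_annotations(gold, mode)
  universe <- unique(c(gold$doc_id, doc_ids))
  alien <- setdiff(pred$doc_id, universe)
  if (length(alien) > 0L) {
    stop("predictions reference unknown documents: ",
         paste(utils::head(alien, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(lex)) {
    pred$concept_id <- resolve_alt_id(pred$concept_id, lex)
    gold$concept_id <- resolve_alt_id(gold$concept_id, lex)
    if (!is.null(lex$root_filter)) {
      keep <- names(lex$concepts)
      pred <- pred[pred$concept_id %in% keep, , drop = FALSE]
      gold <- gold[gold$concept_id %in% keep, , drop = FALSE]
    }
  }
  key <- function(x) {
    if (mode == "MENTION") {
      paste(x$doc_id, x$start, x$end, x$concept_id, sep = "\r")
    } else {
      unique(paste(x$doc_id, x$concept_id, sep = "\r"))
    }
  }
  kp <- key(pred)
  kg <- key(gold)
  tp <- sum(kp %in% kg)
  fp <- length(kp) - tp
  fn <- length(kg) - tp
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "eval_report")
}

as_annotations <- function(x, mode) {
  stopifnot(is.data.frame(x))
  need <- if (mode == "MENTION") {
    c("doc_id", "start", "end", "concept_id")
  } else {
    c("doc_id", "concept_id")
  }
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    stop("annotation table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "tp %d, fp %d, fn %d | P %.1f%%  R %.1f%%  F1 %.1f%%\n",
    x$tp, x$fp, x$fn, 100 * x$precision, 100 * x$recall, 100 * x$f1))
  invisible(x)
}

#' Read gold annotations from TSV
#'
#' Format: `doc_id<TAB>start<TAB>end<TAB>concept_id`, with header.
#'
#' @param path TSV file path.
#' @return Annotation data frame.
#' @export
read_annotations <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_annotations(x, "MENTION")
}
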