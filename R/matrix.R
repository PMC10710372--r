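#' Build the 3-mer transition scoring matrix from a pair corpus
#'
#' For every (canonical, typo) pair with distinct strings, index-aligned
#' 3-mer transitions are counted (absent transitions from length mismatch
#' contribute nothing; surplus typo 3-mers generate no entry). Counts are
#' normalized per source 3-mer over all observed targets, and entries whose
#' probability falls below `prune_threshold` are removed *after*
#' normalization, so a pruned row sums to less than 1. Pairs of identical
#' strings are excluded entirely; duplicate rows in the corpus count
#' multiply.
#'
#' @param corpus Pair corpus data frame (`canonical`, `typo`), see
#'   [read_pair_corpus()].
#' @param prune_threshold Minimum retained probability, in `[0, 1)`;
#'   default 0.01.
#' @param provenance Free-text metadata stored with the matrix.
#' @return A `tblat_matrix`: list with `entries` (named list: source 3-mer
#'   -> named numeric vector of target probabilities), `prune_threshold`,
#'   `provenance`.
#' @export
build_matrix <- function(corpus, prune_threshold = 0.01,
                         provenance = "built by tblat::build_matrix") {
  corpus <- as_pair_corpus(corpus)
  stopifnot(prune_threshold >= 0, prune_threshold < 1)
  if (nrow(corpus) == 0L) stop("empty pair corpus", call. = FALSE)
  src <- character(0)
  tgt <- character(0)
  for (i in seq_len(nrow(corpus))) {
    if (corpus$canonical[i] == corpus$typo[i]) next
    tr <- pair_transitions(corpus$canonical[i], corpus$typo[i])$transitions
    ok <- !is.na(tr$target)
    src <- c(src, tr$source[ok])
    tgt <- c(tgt, tr$target[ok])
  }
  if (length(src) == 0L) {
    stop("corpus yields no transitions (identity pairs only?)",
         call. = FALSE)
  }
  counts <- table(src, tgt)
  entries <- lapply(rownames(counts), function(s) {
    row <- counts[s, ]
    row <- row[row > 0]
    p <- as.numeric(row) / sum(row)
    names(p) <- names(row)
    p <- p[p >= prune_threshold]
    sort(p, decreasing = TRUE)
  })
  names(entries) <- rownames(counts)
  entries <- entries[vapply(entries, length, 1L) > 0L]
  new_tblat_matrix(entries, prune_threshold, provenance)
}

new_tblat_matrix <- function(entries, prune_threshold, provenance) {
  structure(list(entries = entries, prune_threshold = prune_threshold,
                 provenance = provenance),
            class = "tblat_matrix")
}

#' @export
print.tblat_matrix <- function(x, ...) {
  nt <- sum(vapply(x$entries, length, 1L))
  cat("tblat 3-mer transition matrix\n",
      "  sources: ", length(x$entries), "; transitions: ", nt,
      "; prune threshold: ", x$prune_threshold, "\n",
      "  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Look up a transition probability
#'
#' @param m A `tblat_matrix`.
#' @param source,target 3-mers.
#' @return The stored probability, or `NA` when the transition is absent.
#' @export
transition_value <- function(m, source, target) {
  row <- m$entries[[source]]
  if (is.null(row)) return(NA_real_)
  v <- row[target]
  if (is.na(names(v)) || is.na(v)) NA_real_ else unname(v)
}

#' Construct a transition matrix from explicit rows
#'
#' Convenience constructor for matrices given directly as probability
#' tables (e.g. a printed worked example) rather than built from a corpus.
#'
#' @param rows Named list: source 3-mer -> named numeric vector of target
#'   probabilities in `(0, 1]`.
#' @param prune_threshold Threshold metadata (no pruning is applied here).
#' @param provenance Free-text metadata.
#' @return A `tblat_matrix`.
#' @export
transition_matrix <- function(rows, prune_threshold = 0.01,
                              provenance = "explicit rows") {
  stopifnot(is.list(rows), length(names(rows)) == length(rows))
  for (s in names(rows)) {
    p <- rows[[s]]
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      stop("row '", s, "' has unnamed targets", call. = FALSE)
    }
    if (any(p <= 0 | p > 1)) {
      stop("row '", s, "' has probabilities outside (0, 1]", call. = FALSE)
    }
  }
  new_tblat_matrix(rows, prune_threshold, provenance)
}

#' Serialize a transition matrix to TSV
#'
#' Three columns `source<TAB>target<TAB>probability` with probabilities at
#' 6 decimal places, preceded by commented header lines carrying the prune
#' threshold and provenance. [load_matrix()] inverts this exactly on the
#' serialized (6-dp) probabilities.
#'
#' @param m A `tblat_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_matrix <- function(m, path) {
  stopifnot(inherits(m, "tblat_matrix"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# prune_threshold=%s", format(m$prune_threshold)),
    sprintf("# provenance=%s", m$provenance)), con)
  for (s in names(m$entries)) {
    row <- m$entries[[s]]
    writeLines(sprintf("%s\t%s\t%.6f", s, names(row), row), con)
  }
  invisible(path)
}

#' Load a transition matrix from TSV (or its JSON export)
#'
#' @param path File written by [save_matrix()] or [save_matrix_json()].
#' @return A `tblat_matrix`.
#' @export
load_matrix <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 1L && startsWith(trimws(first), "{")) {
    return(load_matrix_json(path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  prune <- 0.01
  provenance <- ""
  src <- tgt <- character(0)
  prob <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      if (startsWith(kv, "prune_threshold=")) {
        prune <- as.numeric(sub("prune_threshold=", "", kv, fixed = TRUE))
      } else if (startsWith(kv, "provenance=")) {
        provenance <- sub("provenance=", "", kv, fixed = TRUE)
      }
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 3L) {
      stop("malformed matrix file at line ", i, ": expected 3 columns",
           call. = FALSE)
    }
    p <- suppressWarnings(as.numeric(parts[3L]))
    if (is.na(p) || p <= 0 || p > 1) {
      stop("malformed matrix file at line ", i,
           ": probability must be in (0, 1], got '", parts[3L], "'",
           call. = FALSE)
    }
    src <- c(src, parts[1L])
    tgt <- c(tgt, parts[2L])
    prob <- c(prob, p)
  }
  if (length(src) == 0L) stop("matrix file contains no entries", call. = FALSE)
  entries <- split(stats::setNames(prob, tgt), src)
  entries <- lapply(entries, function(r) sort(r, decreasing = TRUE))
  new_tblat_matrix(entries, prune, provenance)
}

#' Export a transition matrix as a single JSON file
#'
#' @param m A `tblat_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_matrix_json <- function(m, path) {
  stopifnot(inherits(m, "tblat_matrix"))
  obj <- list(prune_threshold = m$prune_threshold,
              provenance = m$provenance,
              entries = lapply(m$entries, function(r) {
                as.list(round(r, 6))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

load_matrix_json <- function(path) {
  obj <- jsonlite::read_json(path)
  entries <- lapply(obj$entries, function(r) {
    p <- vapply(r, as.numeric, 1)
    if (any(p <= 0 | p > 1)) {
      stop("matrix JSON contains probabilities outside (0, 1]",
           call. = FALSE)
    }
    sort(p, decreasing = TRUE)
  })
  new_tblat_matrix(entries, as.numeric(obj$prune_threshold),
                   as.character(obj$provenance))
}
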