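#' Enumerate the attainable alignment-score distribution for a token
#'
#' Captures the whole space an alignment score can take when every 3-mer of
#' `token` systematically transitions through every target stored in its
#' matrix row, one target per position. A 3-mer absent from the matrix
#' contributes a single 0 at its position. When the Cartesian product of
#' row sizes is at most `limit`, the full multiset of sums is enumerated
#' (`EXACT_ENUM`); otherwise `limit` combinations are sampled uniformly
#' with a fixed seed and the exact minimum and maximum (sums of per-row
#' minima / maxima) are appended (`SAMPLED`). Multiset semantics: duplicate
#' sums are kept, so percentiles weight combinations equally.
#'
#' @param token Token of length >= 3.
#' @param m A `tblat_matrix`.
#' @param limit Enumeration budget (default 1e6 combinations).
#' @param seed Seed for `SAMPLED` mode, recorded in the result.
#' @return A `score_space`: list with `token`, `scores` (sorted numeric),
#'   `min`, `max`, `method` (`"EXACT_ENUM"` or `"SAMPLED"`), `degenerate`
#'   (TRUE when no 3-mer of the token is a matrix source), `seed`.
#' @export
build_score_space <- function(token, m, limit = 1e6, seed = 20220201L) {
  stopifnot(inherits(m, "tblat_matrix"), limit >= 1)
  token <- tolower(token)
  ks <- kmers(token)
  rows <- lapply(ks, function(s) {
    r <- m$entries[[s]]
    if (is.null(r) || length(r) == 0L) 0 else unname(r)
  })
  degenerate <- all(vapply(rows, function(r) identical(r, 0), TRUE))
  lo <- sum(vapply(rows, min, 1))
  hi <- sum(vapply(rows, max, 1))
  n_comb <- prod(vapply(rows, length, 1L))
  if (n_comb <= limit) {
    method <- "EXACT_ENUM"
    scores <- 0
    for (r in rows) scores <- as.vector(outer(scores, r, "+"))
  } else {
    method <- "SAMPLED"
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    ndraw <- as.integer(limit)
    scores <- numeric(ndraw)
    for (r in rows) {
      scores <- scores + r[sample.int(length(r), ndraw, replace = TRUE)]
    }
    scores <- c(scores, lo, hi)
  }
  structure(list(token = token, scores = sort(scores), min = lo, max = hi,
                 method = method, degenerate = degenerate, seed = seed),
            class = "score_space")
}

# Save/restore the global RNG state so library code does not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.score_space <- function(x, ...) {
  cat(sprintf("score space for '%s': %d scores in [%.4f, %.4f] (%s%s)\n",
              x$token, length(x$scores), x$min, x$max, x$method,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Percentile placement of a score within a token's score space
#'
#' The empirical step function: 100 times the fraction of stored scores
#' less than or equal to `score`. Monotone non-decreasing;
#' `percentile_of(max(space))` is 100 and any score below the minimum maps
#' to 0.
#'
#' @param score A numeric alignment score (or an `alignment_score`).
#' @param space A non-degenerate `score_space`.
#' @return Percentile in `[0, 100]`.
#' @export
percentile_of <- function(score, space) {
  stopifnot(inherits(space, "score_space"))
  if (space$degenerate) {
    stop("degenerate score space for '", space$token,
         "': no 3-mer of the token is a matrix source", call. = FALSE)
  }
  if (inherits(score, "alignment_score")) score <- score$value
  # scores are sorted: count via binary search
  100 * findInterval(score + 1e-12, space$scores) / length(space$scores)
}

#' Length-indexed percentile cut-off policy
#'
#' Maps token length to the target percentile an alignment score must reach
#' to be accepted. Defaults follow the published guidance: short tokens are
#' volatile and need a lower bar, stabilizing with length — lengths 5 to 8
#' use the 40th percentile, length 9 the 55th, and lengths 10 and above a
#' fixed 70th percentile. Tokens of length 3 or 4 are matched exactly only
#' (`NA` percentile): they carry too few 3-mers for fuzzy alignment.
#'
#' @param bands Named numeric vector mapping token length (as character
#'   names) to percentile; lengths not listed fall through to `default_ge10`
#'   when >= 10, and to `NA` (exact-only) when < 5.
#' @param default_ge10 Percentile used for lengths >= 10.
#' @return A `cutoff_policy`.
#' @export
cutoff_policy <- function(bands = c("5" = 40, "6" = 40, "7" = 40, "8" = 40,
                                    "9" = 55),
                          default_ge10 = 70) {
  stopifnot(all(is.na(bands) | (bands > 0 & bands <= 100)),
            default_ge10 > 0, default_ge10 <= 100)
  structure(list(bands = bands, default_ge10 = default_ge10),
            class = "cutoff_policy")
}

#' Target percentile for a token length
#'
#' @param policy A `cutoff_policy`.
#' @param len Token length (>= 3).
#' @return Percentile in `(0, 100]`, or `NA` meaning exact match only.
#' @export
policy_percentile <- function(policy, len) {
  stopifnot(inherits(policy, "cutoff_policy"), len >= 3)
  key <- as.character(len)
  if (key %in% names(policy$bands)) return(unname(policy$bands[key]))
  if (len >= 10) policy$default_ge10 else NA_real_
}

#' Read / write a cut-off policy as JSON
#'
#' @param policy A `cutoff_policy`; `path` a file path.
#' @return `load_policy` returns a `cutoff_policy`; `save_policy` returns
#'   `path` invisibly.
#' @export
save_policy <- function(policy, path) {
  stopifnot(inherits(policy, "cutoff_policy"))
  jsonlite::write_json(list(bands = as.list(policy$bands),
                            default_ge10 = policy$default_ge10),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_policy
#' @param path Path to a policy JSON file.
#' @export
load_policy <- function(path) {
  obj <- jsonlite::read_json(path)
  bands <- vapply(obj$bands, as.numeric, 1)
  cutoff_policy(bands = bands, default_ge10 = as.numeric(obj$default_ge10))
}

#' Minimal accepted score for a token under a cut-off policy
#'
#' Looks up the policy percentile for the token's length and returns the
#' smallest stored score whose percentile reaches it.
#'
#' @param token The ontology token the space belongs to.
#' @param space Its `score_space`.
#' @param policy A `cutoff_policy`.
#' @return The cut-off score, or `NA` when the policy prescribes exact
#'   matching only for this length.
#' @export
cutoff_score <- function(token, space, policy) {
  p <- policy_percentile(policy, nchar(token))
  if (is.na(p)) return(NA_real_)
  score_at_percentile(space, p)
}

score_at_percentile <- function(space, p) {
  stopifnot(inherits(space, "score_space"), p > 0, p <= 100)
  if (space$degenerate) {
    stop("degenerate score space for '", space$token, "'", call. = FALSE)
  }
  n <- length(space$scores)
  # percentile of scores[i] (ties collapsed) is 100 * (last index of the
  # tied block) / n; take the first value whose percentile >= p
  idx <- ceiling(n * p / 100)
  v <- space$scores[idx]
  # with ties, percentile_of(v) can exceed p already at a smaller value;
  # the smallest score with percentile >= p is the first element of v's
  # tied block or any smaller value with the same cumulative fraction
  first <- findInterval(v - 1e-12, space$scores) + 1L
  space$scores[first]
}

#' Precompute score spaces for every token of a lexicon
#'
#' Score spaces depend only on (token, matrix), so they are computed once
#' per lexicon and reused across queries.
#'
#' @param lex A `tblat_lexicon`.
#' @param m A `tblat_matrix`.
#' @inheritParams build_score_space
#' @return Named list of `score_space`, keyed by token.
#' @export
precompute_score_spaces <- function(lex, m, limit = 1e6, seed = 20220201L) {
  stopifnot(inherits(lex, "tblat_lexicon"))
  toks <- names(lex$token_index)
  toks <- toks[nchar(toks) >= 3L]
  spaces <- lapply(toks, build_score_space, m = m, limit = limit, seed = seed)
  names(spaces) <- toks
  spaces
}

#' Save / load a score-space cache
#'
#' One record per token: token, min, max, method, and a percentile grid at
#' 1% steps (101 quantile values). The cache is keyed by an MD5 checksum of
#' the matrix file it was computed from; loading against a different
#' checksum fails.
#'
#' @param spaces Named list of `score_space` objects.
#' @param path Output TSV path.
#' @param matrix_checksum Checksum string tying the cache to its matrix
#'   (e.g. `tools::md5sum(matrix_file)`).
#' @return `path`, invisibly.
#' @export
save_score_cache <- function(spaces, path, matrix_checksum = "") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# matrix_checksum=%s", matrix_checksum), con)
  writeLines(paste(c("token", "min", "max", "method",
                     sprintf("q%03d", 0:100)), collapse = "\t"), con)
  for (sp in spaces) {
    qs <- stats::quantile(sp$scores, probs = 0:100 / 100, names = FALSE,
                          type = 1)
    writeLines(paste(c(sp$token, sprintf("%.6f", sp$min),
                       sprintf("%.6f", sp$max), sp$method,
                       sprintf("%.6f", qs)), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname save_score_cache
#' @export
load_score_cache <- function(path, matrix_checksum = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  stored <- sub("# matrix_checksum=", "", lines[1L], fixed = TRUE)
  if (!is.null(matrix_checksum) && nzchar(stored) &&
      !identical(unname(as.character(matrix_checksum)), stored)) {
    stop("score cache was built for a different matrix (checksum mismatch)",
         call. = FALSE)
  }
  body <- lines[-(1:2)]
  spaces <- list()
  for (ln in body) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    qs <- as.numeric(parts[-(1:4)])
    spaces[[parts[1L]]] <- structure(
      list(token = parts[1L], scores = sort(qs),
           min = as.numeric(parts[2L]), max = as.numeric(parts[3L]),
           method = paste0(parts[4L], "_GRID"),
           degenerate = as.numeric(parts[3L]) == 0, seed = NA_integer_),
      class = "score_space")
  }
  spaces
}
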