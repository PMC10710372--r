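#' Score an explicit sequence of 3-mer transitions
#'
#' Low-level scorer underlying [align_score()]: sums, over candidate 3-mer
#' positions, the matrix value of each `source -> target` transition. When
#' a transition is absent from the matrix a penalty fills in:
#' `penalty = f(category) * id(source)`, where `category` is the error
#' category of the transition, `f` its relative frequency in `profile`
#' (`f(IDENTITY) = 1`), and `id(source)` the identity value
#' `m[source][source]` when stored, else the mean identity value over the
#' matrix (0 for an empty matrix). Positions with target `NA` (candidate
#' 3-mers with no aligned query 3-mer) contribute 0 and count as uncovered
#' — the lack of coverage is penalized through the score's percentile, not
#' by subtraction, so the score stays non-negative.
#'
#' @param sources Character vector of candidate 3-mers (drives positions).
#' @param targets Character vector, same length; `NA` marks an uncovered
#'   position.
#' @param m A `tblat_matrix`.
#' @param profile An `error_profile` of penalty weights; default
#'   [default_error_profile()].
#' @return A list of class `alignment_score`: `value`, `covered`, `total`.
#' @export
score_transitions <- function(sources, targets, m,
                              profile = default_error_profile()) {
  stopifnot(inherits(m, "tblat_matrix"), length(sources) == length(targets))
  value <- 0
  covered <- 0L
  for (i in seq_along(sources)) {
    if (is.na(targets[i])) next
    v <- transition_value(m, sources[i], targets[i])
    if (!is.na(v)) {
      value <- value + v
      covered <- covered + 1L
    } else {
      value <- value + transition_penalty(sources[i], targets[i], m, profile)
    }
  }
  structure(list(value = value, covered = covered,
                 total = length(sources)),
            class = "alignment_score")
}

transition_penalty <- function(source, target, m, profile) {
  cat <- classify_transition(source, target)
  f <- if (cat == "IDENTITY") 1 else unname(profile[cat])
  f * identity_value(m, source)
}

identity_value <- function(m, source) {
  v <- transition_value(m, source, source)
  if (!is.na(v)) return(v)
  mean_identity_value(m)
}

mean_identity_value <- function(m) {
  ids <- vapply(names(m$entries),
                function(s) transition_value(m, s, s), 1)
  ids <- ids[!is.na(ids)]
  if (length(ids) == 0L) 0 else mean(ids)
}

#' @export
print.alignment_score <- function(x, ...) {
  cat(sprintf("alignment score %.4f (covered %d/%d positions)\n",
              x$value, x$covered, x$total))
  invisible(x)
}

#' Token-level alignment score
#'
#' Scores a (possibly misspelled) query token against a candidate ontology
#' token: the candidate's 3-mers drive the positions, each paired with the
#' query 3-mer at the same index, and the transition sequence is scored
#' with [score_transitions()]. The result is interpreted against the
#' candidate's own score distribution (see [build_score_space()] and
#' [percentile_of()]).
#'
#' @param candidate Ontology ("canonical") token, length >= 3.
#' @param query Query token, length >= 3.
#' @inheritParams score_transitions
#' @return An `alignment_score` (`value`, `covered`, `total`).
#' @export
align_score <- function(candidate, query, m,
                        profile = default_error_profile()) {
  pt <- pair_transitions(tolower(candidate), tolower(query))$transitions
  score_transitions(pt$source, pt$target, m, profile)
}
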