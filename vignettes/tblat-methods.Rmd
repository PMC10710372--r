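---
title: "Token BLAST-like alignment: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Token BLAST-like alignment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tblat)
```

## The problem and the model

Clinical free text is full of typographical errors: *shoret* for *short*,
*sezuire* for *seizure*. Dictionary-based concept recognizers, which link
text spans to ontology concepts (our reference use case is phenotype
ontologies of the HPO kind) by token lookup, record near-zero recall the
moment a required token is misspelled. `tblat` treats the problem the way
BLAST treats biosequences: a token is a sequence of overlapping character
3-mers, misspellings are "mutations" of those 3-mers, and a substitution
matrix learned from real canonical-token/typo pairs scores how plausible
each 3-mer transition is.

**Scoring matrix.** Given a corpus of (canonical, typo) token pairs, each
pair with distinct strings contributes its index-aligned 3-mer transitions:
the canonical token's 3-mer at index *i* against the typo's 3-mer at index
*i*. Counts are normalized per source 3-mer into probabilities and entries
below a prune threshold (default 0.01) are dropped *after* normalization —
a pruned row therefore sums to less than 1, which matches how the published
row for `abn` (0.49 + 0.20 + ... ≈ 0.80) behaves. Identity *pairs* are
excluded; identity *transitions* inside a genuinely misspelled pair (e.g.
`abn -> abn` in abnormal/abnrmal) are signal and are counted.

**Alignment score.** For a candidate ontology token *c* with 3-mers
\(s_1..s_k\) and a query token *q* with 3-mers \(t_1..t_m\),

\[ \mathrm{score}(c, q) \;=\; \sum_{i=1}^{k} v(s_i, t_i), \]

where \(v(s_i, t_i)\) is the matrix value when the transition is stored,
a *penalty* when it is not, and 0 when \(i > m\) (the query is too short to
cover the position). The score is interpreted *relative to the candidate's
own score distribution*, so contributing 0 at uncovered positions is itself
the coverage penalty: the percentile drops. This keeps scores non-negative
and needs no ad-hoc subtraction.

**Error taxonomy and the penalty.** Every 3-mer transition falls in exactly
one of seven categories, tested most-specific first:
IDENTITY, INVERSION (two characters swapped: `tar -> atr`), GAP_SHIFT
(insertion mid-3-mer: `tar -> t_a`), SHIFT (a bigram shifted one position:
`met -> ame`), SINGLE_REPLACEMENT (Hamming 1), DOUBLE_REPLACEMENT
(Hamming 2), OTHER. The source material describes the missing-transition
penalty only qualitatively ("frequency values of the error types ... used
as a penalty in conjunction with identity transition values"), so the exact
formula was an open design point. We use

\[ \mathrm{penalty}(s_i, t_i) = f(\mathrm{cat}(s_i, t_i)) \cdot
   \mathrm{id}(s_i), \]

with \(f\) the category's relative frequency (defaults from a large
clinical corpus: shift 42.25%, single replacement 18.9%, double replacement
8.79%, gap shift 5.63%, inversion 3.02%, other 21.41%) and
\(\mathrm{id}(s_i)\) the row's identity value, falling back to the matrix's
mean identity value, and to 0 for an empty matrix. This is the most direct
multiplicative reading of the description; it guarantees a penalty never
exceeds the row's identity value, preserving self-alignment dominance. The
function is small and isolated (`score_transitions()`), so an alternative
penalty can be swapped in.

**Precedence rationale.** Several categories overlap logically (an adjacent
swap is also Hamming-2; a duplication produces 3-mers matching the
insertion pattern). Evaluating the rarer structured categories first keeps
them from being absorbed by the broad Hamming classes — otherwise the
published 3.02% inversion / 5.63% gap-shift rates could never be observed.
A consequence worth knowing: in a duplicated-letter pair like
abnormal/abbnormal the two 3-mers spanning the edit classify as GAP_SHIFT
and only the downstream 3-mers as SHIFT, so shift frequency for that pair
is 4/6, not 1.

## Score distributions and cut-offs

For each ontology token, the full space of attainable scores is the
multiset of sums obtained by letting every position independently take each
stored target of its row (`build_score_space()`). Multiset — not set —
semantics matter: percentiles then weight combinations equally instead of
skewing toward rare sums. Up to 10^6 combinations are enumerated exactly;
beyond that, 10^6 combinations are sampled under a fixed recorded seed and
the analytic minimum and maximum (sums of per-row minima/maxima) are
appended so the endpoints stay exact. Percentiles use the empirical step
function (no interpolation — the distribution is discrete and the choice is
documented rather than guessed).

A score is accepted when it reaches a length-indexed percentile cut-off
(`cutoff_policy()`): lengths 5–8 use the 40th percentile, length 9 the
55th, length 10 and above a fixed 70th. Short tokens are volatile — a
single character change rewrites up to three of their few 3-mers — hence
the lower bar; from length 10 the distributions are stable enough for a
fixed 70th percentile. Tokens of length 3–4 are matched exactly only: with
one or two 3-mers, fuzzy alignment is noise. The per-length values below 10
are read qualitatively from the published coverage trends and are
config-replaceable (`save_policy()`/`load_policy()`); the ≥ 10 value of 70
is stated guidance. Score spaces are query-independent, so
`precompute_score_spaces()` computes them once per lexicon and
`save_score_cache()` persists a 1%-step quantile grid keyed by the matrix
file's checksum.

## Lexicon and candidate seeding

`load_ontology()` reads OBO 1.4 or OBO-graph JSON, keeps labels and *exact*
synonyms (broader synonym types are deliberately excluded), resolves
`alt_id`s to primary IDs, and optionally restricts concepts to the `is_a`
descendants of a root (the phenotypic-abnormality subtree in the HPO use
case). Labels pass through the same pipeline as text: lowercasing,
punctuation cleansing, stop-word removal (a packaged, replaceable English
list), with a minimum token length of 3 — the corpus-preparation floor of 4
applies to typo-pair corpora, but lexicon tokens of length 3–4 must remain
visible for exact matching. A trigram inverted index provides BLAST-style
seeding: `candidates_for()` returns ontology tokens sharing at least
`min_shared` distinct 3-mers with the query (1 when the query has ≤ 4
3-mers, else 2 — a recall/candidate-set-size balance the source leaves
open).

## Entity linkage

`link_span()` resolves each content token of a span: exact hit first,
otherwise the candidate token with the highest alignment percentile among
those clearing their cut-off. A concept is returned iff the full
content-token multiset of one of its labels/synonyms is covered by distinct
resolved span tokens, order-insensitively (token order is part of the noise
model). The concept score is the mean percentile of the matched tokens;
ties prefer the more specific (longer) label, then the smallest concept ID
— reproducible and biased toward specific phenotypes. `exact_match()` is
the same machinery with equality-only resolution, and whenever it fires,
`link_span()` returns the same concept flagged EXACT. `annotate()` adds a
sliding-window (default width 6 content tokens) boundary heuristic with
longest-match-first overlap resolution; it is plumbing — the method's claim
is about linkage quality on given spans, and the evaluation mode
(`link_spans()` + `evaluate()`) reflects that.

## The synthetic world

The generators exist so every component is testable without external
downloads; their defaults are the stated conditions of the procedure they
emulate, not tunable dials.

* `make_typo()` realizes one category-specific edit (duplication,
  replacement, adjacent replacement pair, insertion, adjacent swap) and
  *verifies* by re-classification that the requested category appears among
  the aligned transitions. The duplication position is restricted to
  `1..len-3` so a downstream shifted 3-mer exists.
* `gen_typo_errors()` applies the banded edit counts — 1 edit for lengths
  below 10, 3 for 10–17, 4 for 18 and above — at distinct non-adjacent
  positions (applied right-to-left so insertions do not displace pending
  positions; the source does not specify placement). Category mix defaults
  to uniform over shift / single replacement / inversion, the three
  categories named for label perturbation.
* `gen_pair_corpus()` draws transitions i.i.d. from a known per-3-mer
  distribution for matrix-recovery tests. It operates on length-3 tokens
  only: overlapping 3-mers of longer tokens couple the per-position draws,
  so no string can realize arbitrary independent transitions. Rows with
  identity mass are rejected — identical pairs are excluded from matrix
  building, so that mass would be unrecoverable by construction.
* `perturb_corpus()` rewrites mapped canonical tokens inside annotated
  spans and recomputes all offsets, reproducing the typo-corpus
  construction procedure.
* The packaged toy ontology (16 terms, multiword labels, an exact synonym,
  an `alt_id`, a 17-character biochemical token, one concept outside the
  phenotype root, one obsolete term) is entirely synthetic and is the
  universal test substrate.

What a green test does and does not establish: the synthetic corpus has
independent, cleanly categorized edits and a 36-token vocabulary; real
clinical notes have correlated multi-error typos, abbreviations,
hyphenation and a ~6,900-token vocabulary with much denser trigram
collisions. Recovery of generator parameters and the exact-vs-fuzzy recall
direction transfer; absolute precision/recall values do not, and the
published benchmark numbers on external corpora are out of scope by design.

## Numerical and degenerate-input choices

* Probabilities serialize at 6 decimal places (the precision the source
  prints); round-trip equality is defined on the serialized values.
* A token none of whose 3-mers is a matrix source yields a degenerate score
  space (min = max = 0) and is flagged; percentile lookup on it is an
  error, and the recognizer skips such candidates rather than guessing.
* An unseen *identity* transition (source row absent) is penalized with
  factor 1 times the mean identity value — the least-surprising neutral
  filler; an empty matrix scores 0 everywhere.
* Character offsets are 0-based half-open throughout; all matching is
  case-insensitive (ontology labels are capitalized, clinical tokens are
  not; the source never discusses case).
* Seeds: every stochastic routine either takes a seed argument or restores
  the caller's RNG state afterwards.

## Known limitations

Transposition-heavy misspellings of short tokens can share *no* trigram
with their canonical form (*sezuire*/*seizure*) and are then unseedable —
the same failure class the source reports for its own error analysis.
Tokens shorter than 5 characters are exact-only by policy, so a typo in a
short required token blocks linkage. The boundary detector is a heuristic
convenience, excluded from any accuracy claim. The OBO reader is minimal
(id, name, EXACT synonyms, alt_id, is_a, is_obsolete); ontologies relying
on other constructs need the OBO-graph JSON path or pre-processing.
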