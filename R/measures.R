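#' String similarity measures built on the LCS length
#'
#' Three scalar measures of the similarity between two token sequences with
#' lengths `la = L(A)` and `lb = L(B)` sharing a longest common subsequence
#' of length `lcsl`:
#'
#' * **LCS ratio**: `lcsl / max(la, lb)` — the LCS relative to the longer
#'   sequence.
#' * **T-LCS** (twofold LCS): `2 * lcsl / (la + lb)` — the LCS relative to
#'   the mean length.
#' * **W-LCS** (weighted LCS): `(lcsl + 1) * lcsl / (la * lcsl + lb)` with
#'   operands ordered so `la <= lb`; defined as 0 when `lcsl = 0`. Weighting
#'   by the LCS length inflates scores of long matches, spreading candidate
#'   scores over a wider range for threshold selection.
#'
#' For every admissible triple `1 <= lcsl <= la <= lb`,
#' `wlcs >= tlcs >= lcs`; all three equal 1 iff `lcsl = la = lb` and 0 iff
#' `lcsl = 0`. All are vectorized and recycle arguments.
#'
#' @param lcsl LCS length(s), `0 <= lcsl <= min(la, lb)`.
#' @param la,lb sequence lengths; at least one must be positive.
#' @return numeric vector of similarities in \[0, 1\].
#' @examples
#' lcs_similarity(3, 3, 7)
#' tlcs_similarity(2, 2, 6)
#' wlcs_similarity(2, 2, 3)
#' @name lcs_measures
NULL

check_measure_args <- function(lcsl, la, lb) {
  if (any(la < 0 | lb < 0 | lcsl < 0)) stop("lengths and lcsl must be non-negative")
  if (any(pmax(la, lb) == 0)) {
    stop("similarity is undefined for two empty sequences (L(A) = L(B) = 0)")
  }
  if (any(lcsl > pmin(la, lb))) stop("lcsl cannot exceed min(la, lb)")
}

#' @rdname lcs_measures
#' @export
lcs_similarity <- function(lcsl, la, lb) {
  check_measure_args(lcsl, la, lb)
  lcsl / pmax(la, lb)
}

#' @rdname lcs_measures
#' @export
tlcs_similarity <- function(lcsl, la, lb) {
  check_measure_args(lcsl, la, lb)
  2 * lcsl / (la + lb)
}

#' @rdname lcs_measures
#' @export
wlcs_similarity <- function(lcsl, la, lb) {
  check_measure_args(lcsl, la, lb)
  lo <- pmin(la, lb)
  hi <- pmax(la, lb)
  out <- ifelse(lcsl == 0, 0, (lcsl + 1) * lcsl / (lo * lcsl + hi))
  as.numeric(out)
}

#' Word-matching baseline similarity
#'
#' All-or-nothing comparison: 1 when the two token sequences are identical
#' (same length, surfaces and order), else 0. Two empty sequences are
#' vacuously identical. This is the exact-string-matching regime that
#' semantic measures are compared against.
#'
#' @param x,y `token_sequence` objects or character vectors.
#' @return 0 or 1.
#' @export
word_match_similarity <- function(x, y) {
  xa <- normalize_text(as_tokens(x))
  xb <- normalize_text(as_tokens(y))
  as.numeric(length(xa) == length(xb) && all(xa == xb))
}

token_bigrams <- function(toks) {
  padded <- c("\x02", toks, "\x03")
  paste(padded[-length(padded)], padded[-1], sep = "\x1f")
}

# size of the multiset intersection of two character vectors
multiset_intersection <- function(ga, gb) {
  u <- unique(ga)
  ca <- tabulate(match(ga, u), length(u))
  cb <- tabulate(match(gb, u), length(u))
  sum(pmin(ca, cb))
}

#' Token-bigram baseline similarity
#'
#' Dice coefficient over the multisets of adjacent token pairs, with start
#' and end boundary markers added to both sequences so sequences shorter
#' than two tokens are well defined.
#'
#' @param x,y `token_sequence` objects or character vectors.
#' @return similarity in \[0, 1\].
#' @export
bigram_similarity <- function(x, y) {
  ga <- token_bigrams(normalize_text(as_tokens(x)))
  gb <- token_bigrams(normalize_text(as_tokens(y)))
  2 * multiset_intersection(ga, gb) / (length(ga) + length(gb))
}

measure_choices <- c("lcs", "tlcs", "wlcs", "word", "bigram")

normalize_measure <- function(measure) {
  m <- tolower(gsub("[^a-z]", "", tolower(measure)))
  m <- switch(m,
    "lcs" = "lcs",
    "tlcs" = "tlcs",
    "dlcs" = "tlcs",
    "wlcs" = "wlcs",
    "word" = "word",
    "wordmatch" = "word",
    "wordmatching" = "word",
    "bigram" = "bigram",
    "bigrams" = "bigram",
    stop("unknown measure: ", measure,
         " (expected one of lcs, tlcs, wlcs, word-match, bigram)")
  )
  m
}

#' Similarity between two token sequences under a named measure
#'
#' Convenience wrapper: computes the semantic LCS (for the LCS-family
#' measures) and returns a one-row tibble recording the measure, the LCS
#' length, the two sequence lengths and the similarity value.
#'
#' @param x,y `token_sequence` objects or character vectors.
#' @param measure one of `"lcs"`, `"tlcs"`, `"wlcs"`, `"word-match"`,
#'   `"bigram"`.
#' @param onto a [term_ontology()] or `NULL`.
#' @param epsilon semantic matching threshold.
#' @param inclusive use `>=` instead of `>` for the threshold test.
#' @return tibble with columns `measure`, `value`, `lcsl`, `la`, `lb`.
#' @export
sequence_similarity <- function(x, y, measure = "wlcs", onto = NULL,
                                epsilon = 0.8, inclusive = FALSE) {
  m <- normalize_measure(measure)
  xa <- normalize_text(as_tokens(x))
  xb <- normalize_text(as_tokens(y))
  la <- length(xa)
  lb <- length(xb)
  if (m %in% c("lcs", "tlcs", "wlcs")) {
    lcsl <- semantic_lcs(xa, xb, onto, epsilon, inclusive)$length
    fun <- switch(m, lcs = lcs_similarity, tlcs = tlcs_similarity, wlcs = wlcs_similarity)
    value <- if (la == 0 && lb == 0) 1 else if (la == 0 || lb == 0) 0 else fun(lcsl, la, lb)
  } else if (m == "word") {
    lcsl <- NA_integer_
    value <- word_match_similarity(xa, xb)
  } else {
    lcsl <- NA_integer_
    value <- bigram_similarity(xa, xb)
  }
  tibble::tibble(measure = m, value = value, lcsl = as.integer(lcsl),
                 la = la, lb = lb)
}
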