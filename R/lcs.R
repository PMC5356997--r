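new_lcs_result <- function(length, matrix, matched_pairs, la, lb) {
  structure(
    list(length = length, matrix = matrix, matched_pairs = matched_pairs,
         la = la, lb = lb),
    class = "lcs_result"
  )
}

#' @export
print.lcs_result <- function(x, ...) {
  cat(sprintf("<lcs_result> LCSL = %d (L(A) = %d, L(B) = %d)\n",
              x$length, x$la, x$lb))
  invisible(x)
}

# Traceback of one optimal path, preferring diagonal, then up, then left,
# so matched_pairs is deterministic.
traceback_pairs <- function(c_mat, hit) {
  i <- nrow(c_mat) - 1L
  j <- ncol(c_mat) - 1L
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  while (i > 0 && j > 0) {
    if (hit[i, j] && c_mat[i + 1, j + 1] == c_mat[i, j] + 1L) {
      pairs_i <- c(i, pairs_i)
      pairs_j <- c(j, pairs_j)
      i <- i - 1L
      j <- j - 1L
    } else if (c_mat[i, j + 1] >= c_mat[i + 1, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  tibble::tibble(i = pairs_i, j = pairs_j)
}

lcs_run <- function(xa, xb, onto, epsilon, inclusive) {
  m <- length(xa)
  n <- length(xb)
  sim <- similarity_matrix(xa, xb, onto)
  c_mat <- lcs_dp_fill(sim, epsilon, inclusive)
  hit <- if (m && n) {
    if (inclusive) sim >= epsilon else sim > epsilon
  } else {
    matrix(logical(0), m, n)
  }
  pairs <- if (m && n) traceback_pairs(c_mat, hit) else tibble::tibble(i = integer(0), j = integer(0))
  new_lcs_result(c_mat[m + 1, n + 1], c_mat, pairs, m, n)
}

#' Classic longest common subsequence
#'
#' Standard LCS dynamic program over token sequences with surface equality
#' as the match test: `c[i,j] = c[i-1,j-1] + 1` when `a_i = b_j`, else
#' `max(c[i-1,j], c[i,j-1])`, with zero first row and column.
#'
#' @param x,y `token_sequence` objects or character vectors.
#' @return an `lcs_result` with the LCS length, the full DP matrix
#'   (`(m+1) x (n+1)`) and the matched index pairs of one optimal path
#'   (ties resolved diagonal first, then up, then left).
#' @examples
#' classic_lcs(c("a", "b", "c"), c("a", "x", "c"))$length
#' @export
classic_lcs <- function(x, y) {
  xa <- normalize_text(as_tokens(x))
  xb <- normalize_text(as_tokens(y))
  lcs_run(xa, xb, onto = NULL, epsilon = 0.5, inclusive = FALSE)
}

#' Semantic longest common subsequence
#'
#' LCS dynamic program in which two tokens match when their ontology
#' similarity exceeds the threshold `epsilon` (strictly, by default;
#' `inclusive = TRUE` uses `>=`). With an empty ontology and fallback off
#' the similarity degenerates to the exact-match indicator and the result
#' equals [classic_lcs()] for any `epsilon < 1`.
#'
#' @param x,y `token_sequence` objects or character vectors.
#' @param onto a [term_ontology()] or `NULL`.
#' @param epsilon matching threshold in \[0, 1\].
#' @param inclusive if `TRUE`, tokens match when similarity `>= epsilon`.
#' @return an `lcs_result`; see [classic_lcs()].
#' @export
semantic_lcs <- function(x, y, onto = NULL, epsilon = 0.8, inclusive = FALSE) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon >= 0, epsilon <= 1)
  xa <- normalize_text(as_tokens(x))
  xb <- normalize_text(as_tokens(y))
  lcs_run(xa, xb, onto, epsilon, inclusive)
}

#' Brute-force LCS oracle
#'
#' Independent test oracle: enumerates subsequences of the shorter-to-try
#' sequence from longest to shortest and returns the length of the first
#' one that embeds into the other sequence under the match predicate.
#' Exponential; refuses sequences longer than 12 tokens.
#'
#' @param x,y `token_sequence` objects or character vectors (length <= 12).
#' @param match vectorizable predicate `function(a, b)`; defaults to
#'   surface equality.
#' @return integer LCS length.
#' @export
brute_force_lcs <- function(x, y, match = function(a, b) a == b) {
  xa <- normalize_text(as_tokens(x))
  xb <- normalize_text(as_tokens(y))
  m <- length(xa)
  n <- length(xb)
  if (m > 12 || n > 12) stop("brute_force_lcs refuses sequences longer than 12 tokens")
  if (m == 0 || n == 0) return(0L)
  # evaluate the predicate once per token pair, then enumerate index subsets
  hit <- matrix(FALSE, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) hit[i, j] <- isTRUE(match(xa[i], xb[j]))
  }
  embeds <- function(idx) {
    j <- 1L
    for (i in idx) {
      while (j <= n && !hit[i, j]) j <- j + 1L
      if (j > n) return(FALSE)
      j <- j + 1L
    }
    TRUE
  }
  for (k in seq(min(m, n), 1L)) {
    combos <- utils::combn(m, k, simplify = FALSE)
    for (idx in combos) {
      if (embeds(idx)) return(as.integer(k))
    }
  }
  0L
}

# Batch LCSL of one query against many tokenized entries, sharing the
# query-vs-vocabulary similarity rows across entries.
lcs_length_many <- function(q_tokens, entry_token_list, onto = NULL,
                            epsilon = 0.8, inclusive = FALSE) {
  la <- length(q_tokens)
  if (la == 0 || length(entry_token_list) == 0) {
    return(rep(0L, length(entry_token_list)))
  }
  vocab <- unique(unlist(entry_token_list, use.names = FALSE))
  simq <- similarity_matrix(q_tokens, vocab, onto)
  vapply(entry_token_list, function(et) {
    if (length(et) == 0) return(0L)
    s <- simq[, match(et, vocab), drop = FALSE]
    lcs_dp_length(s, epsilon, inclusive)
  }, integer(1))
}

#' @export
tidy.lcs_result <- function(x, ...) x$matched_pairs

#' @export
glance.lcs_result <- function(x, ...) {
  tibble::tibble(lcsl = x$length, la = x$la, lb = x$lb)
}
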