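icd10_code_pattern <- "^[A-Z][0-9]{2}\\.[0-9]{3}$"

#' Validate 6-character ICD-10 codes
#'
#' A valid code is an upper-case letter, two digits, a dot and three digits
#' (e.g. `B15.000`).
#'
#' @param code character vector.
#' @return logical vector.
#' @export
is_valid_icd10 <- function(code) {
  grepl(icd10_code_pattern, code)
}

new_sdl <- function(entries, config) {
  structure(
    list(entries = entries, config = config),
    class = "sdl"
  )
}

#' Build a standard diagnosis library from a data frame
#'
#' Validates codes (pattern and uniqueness) and tokenizes every standard
#' name once with the supplied segmenter configuration.
#'
#' @param df data frame with columns `name` and `code`.
#' @param config a [segmenter_config()] used for the library and later for
#'   queries against it.
#' @return an object of class `sdl`.
#' @export
sdl_library <- function(df, config = segmenter_config()) {
  stopifnot(is.data.frame(df), all(c("name", "code") %in% names(df)))
  df <- tibble::as_tibble(df[, c("name", "code")])
  df$name <- as.character(df$name)
  df$code <- as.character(df$code)
  if (nrow(df) == 0) warning("standard diagnosis library is empty")
  bad <- which(!is_valid_icd10(df$code))
  if (length(bad)) {
    stop(sprintf("invalid ICD-10 code '%s' (entry %d)", df$code[bad[1]], bad[1]))
  }
  if (any(!nzchar(stringr::str_trim(df$name)))) stop("empty diagnosis name in library")
  dup <- df$code[duplicated(df$code)]
  if (length(dup)) stop("duplicate ICD-10 code(s): ", paste(unique(dup), collapse = ", "))
  df$tokens <- lapply(df$name, function(nm) tokenize(nm, config)$tokens)
  df$lb <- vapply(df$tokens, length, integer(1))
  sdl <- new_sdl(df, config)
  # caches for batch scoring: shared token vocabulary, per-entry indices
  # into it, and per-entry padded bigram lists
  sdl$vocab <- unique(unlist(df$tokens, use.names = FALSE))
  sdl$tok_idx <- lapply(df$tokens, match, sdl$vocab)
  sdl$bigrams <- lapply(df$tokens, token_bigrams)
  sdl
}

#' Load a standard diagnosis library from TSV
#'
#' Expects UTF-8 lines `name<TAB>code`; `#` comment lines and blank lines
#' are ignored. Codes must match the 6-character ICD-10 pattern and be
#' unique. Every entry is tokenized once at load time.
#'
#' @param path file path.
#' @param config a [segmenter_config()].
#' @return an `sdl` object.
#' @export
load_sdl <- function(path, config = segmenter_config()) {
  if (!file.exists(path)) stop("SDL file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(stringr::str_trim(lines)) & !grepl("^\\s*#", lines))
  rows <- lapply(keep, function(ln) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop(sprintf("malformed SDL line %d: expected name<TAB>code", ln))
    }
    name <- stringr::str_trim(parts[1])
    code <- stringr::str_trim(parts[2])
    if (!is_valid_icd10(code)) {
      stop(sprintf("SDL line %d: invalid ICD-10 code '%s'", ln, code))
    }
    tibble::tibble(name = name, code = code)
  })
  df <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(name = character(0), code = character(0))
  sdl_library(df, config)
}

#' Write a standard diagnosis library to TSV
#'
#' @param sdl an `sdl` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdl <- function(sdl, path) {
  stopifnot(inherits(sdl, "sdl"))
  writeLines(paste(sdl$entries$name, sdl$entries$code, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.sdl <- function(x, ...) {
  cat(sprintf("<sdl> %d entries\n", nrow(x$entries)))
  print(utils::head(x$entries[, c("name", "code")], 5))
  invisible(x)
}

new_coding_result <- function(query, candidates, decision, threshold) {
  structure(
    list(query = query, candidates = candidates, decision = decision,
         threshold = threshold),
    class = "coding_result"
  )
}

#' @export
print.coding_result <- function(x, ...) {
  cat(sprintf("<coding_result> query: %s\n  decision: %s (threshold %.3f)\n",
              x$query, x$decision, x$threshold))
  print(x$candidates)
  invisible(x)
}

#' Assign an ICD-10 code to one diagnosis string
#'
#' The full coding pipeline for a single query: segment and filter the
#' query with the library's segmenter configuration, score it against every
#' library entry with the chosen similarity measure (the LCS-family
#' measures run the semantic LCS with the ontology and threshold
#' `epsilon`), rank candidates, and set the routing decision. The
#' confidence of each candidate is its similarity to the query; the result
#' is `auto_output` when the top confidence strictly exceeds
#' `confidence_threshold`, else `manual_review`.
#'
#' Ties in confidence are broken by larger LCS length, then by shorter
#' standard name (fewer unmatched tokens), then by lexicographic code, so
#' the ranking is total and deterministic.
#'
#' @param query raw diagnosis string.
#' @param sdl an `sdl` object from [load_sdl()] or [sdl_library()].
#' @param onto a [term_ontology()] or `NULL`.
#' @param measure `"lcs"`, `"tlcs"`, `"wlcs"` (default), `"word-match"` or
#'   `"bigram"`.
#' @param epsilon semantic matching threshold in \[0, 1\].
#' @param top_k number of candidates to keep (>= 1).
#' @param inclusive use `>=` for the epsilon test.
#' @param confidence_threshold routing threshold; the default 0.803 is the
#'   operating point at which auto-output retains high accuracy.
#' @return a `coding_result` with ranked candidates
#'   (tibble `code`, `name`, `confidence`) and a `decision`.
#' @examples
#' fx <- paper_fixtures()
#' assign_code("JIA GAN BAN GAN HUN MI", fx$sdl, fx$ontology)
#' @export
assign_code <- function(query, sdl, onto = NULL, measure = "wlcs",
                        epsilon = 0.8, top_k = 5, inclusive = FALSE,
                        confidence_threshold = 0.803) {
  stopifnot(inherits(sdl, "sdl"), top_k >= 1)
  if (nrow(sdl$entries) == 0) stop("standard diagnosis library is empty")
  m <- normalize_measure(measure)
  q <- tokenize(query, sdl$config)
  if (length(q) == 0) stop("query segments to zero tokens: ", query)
  la <- length(q)
  lbs <- sdl$entries$lb

  if (m %in% c("lcs", "tlcs", "wlcs")) {
    # one similarity row per query token over the shared entry vocabulary,
    # then a C-level DP per entry on an index slice
    simq <- similarity_matrix(q$tokens, sdl$vocab, onto)
    lcsl <- vapply(sdl$tok_idx, function(ix) {
      if (length(ix) == 0) return(0L)
      lcs_dp_length(simq[, ix, drop = FALSE], epsilon, inclusive)
    }, integer(1))
    fun <- switch(m, lcs = lcs_similarity, tlcs = tlcs_similarity, wlcs = wlcs_similarity)
    conf <- numeric(length(lbs))
    ok <- lbs > 0
    if (any(ok)) conf[ok] <- fun(lcsl[ok], la, lbs[ok])
  } else if (m == "word") {
    # entry tokens are pre-normalized at load time; compare directly
    lcsl <- rep(NA_integer_, length(lbs))
    qt <- q$tokens
    conf <- vapply(sdl$entries$tokens, function(et) {
      as.numeric(length(et) == la && all(et == qt))
    }, numeric(1))
  } else {
    lcsl <- rep(NA_integer_, length(lbs))
    ga <- token_bigrams(q$tokens)
    conf <- vapply(sdl$bigrams, function(gb) {
      2 * multiset_intersection(ga, gb) / (length(ga) + length(gb))
    }, numeric(1))
  }

  cand <- tibble::tibble(
    code = sdl$entries$code,
    name = sdl$entries$name,
    confidence = conf,
    lcsl = lcsl,
    lb = lbs
  )
  ord <- order(-cand$confidence,
               -ifelse(is.na(cand$lcsl), 0L, cand$lcsl),
               cand$lb, cand$code)
  cand <- cand[ord, , drop = FALSE]
  cand <- utils::head(cand, top_k)
  res <- new_coding_result(query, cand[, c("code", "name", "confidence")],
                           "manual_review", confidence_threshold)
  apply_confidence_policy(res, confidence_threshold)
}

#' Apply the confidence routing policy
#'
#' Sets the decision to `auto_output` when the top candidate's confidence
#' strictly exceeds the threshold, otherwise `manual_review` (including the
#' no-candidates case). The confidence value reflects how well the output
#' code's standard name describes the query, so low-confidence assignments
#' are routed to a human coder.
#'
#' @param result a `coding_result`.
#' @param threshold routing threshold in \[0, 1\].
#' @return the updated `coding_result`.
#' @export
apply_confidence_policy <- function(result, threshold = 0.803) {
  stopifnot(inherits(result, "coding_result"),
            threshold >= 0, threshold <= 1)
  top <- if (nrow(result$candidates)) result$candidates$confidence[1] else -Inf
  result$decision <- if (top > threshold) "auto_output" else "manual_review"
  result$threshold <- threshold
  result
}

#' Code a batch of diagnoses
#'
#' Data-frame-first batch interface: takes a data frame of queries (or a
#' character vector), codes each against the library, and returns one row
#' per query with the top candidate, its confidence, and the routing
#' decision. Use `top_k > 1` together with [tidy()] on individual
#' [assign_code()] results to inspect runner-up candidates.
#'
#' @param queries data frame with a `query` column, or character vector.
#' @param sdl an `sdl` object.
#' @param onto a [term_ontology()] or `NULL`.
#' @inheritParams assign_code
#' @return tibble with columns `query`, `code`, `name`, `confidence`,
#'   `decision` (existing columns of `queries` are preserved).
#' @export
code_diagnoses <- function(queries, sdl, onto = NULL, measure = "wlcs",
                           epsilon = 0.8, inclusive = FALSE,
                           confidence_threshold = 0.803) {
  if (is.character(queries)) queries <- tibble::tibble(query = queries)
  stopifnot(is.data.frame(queries), "query" %in% names(queries))
  queries <- tibble::as_tibble(queries)
  res <- lapply(queries$query, function(qq) {
    r <- assign_code(qq, sdl, onto, measure, epsilon, top_k = 1,
                     inclusive = inclusive,
                     confidence_threshold = confidence_threshold)
    glance(r)
  })
  dplyr::bind_cols(
    queries[, setdiff(names(queries), c("code", "name", "confidence", "decision")), drop = FALSE],
    dplyr::bind_rows(res)[, c("code", "name", "confidence", "decision")]
  )
}

#' @export
tidy.coding_result <- function(x, ...) {
  dplyr::mutate(x$candidates, rank = dplyr::row_number(), .before = 1)
}

#' @export
glance.coding_result <- function(x, ...) {
  if (nrow(x$candidates) == 0) {
    return(tibble::tibble(query = x$query, code = NA_character_,
                          name = NA_character_, confidence = NA_real_,
                          decision = x$decision))
  }
  tibble::tibble(
    query = x$query,
    code = x$candidates$code[1],
    name = x$candidates$name[1],
    confidence = x$candidates$confidence[1],
    decision = x$decision
  )
}
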