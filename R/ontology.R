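#' Build a term ontology of synonym groups
#'
#' The ontology supplies the pairwise token similarity used inside the
#' semantic LCS recurrence. Two distinct surfaces that share a synonym group
#' score that group's weight; a surface may appear in several groups and the
#' maximum weight over shared groups wins. With `fallback = TRUE`, surfaces
#' sharing no group score the Dice coefficient of their character bigrams,
#' which catches small spelling variants. No transitive closure is applied
#' across groups.
#'
#' @param groups a data frame with columns `concept_id`, `weight`,
#'   `members` (list-column of character vectors), e.g. built by
#'   [synonym_group()] rows bound together, or `NULL` for an empty ontology.
#' @param fallback logical; enable the character-bigram Dice fallback.
#' @return an object of class `term_ontology`.
#' @examples
#' onto <- term_ontology(synonym_group("c1", c("YI XING GAN YAN", "XUE QING XING GAN YAN"), 0.9))
#' token_similarity("YI XING GAN YAN", "XUE QING XING GAN YAN", onto)
#' @export
term_ontology <- function(groups = NULL, fallback = FALSE) {
  if (is.null(groups)) {
    groups <- tibble::tibble(
      concept_id = character(0), weight = numeric(0), members = list()
    )
  }
  stopifnot(is.data.frame(groups),
            all(c("concept_id", "weight", "members") %in% names(groups)))
  groups <- tibble::as_tibble(groups)
  if (anyDuplicated(groups$concept_id)) {
    stop("duplicate concept_id in ontology: ",
         paste(unique(groups$concept_id[duplicated(groups$concept_id)]), collapse = ", "))
  }
  if (any(groups$weight <= 0 | groups$weight > 1)) {
    stop("synonym group weight must lie in (0, 1]")
  }
  groups$members <- lapply(groups$members, function(m) {
    m <- unique(normalize_text(m))
    m <- m[nzchar(m)]
    if (length(m) < 1) stop("synonym group must have at least one member")
    m
  })
  # pair lookup table: "a\x1fb" -> max group weight over shared groups
  pairs <- new.env(parent = emptyenv(), hash = TRUE)
  for (g in seq_len(nrow(groups))) {
    m <- groups$members[[g]]
    w <- groups$weight[g]
    if (length(m) < 2) next
    for (a in m) {
      for (b in m) {
        if (a == b) next
        key <- paste0(a, "\x1f", b)
        old <- if (exists(key, envir = pairs, inherits = FALSE)) get(key, envir = pairs) else 0
        if (w > old) assign(key, w, envir = pairs)
      }
    }
  }
  structure(
    list(groups = groups, fallback = isTRUE(fallback), pairs = pairs),
    class = "term_ontology"
  )
}

#' Define one synonym group
#'
#' @param concept_id opaque identifier, unique within an ontology.
#' @param members character vector of interchangeable term surfaces.
#' @param weight similarity in (0, 1] assigned to within-group pairs. The
#'   default 0.9 exceeds the default semantic-matching threshold (0.8), so
#'   listed synonyms count as LCS matches.
#' @return one-row tibble suitable for [term_ontology()].
#' @export
synonym_group <- function(concept_id, members, weight = 0.9) {
  tibble::tibble(
    concept_id = as.character(concept_id),
    weight = as.numeric(weight),
    members = list(as.character(members))
  )
}

#' @export
print.term_ontology <- function(x, ...) {
  cat(sprintf(
    "<term_ontology> %d groups, %d member surfaces, fallback %s\n",
    nrow(x$groups), length(unique(unlist(x$groups$members))),
    if (x$fallback) "on" else "off"
  ))
  invisible(x)
}

# Dice coefficient over character bigrams of the space-stripped surfaces;
# single characters count as their own unigram so length-1 surfaces compare.
char_bigram_dice <- function(a, b) {
  grams <- function(s) {
    s <- gsub("\\s+", "", s)
    n <- nchar(s)
    if (n == 0) return(character(0))
    if (n == 1) return(s)
    substring(s, 1:(n - 1), 2:n)
  }
  ga <- grams(a)
  gb <- grams(b)
  if (length(ga) == 0 && length(gb) == 0) return(1)
  if (length(ga) == 0 || length(gb) == 0) return(0)
  ta <- table(ga)
  tb <- table(gb)
  common <- intersect(names(ta), names(tb))
  inter <- sum(pmin(ta[common], tb[common]))
  2 * inter / (length(ga) + length(gb))
}

#' Pairwise token similarity
#'
#' Returns the maximum of: 1 if the normalized surfaces are equal; the
#' synonym-group weight if the surfaces share a group; the character-bigram
#' Dice coefficient if the ontology's fallback is on; otherwise 0.
#' Symmetric and bounded in \[0, 1\]. With an empty ontology and fallback
#' off this is the exact-match indicator (the word-matching regime).
#'
#' @param a,b tokens (character scalars, normalized or raw).
#' @param onto a [term_ontology()]; `NULL` means empty, fallback off.
#' @return similarity in \[0, 1\].
#' @export
token_similarity <- function(a, b, onto = NULL) {
  a <- normalize_text(a)
  b <- normalize_text(b)
  token_similarity_many(a, b, onto)
}

# Vectorized over b; a is scalar. Inputs assumed normalized.
token_similarity_many <- function(a, bs, onto = NULL) {
  sim <- as.numeric(a == bs)
  rest <- which(sim < 1)
  if (length(rest) == 0) return(sim)
  if (!is.null(onto)) {
    stopifnot(inherits(onto, "term_ontology"))
    keys <- paste0(a, "\x1f", bs[rest])
    w <- vapply(mget(keys, envir = onto$pairs, ifnotfound = 0), identity, numeric(1))
    sim[rest] <- pmax(sim[rest], w)
    if (onto$fallback) {
      low <- rest[sim[rest] < 1]
      if (length(low)) {
        d <- vapply(bs[low], function(b) char_bigram_dice(a, b), numeric(1))
        sim[low] <- pmax(sim[low], d)
      }
    }
  }
  sim
}

# m x n similarity matrix between two token vectors.
similarity_matrix <- function(xa, xb, onto = NULL) {
  m <- length(xa)
  n <- length(xb)
  if (m == 0 || n == 0) return(matrix(numeric(0), nrow = m, ncol = n))
  out <- matrix(0, nrow = m, ncol = n)
  for (i in seq_len(m)) out[i, ] <- token_similarity_many(xa[i], xb, onto)
  out
}

#' Load a term ontology from TSV or JSON
#'
#' TSV dialect: `concept_id<TAB>weight<TAB>member1|member2|...`, `#`
#' comments and blank lines ignored. JSON dialect: an array of objects
#' `{"id": ..., "weight": ..., "members": [...]}`. Duplicate concept ids
#' and weights outside (0, 1] are rejected.
#'
#' @param path file path (`.json` selects the JSON dialect).
#' @param fallback enable the character-bigram Dice fallback.
#' @return a [term_ontology()].
#' @export
load_ontology <- function(path, fallback = FALSE) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    groups <- dplyr::bind_rows(lapply(js, function(g) {
      if (is.null(g$id) || is.null(g$weight) || is.null(g$members)) {
        stop("ontology JSON entries need fields id, weight, members")
      }
      synonym_group(g$id, unlist(g$members), as.numeric(g$weight))
    }))
    return(term_ontology(groups, fallback = fallback))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- stringr::str_trim(stringr::str_remove(lines[ln], "^#.*$"))
    if (!nzchar(line)) next
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3) {
      stop(sprintf("malformed ontology line %d: expected 3 tab-separated fields", ln))
    }
    w <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(w)) stop(sprintf("malformed ontology line %d: weight is not numeric", ln))
    if (w <= 0 || w > 1) {
      stop(sprintf("ontology line %d: weight %s outside (0, 1]", ln, parts[2]))
    }
    members <- strsplit(parts[3], "|", fixed = TRUE)[[1]]
    rows[[length(rows) + 1]] <- synonym_group(parts[1], members, w)
  }
  groups <- if (length(rows)) dplyr::bind_rows(rows) else NULL
  term_ontology(groups, fallback = fallback)
}

#' Write a term ontology to TSV
#'
#' @param onto a [term_ontology()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(onto, path) {
  stopifnot(inherits(onto, "term_ontology"))
  lines <- vapply(seq_len(nrow(onto$groups)), function(i) {
    paste(onto$groups$concept_id[i], format(onto$groups$weight[i]),
          paste(onto$groups$members[[i]], collapse = "|"), sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
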