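#' Perturbation specification for synthetic queries
#'
#' Each operation is applied independently to a sampled standard name with
#' its stated probability, emulating how clinicians deviate from standard
#' diagnosis names: swapping a term for a synonym, dropping a modifier,
#' inserting a filler word, a small spelling mistake, or abbreviating the
#' disease root. At least one probability must be positive unless the spec
#' is explicitly the identity (all zero), which yields verbatim queries.
#' The disease-root token is never deleted, so the gold code always remains
#' recoverable.
#'
#' @param synonym_swap,token_drop,token_insert,char_typo,abbreviation
#'   per-operation probabilities in \[0, 1\].
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(synonym_swap = 0.4, token_drop = 0.25,
                              token_insert = 0.15, char_typo = 0.15,
                              abbreviation = 0.25) {
  p <- c(synonym_swap = synonym_swap, token_drop = token_drop,
         token_insert = token_insert, char_typo = char_typo,
         abbreviation = abbreviation)
  if (any(p < 0 | p > 1)) stop("perturbation probabilities must lie in [0, 1]")
  structure(as.list(p), class = "perturbation_spec")
}

# Pinyin-like syllable pool for synthetic vocabularies.
syllable_pool <- function() {
  onsets <- c("b", "p", "m", "f", "d", "t", "n", "l", "g", "k", "h",
              "j", "q", "x", "zh", "ch", "sh", "r", "z", "c", "s", "w", "y")
  rimes <- c("a", "ai", "an", "ang", "ao", "e", "ei", "en", "eng",
             "i", "ia", "ian", "iao", "in", "ing", "o", "ong", "ou",
             "u", "ua", "uan", "un", "uo")
  as.vector(outer(onsets, rimes, paste0))
}

sample_word <- function(syllables, n_syll) {
  paste(sample(syllables, n_syll, replace = TRUE), collapse = " ")
}

#' Generate a reproducible synthetic coding benchmark
#'
#' Builds a synthetic standard diagnosis library whose names are 2-8-token
#' compositions (modifiers, a disease root, and optionally the connective
#' "ban" plus a complication), a synonym ontology covering a stated
#' fraction of the vocabulary (plus abbreviations of multi-syllable roots),
#' and a set of perturbed queries with known gold codes. Generation is a
#' pure function of the parameters and `seed`.
#'
#' @param n_codes number of library entries (>= 1).
#' @param n_queries number of perturbed queries (>= 1).
#' @param vocab_size number of vocabulary words (>= 10).
#' @param spec a [perturbation_spec()].
#' @param seed integer RNG seed.
#' @param synonym_coverage fraction of vocabulary words given a synonym
#'   alias in the ontology.
#' @return list of class `lcs_benchmark` with elements `sdl`, `ontology`,
#'   `queries` (tibble `query`, `gold_code`, `ops`), `config`, `params`.
#' @examples
#' bm <- generate_benchmark(n_codes = 20, n_queries = 30, seed = 1)
#' head(bm$queries)
#' @export
generate_benchmark <- function(n_codes = 100, n_queries = 200, vocab_size = 60,
                               spec = perturbation_spec(), seed = 1,
                               synonym_coverage = 0.5) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (n_codes < 1 || n_queries < 1 || vocab_size < 10) {
    stop("need n_codes >= 1, n_queries >= 1, vocab_size >= 10")
  }
  withr::with_seed(as.integer(seed), {
    syllables <- syllable_pool()

    # vocabulary: 1-3 syllable words, unique, partitioned into roles
    vocab <- character(0)
    while (length(vocab) < vocab_size) {
      w <- sample_word(syllables, sample(1:3, 1, prob = c(0.2, 0.5, 0.3)))
      if (!(w %in% vocab) && w != "ban" && w != "bu ban") vocab <- c(vocab, w)
    }
    n_root <- max(1L, round(0.4 * vocab_size))
    n_mod <- max(1L, round(0.35 * vocab_size))
    roots <- vocab[seq_len(n_root)]
    modifiers <- vocab[seq_len(n_mod) + n_root]
    complications <- vocab[seq((n_root + n_mod + 1), vocab_size)]

    # diagnosis names: modifier* + root + (ban + complication)?
    make_name <- function() {
      n_m <- sample(0:3, 1, prob = c(0.2, 0.4, 0.3, 0.1))
      toks <- c(
        if (n_m > 0) sample(modifiers, n_m) else character(0),
        sample(roots, 1)
      )
      if (stats::runif(1) < 0.4) {
        toks <- c(toks, "ban", sample(complications, 1))
      }
      toks
    }
    names_ <- character(0)
    keys <- character(0) # filtered token sequences must be unique, else
    tries <- 0L          # verbatim self-retrieval would be ambiguous
    while (length(names_) < n_codes) {
      toks <- make_name()
      key <- paste(toks[toks != "ban"], collapse = "|")
      nm <- paste(toks, collapse = " ")
      tries <- tries + 1L
      if (!(key %in% keys)) {
        names_ <- c(names_, nm)
        keys <- c(keys, key)
      }
      if (tries > 50L * n_codes) stop("could not generate enough unique names; increase vocab_size")
    }
    idx <- seq_len(n_codes) - 1L
    codes <- paste0(
      LETTERS[idx %/% 100000L + 1L],
      sprintf("%02d", (idx %/% 1000L) %% 100L), ".",
      sprintf("%03d", idx %% 1000L)
    )

    # ontology: aliases for a fraction of vocabulary + root abbreviations
    alias_of <- function(w) {
      a <- w
      while (a %in% vocab || a %in% c("ban", "bu ban")) {
        a <- sample_word(syllables, max(1L, length(strsplit(w, " ")[[1]])))
      }
      a
    }
    n_alias <- round(synonym_coverage * vocab_size)
    aliased <- if (n_alias > 0) sample(vocab, n_alias) else character(0)
    aliases <- stats::setNames(vapply(aliased, alias_of, character(1)), aliased)
    groups <- lapply(seq_along(aliases), function(i) {
      synonym_group(paste0("syn", i), c(names(aliases)[i], aliases[[i]]), 0.9)
    })
    # abbreviation of a multi-syllable root: first + last syllable
    abbrevs <- character(0)
    for (r in roots) {
      sy <- strsplit(r, " ")[[1]]
      if (length(sy) >= 2) {
        ab <- paste(sy[c(1, length(sy))], collapse = " ")
        if (!(ab %in% vocab) && ab != r && !(ab %in% abbrevs)) {
          abbrevs[r] <- ab
          groups[[length(groups) + 1]] <-
            synonym_group(paste0("abbr", length(abbrevs)), c(r, ab), 0.9)
        }
      }
    }
    ontology <- term_ontology(if (length(groups)) dplyr::bind_rows(groups) else NULL)

    filler <- character(0)
    while (length(filler) < 5) {
      w <- sample_word(syllables, 2)
      if (!(w %in% c(vocab, unname(aliases), unname(abbrevs)))) filler <- c(filler, w)
    }

    lexicon <- unique(c(vocab, unname(aliases), unname(abbrevs), filler, "bu ban"))
    lexicon <- lexicon[vapply(lexicon, function(w) length(strsplit(w, " ")[[1]]) > 1, logical(1))]
    config <- segmenter_config(lexicon = lexicon, stop_words = "ban",
                               negation_words = "bu ban")
    sdl <- sdl_library(tibble::tibble(name = names_, code = codes), config)

    # perturbed queries
    typo <- function(w) {
      chars <- strsplit(w, "")[[1]]
      pos <- which(chars %in% letters)
      if (!length(pos)) return(w)
      i <- sample(pos, 1)
      chars[i] <- sample(setdiff(letters, chars[i]), 1)
      paste(chars, collapse = "")
    }
    pick1 <- function(cand) if (length(cand) == 1) cand else sample(cand, 1)
    # the disease root stays protected through every op (it may be swapped
    # for its ontology-registered alias or abbreviation, both recoverable,
    # but is never dropped or typo'd), so the gold code stays recoverable
    perturb <- function(name) {
      toks <- tokenize(name, config)$tokens
      is_root <- rep(FALSE, length(toks))
      rp <- which(toks %in% roots)
      if (length(rp)) is_root[rp[length(rp)]] <- TRUE
      ops <- character(0)
      if (stats::runif(1) < spec$synonym_swap) {
        cand <- which(toks %in% names(aliases))
        if (length(cand)) {
          i <- pick1(cand)
          toks[i] <- aliases[[toks[i]]]
          ops <- c(ops, "synonym_swap")
        }
      }
      if (stats::runif(1) < spec$abbreviation && any(is_root) &&
          toks[is_root] %in% names(abbrevs)) {
        toks[is_root] <- abbrevs[[toks[is_root]]]
        ops <- c(ops, "abbreviation")
      }
      if (stats::runif(1) < spec$token_drop) {
        cand <- which(toks %in% modifiers & !is_root)
        if (length(cand)) {
          i <- pick1(cand)
          toks <- toks[-i]
          is_root <- is_root[-i]
          ops <- c(ops, "token_drop")
        }
      }
      if (stats::runif(1) < spec$token_insert) {
        i <- sample(0:length(toks), 1)
        toks <- append(toks, sample(filler, 1), after = i)
        is_root <- append(is_root, FALSE, after = i)
        ops <- c(ops, "token_insert")
      }
      if (stats::runif(1) < spec$char_typo) {
        cand <- which(!is_root & !(toks %in% c("ban", "bu ban")))
        if (length(cand)) {
          i <- pick1(cand)
          toks[i] <- typo(toks[i])
          ops <- c(ops, "char_typo")
        }
      }
      list(query = paste(toks, collapse = " "),
           ops = if (length(ops)) paste(ops, collapse = "+") else "none")
    }

    pick <- sample(n_codes, n_queries, replace = TRUE)
    pert <- lapply(names_[pick], perturb)
    queries <- tibble::tibble(
      query = vapply(pert, `[[`, character(1), "query"),
      gold_code = codes[pick],
      ops = vapply(pert, `[[`, character(1), "ops")
    )

    structure(
      list(sdl = sdl, ontology = ontology, queries = queries, config = config,
           params = list(n_codes = n_codes, n_queries = n_queries,
                         vocab_size = vocab_size, seed = as.integer(seed),
                         synonym_coverage = synonym_coverage, spec = spec)),
      class = "lcs_benchmark"
    )
  })
}

#' @export
print.lcs_benchmark <- function(x, ...) {
  cat(sprintf("<lcs_benchmark> %d codes, %d queries, seed %d\n",
              nrow(x$sdl$entries), nrow(x$queries), x$params$seed))
  invisible(x)
}

#' Write a benchmark to a directory
#'
#' Writes `sdl.tsv`, `ontology.tsv`, `lexicon.txt`, `stopwords.txt` and
#' `queries.tsv` (columns `query`, `gold_code`, `ops`) so a benchmark can be
#' rerun through the command-line interface.
#'
#' @param bm an `lcs_benchmark`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bm, dir) {
  stopifnot(inherits(bm, "lcs_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sdl(bm$sdl, file.path(dir, "sdl.tsv"))
  write_ontology(bm$ontology, file.path(dir, "ontology.tsv"))
  writeLines(bm$config$lexicon, file.path(dir, "lexicon.txt"), useBytes = TRUE)
  stops <- c(
    setdiff(bm$config$stop_words, bm$config$negation_words),
    paste0(bm$config$negation_words, "\tNEG")
  )
  writeLines(stops, file.path(dir, "stopwords.txt"), useBytes = TRUE)
  q <- bm$queries
  writeLines(c("query\tgold_code\tops",
               paste(q$query, q$gold_code, q$ops, sep = "\t")),
             file.path(dir, "queries.tsv"), useBytes = TRUE)
  invisible(dir)
}
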