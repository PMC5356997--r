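#' Segmenter configuration
#'
#' Bundles the vocabulary and filtering word lists that drive word
#' segmentation. The segmenter is a deterministic forward-maximum-matching
#' (FMM) tokenizer over a user-supplied lexicon; any span not covered by a
#' lexicon entry falls back to single-unit tokens. In `"char"` mode every
#' unit becomes its own token and the lexicon is ignored.
#'
#' Negation words ("BU BAN" / without) are exempt from stop-word removal
#' because they flip the clinical meaning of a diagnosis; a word listed in
#' both `stop_words` and `negation_words` is kept.
#'
#' @param lexicon character vector of vocabulary entries (multi-unit words).
#' @param stop_words character vector of removable connective words.
#' @param negation_words character vector of words exempt from removal and
#'   flagged as negations.
#' @param mode `"token"` (lexicon FMM, the default) or `"char"`
#'   (every unit is a token).
#' @return an object of class `segmenter_config`.
#' @examples
#' cfg <- segmenter_config(
#'   lexicon = c("JIA XING", "BING DU XING GAN YAN", "GAN HUN MI"),
#'   stop_words = "BAN", negation_words = "BU BAN"
#' )
#' segment("JIA XING BING DU XING GAN YAN BAN GAN HUN MI", cfg)
#' @export
segmenter_config <- function(lexicon = character(),
                             stop_words = character(),
                             negation_words = character(),
                             mode = c("token", "char")) {
  mode <- match.arg(mode)
  lexicon <- unique(normalize_text(lexicon))
  lexicon <- lexicon[nzchar(lexicon)]
  stop_words <- unique(normalize_text(stop_words))
  stop_words <- stop_words[nzchar(stop_words)]
  negation_words <- unique(normalize_text(negation_words))
  negation_words <- negation_words[nzchar(negation_words)]

  lex_units <- lapply(lexicon, text_units)
  lens <- vapply(lex_units, length, integer(1))
  # only multi-unit entries matter for FMM; single units fall back anyway
  keys <- vapply(lex_units, paste, character(1), collapse = "\x1f")
  structure(
    list(
      lexicon = lexicon,
      stop_words = stop_words,
      negation_words = negation_words,
      mode = mode,
      lex_keys = keys,
      max_len = if (length(lens)) max(lens) else 1L
    ),
    class = "segmenter_config"
  )
}

#' @export
print.segmenter_config <- function(x, ...) {
  cat(sprintf(
    "<segmenter_config> mode=%s, %d lexicon entries, %d stop words, %d negation words\n",
    x$mode, length(x$lexicon), length(x$stop_words), length(x$negation_words)
  ))
  invisible(x)
}

new_token_sequence <- function(tokens, is_negation, source) {
  structure(
    list(
      tokens = as.character(tokens),
      is_negation = as.logical(is_negation),
      source = source
    ),
    class = "token_sequence"
  )
}

#' @export
length.token_sequence <- function(x) length(x$tokens)

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence> L = %d\n", length(x)))
  if (length(x)) {
    marks <- ifelse(x$is_negation, " [NEG]", "")
    cat(paste0("  ", seq_along(x$tokens), ": ", x$tokens, marks), sep = "\n")
  }
  invisible(x)
}

#' @export
as.character.token_sequence <- function(x, ...) x$tokens

# Accept token_sequence or plain character vector everywhere downstream.
as_tokens <- function(x) {
  if (inherits(x, "token_sequence")) x$tokens else as.character(x)
}

#' Segment a diagnosis string into a token sequence
#'
#' Greedy forward longest match against the configured lexicon: at each
#' position the longest lexicon entry starting there wins; units not covered
#' by any entry are emitted as single-unit tokens. Whitespace-separated
#' chunks (pinyin syllables) are the atomic units of ASCII text; CJK text is
#' split into per-character units, so segmentation works identically on
#' transcribed and native input.
#'
#' @param text raw diagnosis string (may be empty).
#' @param config a [segmenter_config()].
#' @return a `token_sequence` preserving token order of appearance.
#' @export
segment <- function(text, config = segmenter_config()) {
  stopifnot(inherits(config, "segmenter_config"))
  norm <- normalize_text(if (is.null(text) || length(text) == 0) "" else text)
  units <- text_units(norm)
  n <- length(units)
  if (n == 0) return(new_token_sequence(character(0), logical(0), norm))

  if (config$mode == "char") {
    return(new_token_sequence(units, rep(FALSE, n), norm))
  }

  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    k_max <- min(config$max_len, n - i + 1L)
    k_hit <- 1L
    if (k_max >= 2L && length(config$lex_keys)) {
      for (k in seq(k_max, 2L)) {
        key <- paste(units[i:(i + k - 1L)], collapse = "\x1f")
        if (key %in% config$lex_keys) {
          k_hit <- k
          break
        }
      }
    }
    tokens <- c(tokens, join_units(units[i:(i + k_hit - 1L)]))
    i <- i + k_hit
  }
  new_token_sequence(tokens, rep(FALSE, length(tokens)), norm)
}

#' Remove stop words from a token sequence
#'
#' Drops tokens listed as stop words, except negation words, which are
#' always retained (and flagged) because removing "without" would merge
#' e.g. "hepatitis A without hepatic coma" into its opposite. Idempotent;
#' survivor order is preserved.
#'
#' @param seq a `token_sequence` from [segment()].
#' @param config a [segmenter_config()].
#' @return filtered `token_sequence`.
#' @export
filter_words <- function(seq, config = segmenter_config()) {
  stopifnot(inherits(seq, "token_sequence"), inherits(config, "segmenter_config"))
  toks <- seq$tokens
  is_neg <- toks %in% config$negation_words
  keep <- !(toks %in% config$stop_words) | is_neg
  new_token_sequence(toks[keep], is_neg[keep], seq$source)
}

#' Segment and filter in one step
#'
#' @inheritParams segment
#' @return filtered `token_sequence`.
#' @export
tokenize <- function(text, config = segmenter_config()) {
  filter_words(segment(text, config), config)
}

#' Read a lexicon file
#'
#' UTF-8 plain text, one entry per line; `#` starts a comment; blank lines
#' ignored.
#'
#' @param path file path.
#' @return character vector of entries.
#' @export
load_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
  lines[nzchar(lines)]
}

#' Read a stop-word file
#'
#' Same format as [load_lexicon()]; a line whose entry is followed by a tab
#' and `NEG` marks a negation word (kept during filtering, flagged on
#' tokens).
#'
#' @param path file path.
#' @return list with elements `stop_words` and `negation_words`.
#' @export
load_stopwords <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"), side = "right")
  lines <- lines[nzchar(stringr::str_trim(lines))]
  parts <- stringr::str_split(lines, "\t")
  words <- stringr::str_trim(vapply(parts, `[`, character(1), 1))
  neg <- vapply(parts, function(p) length(p) > 1 && toupper(stringr::str_trim(p[2])) == "NEG", logical(1))
  list(stop_words = words, negation_words = words[neg])
}
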