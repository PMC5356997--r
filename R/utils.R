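#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; similarity tables in the coding
#' literature are printed with conventional half-up rounding, so regression
#' against printed values needs this variant.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (half away from zero).
#' @examples
#' round_half_up(c(0.005, 0.865, 2/3), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Normalize text for matching
#'
#' Unicode NFC normalization, case folding and whitespace squeezing, applied
#' to every string (queries, lexicon entries, ontology members, library
#' names) before any comparison.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- stringi::stri_trans_tolower(x)
  stringr::str_squish(x)
}

# Split a normalized string into matching units. A whitespace-separated
# chunk is one unit (pinyin transcription: one syllable stands for one
# Chinese character); a chunk containing non-ASCII (CJK) characters is
# split into per-character units.
text_units <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  chunks <- strsplit(x, "\\s+")[[1]]
  chunks <- chunks[nzchar(chunks)]
  out <- lapply(chunks, function(ch) {
    if (stringr::str_detect(ch, "[^\\x01-\\x7f]")) {
      strsplit(ch, "")[[1]]
    } else {
      ch
    }
  })
  unlist(out, use.names = FALSE)
}

# Join units back into a token surface: pinyin syllables with spaces,
# CJK characters without.
join_units <- function(units) {
  if (length(units) == 0) return("")
  ascii <- !stringr::str_detect(units, "[^\\x01-\\x7f]")
  if (all(ascii)) paste(units, collapse = " ") else paste(units, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
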