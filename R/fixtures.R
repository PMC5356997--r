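#' Bundled worked examples
#'
#' Returns the small pinyin-transcribed reference set used throughout the
#' documentation and tests: a four-entry hepatitis-A standard diagnosis
#' library, the segmenter configuration that reproduces the published token
#' sequences, the abbreviated query and its gold code, a small synonym
#' ontology linking the abbreviation "JIA GAN" to the full hepatitis-A
#' terms, and the 30-row similarity reference table.
#'
#' The reference table lists printed similarity values for all triples
#' `L(A) = 1..6`, `L(B) = L(A)..L(A)+4`, `LCSL = L(A)`. Each row carries a
#' `consistent` flag computed by re-evaluating the three formulas: the ten
#' rows with `L(A) >= 5` contain printed values that disagree with the
#' formulas (typographical errors in the source table) and are flagged
#' `FALSE`.
#'
#' @return list with elements `sdl`, `config`, `ontology`, `query_exact`,
#'   `query_abbrev`, `gold_code`, `segmentation_example` (list with `raw`,
#'   `segmented`, `filtered`), and `table3` (tibble with columns `la`, `lb`,
#'   `lcsl`, `lcs`, `tlcs`, `wlcs`, `consistent`).
#' @examples
#' fx <- paper_fixtures()
#' nrow(fx$sdl$entries)
#' sum(fx$table3$consistent)
#' @export
paper_fixtures <- function() {
  config <- segmenter_config(
    lexicon = c(
      "JIA XING", "BING DU XING GAN YAN", "GAN HUN MI",
      "JI XING", "ZHONG XING", "YA JI XING",
      "JIA GAN", "BU BAN", "BAN"
    ),
    stop_words = c("BAN"),
    negation_words = c("BU BAN")
  )
  sdl <- sdl_library(
    tibble::tibble(
      name = c(
        "JIA XING BING DU XING GAN YAN BAN GAN HUN MI",
        "JI XING JIA XING BING DU XING GAN YAN BAN GAN HUN MI",
        "JI XING ZHONG XING JIA XING BING DU XING GAN YAN BAN GAN HUN MI",
        "YA JI XING ZHONG XING JIA XING BING DU XING GAN YAN BAN GAN HUN MI"
      ),
      code = c("B15.000", "B15.001", "B15.002", "B15.003")
    ),
    config
  )
  ontology <- term_ontology(dplyr::bind_rows(
    synonym_group("abbrev-hepatitis-a-1", c("JIA GAN", "JIA XING"), 0.9),
    synonym_group("abbrev-hepatitis-a-2", c("JIA GAN", "BING DU XING GAN YAN"), 0.9),
    synonym_group("serum-hepatitis", c("YI XING GAN YAN", "XUE QING XING GAN YAN"), 0.9)
  ))

  table3 <- tibble::tibble(
    la   = rep(1:6, each = 5),
    lb   = unlist(lapply(1:6, function(a) a:(a + 4))),
    lcsl = rep(1:6, each = 5),
    lcs  = c(1.00, 0.50, 0.33, 0.25, 0.20,
             1.00, 0.67, 0.50, 0.40, 0.33,
             1.00, 0.75, 0.60, 0.50, 0.43,
             1.00, 0.80, 0.67, 0.57, 0.50,
             1.00, 0.81, 0.75, 0.67, 0.55,
             1.00, 0.80, 0.71, 0.66, 0.60),
    tlcs = c(1.00, 0.67, 0.50, 0.40, 0.33,
             1.00, 0.80, 0.67, 0.57, 0.50,
             1.00, 0.86, 0.75, 0.67, 0.60,
             1.00, 0.89, 0.80, 0.73, 0.67,
             1.00, 0.90, 0.82, 0.82, 0.68,
             1.00, 0.85, 0.76, 0.72, 0.65),
    wlcs = c(1.00, 0.67, 0.50, 0.40, 0.33,
             1.00, 0.86, 0.75, 0.67, 0.60,
             1.00, 0.92, 0.86, 0.80, 0.75,
             1.00, 0.95, 0.91, 0.87, 0.83,
             1.00, 0.92, 0.90, 0.87, 0.84,
             1.00, 0.91, 0.83, 0.78, 0.70)
  )
  table3$consistent <-
    round_half_up(lcs_similarity(table3$lcsl, table3$la, table3$lb), 2) == table3$lcs &
    round_half_up(tlcs_similarity(table3$lcsl, table3$la, table3$lb), 2) == table3$tlcs &
    round_half_up(wlcs_similarity(table3$lcsl, table3$la, table3$lb), 2) == table3$wlcs

  list(
    sdl = sdl,
    config = config,
    ontology = ontology,
    query_exact = "JIA XING BING DU XING GAN YAN BAN GAN HUN MI",
    query_abbrev = "JIA GAN BAN GAN HUN MI",
    gold_code = "B15.000",
    segmentation_example = list(
      raw = "JIA XING BING DU XING GAN YAN BAN GAN HUN MI",
      segmented = c("jia xing", "bing du xing gan yan", "ban", "gan hun mi"),
      filtered = c("jia xing", "bing du xing gan yan", "gan hun mi")
    ),
    table3 = table3
  )
}
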