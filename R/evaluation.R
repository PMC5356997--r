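#' Score predictions against a gold standard
#'
#' Retrieval-style confusion counts for top-1 coding: a prediction equal to
#' the gold code is a true positive, a prediction differing from it a false
#' positive, and an abstention (NA prediction or a `manual_review` decision)
#' a false negative — an unreturned relevant record.
#'
#' @param predictions data frame with columns `query` and `code`
#'   (`NA` = abstain); an optional `decision` column turns `manual_review`
#'   rows into abstentions.
#' @param gold data frame with columns `query` and `code`, or a named
#'   character vector `query -> code`. Every predicted query must appear.
#' @return tibble with columns `tp`, `fp`, `fn`.
#' @examples
#' preds <- tibble::tibble(query = c("a", "b", "c"),
#'                         code = c("A00.000", "A00.001", NA))
#' gold <- tibble::tibble(query = c("a", "b", "c"),
#'                        code = c("A00.000", "A00.000", "A00.002"))
#' score_predictions(preds, gold)
#' @export
score_predictions <- function(predictions, gold) {
  stopifnot(is.data.frame(predictions), all(c("query", "code") %in% names(predictions)))
  if (is.data.frame(gold)) {
    stopifnot(all(c("query", "code") %in% names(gold)))
    gold_map <- stats::setNames(as.character(gold$code), gold$query)
  } else {
    gold_map <- gold
  }
  missing <- setdiff(predictions$query, names(gold_map))
  if (length(missing)) {
    stop("query missing from gold standard: ", paste(utils::head(missing, 3), collapse = "; "))
  }
  pred <- as.character(predictions$code)
  if ("decision" %in% names(predictions)) {
    pred[predictions$decision == "manual_review"] <- NA_character_
  }
  g <- unname(gold_map[predictions$query])
  abstain <- is.na(pred)
  tibble::tibble(
    tp = sum(!abstain & pred == g),
    fp = sum(!abstain & pred != g),
    fn = sum(abstain)
  )
}

#' Precision, recall and F-score from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`, and the F-score
#' is their harmonic mean `2pr / (p + r)` (0 when both are 0). When nothing
#' was retrieved (`tp + fp = 0`) precision is defined as 0 with a warning so
#' the F-score stays computable.
#'
#' @param counts data frame (or list) with elements `tp`, `fp`, `fn`, e.g.
#'   from [score_predictions()]. All-zero counts are an error.
#' @param quiet suppress the degenerate-precision warning.
#' @return tibble with columns `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `fscore`.
#' @export
precision_recall_fscore <- function(counts, quiet = FALSE) {
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  stopifnot(length(tp) == 1, tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) stop("metrics undefined: tp + fp + fn = 0")
  if (tp + fp == 0) {
    if (!quiet) warning("no predictions retrieved (tp + fp = 0); precision set to 0")
    p <- 0
  } else {
    p <- tp / (tp + fp)
  }
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = p, recall = r, fscore = f)
}

#' Sweep the confidence threshold and evaluate each operating point
#'
#' Codes every labeled query once per measure (the ranking does not depend
#' on the routing threshold), then re-applies the confidence policy at each
#' threshold: queries whose top confidence exceeds the threshold are
#' auto-coded, the rest abstain. Each row reports the confusion counts,
#' precision/recall/F-score (abstentions count as false negatives) and the
#' coverage — the fraction of queries auto-coded. Coverage is non-increasing
#' in the threshold; raising the threshold trades coverage for accuracy.
#'
#' @param queries data frame with columns `query` and `gold_code`.
#' @param sdl an `sdl` object.
#' @param onto a [term_ontology()] or `NULL`.
#' @param measures character vector of measures to evaluate.
#' @param thresholds ascending numeric vector of confidence thresholds.
#' @param epsilon semantic matching threshold.
#' @param inclusive use `>=` for the epsilon test.
#' @return tibble of class `lcs_sweep`: one row per measure x threshold with
#'   columns `measure`, `threshold`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `fscore`, `coverage`.
#' @export
threshold_sweep <- function(queries, sdl, onto = NULL, measures = "wlcs",
                            thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9),
                            epsilon = 0.8, inclusive = FALSE) {
  stopifnot(is.data.frame(queries), all(c("query", "gold_code") %in% names(queries)))
  if (nrow(queries) == 0) stop("empty query set")
  stopifnot(is.numeric(thresholds), !is.unsorted(thresholds))
  n <- nrow(queries)
  out <- list()
  for (ms in measures) {
    m <- normalize_measure(ms)
    coded <- code_diagnoses(queries, sdl, onto, measure = m, epsilon = epsilon,
                            inclusive = inclusive, confidence_threshold = 0)
    for (th in thresholds) {
      auto <- coded$confidence > th
      counts <- tibble::tibble(
        tp = sum(auto & coded$code == queries$gold_code),
        fp = sum(auto & coded$code != queries$gold_code),
        fn = sum(!auto)
      )
      rep <- precision_recall_fscore(counts, quiet = TRUE)
      rep$measure <- m
      rep$threshold <- th
      rep$coverage <- mean(auto)
      out[[length(out) + 1]] <- rep
    }
  }
  res <- dplyr::bind_rows(out)[, c("measure", "threshold", "tp", "fp", "fn",
                                   "precision", "recall", "fscore", "coverage")]
  class(res) <- c("lcs_sweep", class(res))
  res
}
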