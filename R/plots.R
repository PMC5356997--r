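#' Plot a threshold sweep
#'
#' F-score and coverage against the confidence threshold, one colour per
#' measure: the visual form of the accuracy/coverage trade-off that the
#' routing policy exploits.
#'
#' @param object an `lcs_sweep` tibble from [threshold_sweep()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lcs_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("measure", "threshold", "fscore", "coverage")],
    cols = c("fscore", "coverage"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::labs(x = "confidence threshold", y = NULL,
                  title = "Coding accuracy and coverage by confidence threshold") +
    ggplot2::theme_minimal()
}

#' Plot candidate confidences for one coding result
#'
#' @param object a `coding_result` from [assign_code()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.coding_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$code, .data$confidence),
                                   y = .data$confidence)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "confidence",
                  title = paste("Candidates for:", object$query),
                  subtitle = paste("decision:", object$decision)) +
    ggplot2::theme_minimal()
}
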