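# ggplot2 summaries of the main result types.

#' Plot per-attribute PChem missingness
#'
#' @param records Record tibble.
#' @return A ggplot bar chart of missing fractions.
#' @export
plot_missingness <- function(records) {
  miss <- summarize_missingness(records)
  ggplot2::ggplot(miss,
                  ggplot2::aes(x = .data$attribute,
                               y = .data$missing_fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "missing values",
                  title = "PChem attribute missingness") +
    ggplot2::theme_minimal()
}

#' Plot the PChem score distribution, optionally before vs after filling
#'
#' @param scored Scored record tibble (see [score_records()]).
#' @param filled Optional second scored tibble (e.g. the gap-filled tier)
#'   overlaid for comparison.
#' @return A ggplot histogram of final PChem scores.
#' @export
plot_score_distribution <- function(scored, filled = NULL) {
  df <- dplyr::mutate(scored[, "pchem_score"], stage = "original")
  if (!is.null(filled)) {
    df <- dplyr::bind_rows(
      df, dplyr::mutate(filled[, "pchem_score"], stage = "gap-filled")
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pchem_score,
                                   fill = .data$stage)) +
    ggplot2::geom_histogram(binwidth = 0.25, boundary = 0,
                            position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "final PChem score (0-5)", y = "records",
                  title = "PChem score distribution") +
    ggplot2::theme_minimal()
}

#' Per-replication validation metrics of an experiment
#'
#' @param object A `nanosar_experiment`.
#' @param ... Unused.
#' @return A ggplot of precision, sensitivity, accuracy and F1 per
#'   replication with the replication means.
#' @export
autoplot.nanosar_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics,
    c("precision", "sensitivity", "accuracy", "f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$replication)),
                        alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, colour = "replication",
                  title = "External validation (Toxic positive)") +
    ggplot2::theme_minimal()
}

#' Leave-one-out OOB errors by removed attribute
#'
#' @param object An `importance_report`.
#' @param ... Unused.
#' @return A ggplot bar chart, baseline OOB error as a dashed line.
#' @export
autoplot.importance_report <- function(object, ...) {
  imp <- object$importance
  ggplot2::ggplot(imp,
                  ggplot2::aes(x = stats::reorder(.data$attribute,
                                                  .data$oob_error),
                               y = .data$oob_error)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::geom_hline(yintercept = object$baseline_oob,
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "OOB error without the attribute",
                  title = "Leave-one-out OOB importance") +
    ggplot2::theme_minimal()
}
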