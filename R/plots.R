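# ggplot2 views of the main result types.

#' Plot cross-validated performance per learner
#' @param object A `trace_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trace_cv
#' @export
autoplot.trace_cv <- function(object, ...) {
  m <- tidyr::pivot_longer(object$metrics[, c("learner", "auc", "auprc")],
                           c("auc", "auprc"),
                           names_to = "metric", values_to = "value")
  m$learner <- factor(m$learner, levels = c(learner_names, "meta"))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$learner, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Cross-validated performance by learner") +
    ggplot2::theme_minimal()
}

#' Plot score distributions by gene group
#' @param cv A `trace_cv` whose labels carried a `group` column.
#' @return A ggplot.
#' @export
plot_score_groups <- function(cv) {
  stopifnot(inherits(cv, "trace_cv"), "group" %in% names(cv$scores))
  ggplot2::ggplot(cv$scores,
                  ggplot2::aes(x = .data$group, y = .data$trace_score)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "stacked score (0-10)") +
    ggplot2::theme_minimal()
}

#' Plot the top features of a tissue importance report
#' @param object A `tt_importance`.
#' @param n_top Features shown (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tt_importance
#' @export
autoplot.tt_importance <- function(object, n_top = 20, ...) {
  top <- dplyr::slice_max(object$importance, .data$normalized_importance,
                          n = n_top)
  ggplot2::ggplot(top, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$normalized_importance),
    y = .data$normalized_importance, fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized Shapley importance") +
    ggplot2::theme_minimal()
}

#' Plot verified-gene ranks of a patient benchmark
#' @param object A `tt_benchmark`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tt_benchmark
#' @export
autoplot.tt_benchmark <- function(object, ...) {
  s <- tidyr::pivot_longer(
    object$summary[, c("patient", "verified_rank", "baseline_rank")],
    c("verified_rank", "baseline_rank"),
    names_to = "method", values_to = "rank")
  s$method <- ifelse(s$method == "verified_rank", "stacked model",
                     "expression baseline")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$method, y = .data$rank)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "verified-gene rank (1 = best)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
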