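#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-sample graph-measure plot
#'
#' Median with a one-standard-deviation error bar per sample (computed over
#' that sample's time points), the standard view for comparing the control
#' and transgenic groups on a graph statistic.
#'
#' @param measures Output of [measure_table()].
#' @param metadata Validated metadata tibble (for group colouring).
#' @param measure `"sbwc"` or `"mti"`.
#' @return A ggplot object.
#' @export
plot_measures <- function(measures, metadata, measure = c("sbwc", "mti")) {
  measure <- match.arg(measure)
  summ <- measure_summary(measures) |>
    left_join(distinct(metadata, .data$sample_id, .data$group),
              by = "sample_id")
  med <- paste0(measure, "_median")
  sdev <- paste0(measure, "_sd")
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$sample_id, y = .data[[med]], colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data[[med]] - .data[[sdev]],
      ymax = .data[[med]] + .data[[sdev]]), width = 0.3) +
    ggplot2::labs(x = "sample", y = paste(toupper(measure), "(median over time points)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn evaluate_roc ROC curves per noise amplitude.
#' @param object A `ca_roc` object.
#' @param ... Unused.
#' @export
#' @method autoplot ca_roc
autoplot.ca_roc <- function(object, ...) {
  ggplot2::ggplot(object$curves, ggplot2::aes(
    x = .data$fpr, y = .data$tpr, colour = factor(.data$sigma))) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "noise sigma",
                  title = sprintf("dim %d, noise-averaged AUC = %.3f",
                                  object$dim, object$mean_auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Attractor-size distribution plot for an attractor set
#'
#' @param object A `ca_attractor_set`.
#' @param ... Unused.
#' @return A ggplot object (log-log size distribution with fitted slope when
#'   a power-law fit is possible).
#' @export
#' @method autoplot ca_attractor_set
autoplot.ca_attractor_set <- function(object, ...) {
  fit <- tryCatch(powerlaw_fit(object$attractors$size), error = function(e) NULL)
  if (!is.null(fit)) return(autoplot(fit))
  ggplot2::ggplot(object$attractors, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "attractor size K", y = "count") +
    ggplot2::theme_minimal()
}
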