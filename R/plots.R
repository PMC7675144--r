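# ggplot2 views of fitted models and population reports.

#' STRF heatmap of a fitted model
#'
#' Displays the effective channels x lags filter (the product of the
#' spectral and temporal factors).
#'
#' @param object a [fitted_model()].
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot fitted_model
#' @export
autoplot.fitted_model <- function(object, ...) {
  Hf <- effective_filter(object$strf)
  df <- tibble(
    channel = as.integer(row(Hf)),
    lag_ms = (as.integer(col(Hf)) - 1L) * 10,
    weight = as.vector(Hf)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lag_ms, .data$channel,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", name = "weight") +
    ggplot2::labs(x = "lag (ms)", y = "spectral channel",
                  title = paste(object$architecture, "effective STRF"))
}

#' Population medians and improvement scatter
#'
#' `autoplot()` of a population report shows the median noise-adjusted
#' prediction correlation per architecture (bar panel) next to the
#' per-neuron LN versus GC+STP scatter colored by the improvement flag.
#'
#' @param object a [run_experiment()] report.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot population_report
#' @export
autoplot.population_report <- function(object, ...) {
  s <- object$summary
  med <- tibble(
    architecture = factor(c("LN", "STP", "GC", "GC+STP"),
                          levels = c("LN", "STP", "GC", "GC+STP")),
    median_r = c(s$median_r$ln, s$median_r$stp, s$median_r$gc,
                 s$median_r$both)
  )
  ggplot2::ggplot(med, ggplot2::aes(.data$architecture, .data$median_r)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "median prediction correlation")
}

#' Per-neuron improvement scatter
#'
#' LN versus GC+STP noise-adjusted prediction correlation, colored by the
#' jackknife improvement flag.
#'
#' @param report a [run_experiment()] report.
#' @return a ggplot object.
#' @export
plot_improvement_scatter <- function(report) {
  df <- report$neurons
  ggplot2::ggplot(df, ggplot2::aes(.data$r_ln, .data$r_both,
                                   colour = .data$improved)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#B2182B",
                                            `FALSE` = "grey50"),
                                 name = "improved") +
    ggplot2::labs(x = "LN prediction correlation",
                  y = "GC+STP prediction correlation")
}

#' Equivalence histogram
#'
#' Distribution of the per-neuron STP-vs-GC equivalence score (partial
#' correlation relative to the LN prediction), split by the improvement
#' flag when available.
#'
#' @param report a [run_experiment()] report.
#' @param binwidth histogram bin width.
#' @return a ggplot object.
#' @export
plot_equivalence_histogram <- function(report, binwidth = 0.05) {
  df <- report$neurons[!is.na(report$neurons$equivalence), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$equivalence)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35",
                            colour = "white") +
    ggplot2::labs(x = "equivalence (partial correlation)", y = "neurons")
  if ("improved" %in% names(df) && any(!is.na(df$improved))) {
    p <- p + ggplot2::facet_wrap(~improved,
                                 labeller = ggplot2::label_both, ncol = 1)
  }
  p
}
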