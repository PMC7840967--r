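# ggplot2 visualisations for the package's result objects.

#' Plot a burden result
#'
#' Point-range plot of the four burden metrics with their confidence
#' intervals, each metric on its own panel (free scales).
#'
#' @param object A `burden_result` from [burden_metrics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot burden_result
#' @export
autoplot.burden_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high)
    ) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(
      x = NULL, y = "estimate (95% CI)",
      title = sprintf("%s burden: %d observed vs %.1f expected",
                      object$mode, object$observed, object$expected)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a gene discovery result
#'
#' Quantile-quantile plot of the per-gene minimum Poisson p-values against
#' the uniform expectation, highlighting genes past the significance
#' threshold.
#'
#' @param object A `gene_test_result` from [run_gene_discovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_test_result
#' @export
autoplot.gene_test_result <- function(object, ...) {
  d <- tidy(object)
  d <- d[order(d$p.value), ]
  n <- nrow(d)
  d$expected <- -log10(stats::ppoints(n))
  d$observed <- -log10(pmax(d$p.value, .Machine$double.xmin))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expected, y = .data$observed,
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = expression(-log[10] ~ "expected p"),
      y = expression(-log[10] ~ "observed p"),
      colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' Plot stratified positive predictive values
#'
#' Bar-with-interval plot of PPV per stratum, as produced by
#' [stratified_ppv()].
#'
#' @param strata A tibble with columns `stratum`, `ppv`, `ppv_lo`, `ppv_hi`.
#' @return A ggplot object.
#' @export
plot_stratified_ppv <- function(strata) {
  ggplot2::ggplot(strata, ggplot2::aes(x = stats::reorder(.data$stratum,
                                                          .data$ppv),
                                       y = .data$ppv)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ppv_lo, ymax = .data$ppv_hi), width = 0.2
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "positive predictive value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
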