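# Broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a burden result
#'
#' One row per metric (`burden`, `excess`, `attributable_fraction`, `ppv`)
#' with `estimate`, `conf.low`, `conf.high`.
#'
#' @param x A `burden_result` from [burden_metrics()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy burden_result
#' @export
tidy.burden_result <- function(x, ...) {
  metrics <- c(burden = "burden", excess = "excess",
               attributable_fraction = "af", ppv = "ppv")
  tibble::tibble(
    metric = names(metrics),
    estimate = purrr::map_dbl(names(metrics), ~ x[[.x]]),
    conf.low = purrr::map_dbl(metrics, ~ x[[paste0(.x, "_lo")]]),
    conf.high = purrr::map_dbl(metrics, ~ x[[paste0(.x, "_hi")]])
  )
}

#' Glance at a burden result
#'
#' @param x A `burden_result` from [burden_metrics()].
#' @param ... Unused.
#' @return A one-row tibble: mode, counts, enrichment p-value.
#' @method glance burden_result
#' @export
glance.burden_result <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    observed = x$observed,
    expected = x$expected,
    n_probands = x$n_probands,
    p_enrichment = x$p_enrichment
  )
}

#' Tidy a gene discovery result
#'
#' Standardises the per-gene table: `gene_id`, `p.value` (the minimum
#' Poisson-arm p-value), `bayes_factor`, `q.value`, `significant`.
#'
#' @param x A `gene_test_result` from [run_gene_discovery()].
#' @param ... Unused.
#' @return A tibble sorted by evidence.
#' @method tidy gene_test_result
#' @export
tidy.gene_test_result <- function(x, ...) {
  out <- tibble::tibble(
    gene_id = x$gene_id,
    p.value = pmin(x$p_poisson_female, x$p_poisson_combined, na.rm = TRUE),
    bayes_factor = x$bf_total,
    q.value = x$q_value,
    significant = x$significant
  )
  dplyr::arrange(out, .data$p.value, dplyr::desc(.data$bayes_factor))
}

#' Glance at a gene discovery result
#'
#' @param x A `gene_test_result` from [run_gene_discovery()].
#' @param ... Unused.
#' @return A one-row tibble: genes tested, significant count, threshold.
#' @method glance gene_test_result
#' @export
glance.gene_test_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    threshold = attr(x, "threshold")
  )
}
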