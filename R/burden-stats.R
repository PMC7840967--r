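# Burden ratio, excess, attributable fraction and PPV, with Poisson
# enrichment tests and the two CI constructions: exact-Poisson substitution
# for DNM expectations and MOVER intervals for case/control rates.

#' Upper-tailed Poisson enrichment test
#'
#' `p = P(X >= observed)` for `X ~ Poisson(expected)`.
#'
#' @param observed Observed count (vectorised).
#' @param expected Expected count under the null; must be positive.
#' @return Upper-tail p-value(s).
#' @export
#' @examples
#' poisson_enrichment(5, 1)
poisson_enrichment <- function(observed, expected) {
  if (any(expected <= 0)) abort("`expected` must be positive")
  if (any(observed < 0)) abort("`observed` must be non-negative")
  ppois(observed - 1, expected, lower.tail = FALSE)
}

#' Confidence intervals for DNM burden metrics by expected-count substitution
#'
#' For de novo enrichment the observed count is treated as fixed and the
#' uncertainty placed on the expectation: an exact Poisson 95% interval
#' `(lo_E, hi_E)` is computed around the expected count (Garwood gamma
#' inversion, valid for non-integer expectations) and substituted into the
#' burden, attributable-fraction and PPV formulae — `hi_E` gives each
#' metric's lower bound and `lo_E` its upper bound.
#'
#' @param observed Observed DNM count (held fixed).
#' @param expected Expected DNM count (>= 0).
#' @param n_probands Cohort size, needed for the attributable fraction.
#' @param level Confidence level.
#' @return A one-row tibble with `expected_lo`, `expected_hi` and `lo`/`hi`
#'   pairs for `burden`, `af` and `ppv`.
#' @export
dnm_metric_cis <- function(observed, expected, n_probands, level = 0.95) {
  if (expected < 0) abort("`expected` must be non-negative")
  a <- 1 - level
  lo_e <- if (expected == 0) 0 else qgamma(a / 2, expected)
  hi_e <- qgamma(1 - a / 2, expected + 1)
  tibble::tibble(
    expected_lo = lo_e,
    expected_hi = hi_e,
    burden_lo = observed / hi_e,
    burden_hi = if (lo_e > 0) observed / lo_e else Inf,
    af_lo = (observed - hi_e) / n_probands,
    af_hi = (observed - lo_e) / n_probands,
    ppv_lo = if (observed > 0) (observed - hi_e) / observed else NA_real_,
    ppv_hi = if (observed > 0) (observed - lo_e) / observed else NA_real_
  )
}

#' Confidence intervals for case/control burden metrics (MOVER)
#'
#' In the case/control design the expectation is itself estimated from the
#' control (father) rate, so intervals are built on the ratio and difference
#' of the two Poisson rates by the MOVER construction. The burden ratio CI is
#' the proband:father rate-ratio interval; the attributable-fraction CI is
#' the rate-difference interval; and the PPV CI is one minus the reversed
#' (father:proband) rate-ratio interval.
#'
#' @param observed_probands,n_probands Count and cohort size in cases.
#' @param observed_fathers,n_fathers Count and cohort size in controls.
#' @param level Confidence level.
#' @param method Component interval family (default Jeffreys).
#' @return A one-row tibble with `lo`/`hi` pairs for `burden`, `af`, `ppv`.
#' @export
case_control_metric_cis <- function(observed_probands, n_probands,
                                    observed_fathers, n_fathers,
                                    level = 0.95,
                                    method = c("jeffreys", "exact")) {
  method <- match.arg(method)
  rr <- mover_rate_ratio_ci(observed_probands, n_probands,
                            observed_fathers, n_fathers, level, method)
  rd <- mover_rate_diff_ci(observed_probands, n_probands,
                           observed_fathers, n_fathers, level, method)
  rr_rev <- mover_rate_ratio_ci(observed_fathers, n_fathers,
                                observed_probands, n_probands, level, method)
  tibble::tibble(
    burden_lo = rr[1], burden_hi = rr[2],
    af_lo = rd[1], af_hi = rd[2],
    ppv_lo = 1 - rr_rev[2], ppv_hi = 1 - rr_rev[1]
  )
}

#' Burden metrics for a variant class
#'
#' Computes the burden ratio (observed/expected), excess
#' (observed − expected), attributable fraction (excess per proband) and
#' positive predictive value (excess per observed variant) with an
#' upper-tailed Poisson enrichment p-value and 95% confidence intervals.
#' Two designs are supported: `"dnm"` (expectation from the null mutation
#' model, fixed; CIs by expected-count substitution, see [dnm_metric_cis()])
#' and `"case_control"` (expectation projected from the father rate,
#' `observed_fathers * n_probands / n_fathers`; MOVER CIs, see
#' [case_control_metric_cis()]).
#'
#' @param observed Observed variant count in probands.
#' @param n_probands Number of probands.
#' @param expected Expected count (dnm mode).
#' @param observed_fathers,n_fathers Control count and size (case/control
#'   mode).
#' @param level Confidence level.
#' @param method Component interval family for MOVER CIs.
#' @param cap_fractions Cap reported AF/PPV interval bounds at 1 (100%).
#' @return A one-row tibble of class `burden_result`.
#' @export
#' @examples
#' burden_metrics(observed = 200, n_probands = 1000, expected = 100)
burden_metrics <- function(observed, n_probands,
                           expected = NULL,
                           observed_fathers = NULL, n_fathers = NULL,
                           level = 0.95, method = c("jeffreys", "exact"),
                           cap_fractions = TRUE) {
  method <- match.arg(method)
  if (n_probands <= 0) abort("`n_probands` must be positive")
  cc <- !is.null(observed_fathers)
  if (cc) {
    if (is.null(n_fathers) || n_fathers <= 0) {
      abort("case/control mode needs `n_fathers` > 0")
    }
    expected <- observed_fathers * n_probands / n_fathers
  } else if (is.null(expected)) {
    abort("supply `expected` (dnm mode) or `observed_fathers`/`n_fathers`")
  }
  excess <- observed - expected
  res <- tibble::tibble(
    mode = if (cc) "case_control" else "dnm",
    observed = observed,
    expected = expected,
    n_probands = n_probands,
    burden = if (expected > 0) observed / expected else NA_real_,
    excess = excess,
    attributable_fraction = excess / n_probands,
    ppv = if (observed > 0) excess / observed else NA_real_,
    p_enrichment = if (expected > 0) {
      poisson_enrichment(observed, expected)
    } else {
      NA_real_
    }
  )
  cis <- if (cc) {
    case_control_metric_cis(observed, n_probands,
                            observed_fathers, n_fathers, level, method)
  } else {
    dnm_metric_cis(observed, expected, n_probands, level) |>
      dplyr::select(-"expected_lo", -"expected_hi")
  }
  # excess interval on the count scale, from the uncapped rate-difference CI
  cis$excess_lo <- cis$af_lo * n_probands
  cis$excess_hi <- cis$af_hi * n_probands
  if (cap_fractions) {
    cis <- dplyr::mutate(
      cis,
      dplyr::across(dplyr::all_of(c("af_lo", "af_hi", "ppv_lo", "ppv_hi")),
                    ~ pmin(.x, 1))
    )
  }
  out <- dplyr::bind_cols(res, cis)
  class(out) <- c("burden_result", class(out))
  out
}

#' Bootstrap percentile interval for a ratio of variant-class excesses
#'
#' Probands (and, in the case/control design, fathers — independently) are
#' resampled with replacement; on each replicate the excess
#' (observed − expected) is recomputed in the numerator gene set and in the
#' denominator set, and the percentile interval of the excess ratio across
#' replicates is returned. The reported upper bound is truncated at 1 (an
#' excess fraction cannot meaningfully exceed 100%). Replicates where the
#' denominator excess is non-positive are excluded and counted.
#'
#' @param proband_variants Per-variant records in probands: columns
#'   `sample_id`, `gene_id` (one row per retained variant or DNM).
#' @param proband_ids Full roster of proband ids (samples with zero variants
#'   must be resampled too).
#' @param numerator_genes Character vector of gene ids for the numerator
#'   (e.g. known DD genes).
#' @param denominator_genes Gene ids for the denominator; `NULL` means all.
#' @param expected_by_gene For the dnm design: tibble `gene_id`, `expected`
#'   (fixed expectations; they do not vary under proband resampling because
#'   the cohort size is unchanged).
#' @param father_variants,father_ids For the case/control design: father
#'   records and roster; per-replicate expectations are projected from the
#'   resampled father rate.
#' @param B Number of bootstrap replicates (default 1000).
#' @param probs Percentiles (default `c(0.025, 0.975)`; the 5th/95th
#'   variant is available as `c(0.05, 0.95)`).
#' @param seed Optional integer seed for reproducibility.
#' @return A one-row tibble with `estimate`, `lo`, `hi`, `n_undefined`.
#' @export
bootstrap_excess_ratio <- function(proband_variants, proband_ids,
                                   numerator_genes,
                                   denominator_genes = NULL,
                                   expected_by_gene = NULL,
                                   father_variants = NULL, father_ids = NULL,
                                   B = 1000, probs = c(0.025, 0.975),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cc <- !is.null(father_variants)
  if (!cc && is.null(expected_by_gene)) {
    abort("supply `expected_by_gene` or father tables")
  }
  n_p <- length(proband_ids)

  count_in <- function(tbl, genes) {
    if (is.null(genes)) nrow(tbl) else sum(tbl$gene_id %in% genes)
  }
  expected_in <- function(genes) {
    if (is.null(genes)) {
      sum(expected_by_gene$expected)
    } else {
      sum(expected_by_gene$expected[expected_by_gene$gene_id %in% genes])
    }
  }
  excess_of <- function(p_tbl, f_tbl) {
    if (cc) {
      rate_num <- count_in(f_tbl, numerator_genes) / length(father_ids)
      rate_den <- count_in(f_tbl, denominator_genes) / length(father_ids)
      c(
        count_in(p_tbl, numerator_genes) - rate_num * n_p,
        count_in(p_tbl, denominator_genes) - rate_den * n_p
      )
    } else {
      c(
        count_in(p_tbl, numerator_genes) - expected_in(numerator_genes),
        count_in(p_tbl, denominator_genes) - expected_in(denominator_genes)
      )
    }
  }

  est <- excess_of(proband_variants, father_variants)
  estimate <- est[1] / est[2]

  # index variants by sample for fast resampling
  p_by_sample <- split(proband_variants$gene_id, proband_variants$sample_id)
  f_by_sample <- if (cc) {
    split(father_variants$gene_id, father_variants$sample_id)
  }
  resample <- function(ids, by_sample) {
    take <- sample(ids, replace = TRUE)
    tibble::tibble(gene_id = unlist(by_sample[as.character(take)],
                                    use.names = FALSE))
  }
  ratios <- vapply(seq_len(B), function(b) {
    p_tbl <- resample(proband_ids, p_by_sample)
    f_tbl <- if (cc) resample(father_ids, f_by_sample)
    ex <- excess_of(p_tbl, f_tbl)
    if (ex[2] <= 0) NA_real_ else ex[1] / ex[2]
  }, numeric(1))
  n_undef <- sum(is.na(ratios))
  qs <- quantile(ratios, probs, na.rm = TRUE, names = FALSE)
  tibble::tibble(
    estimate = estimate,
    lo = qs[1],
    hi = min(qs[2], 1),
    n_undefined = n_undef,
    B = B
  )
}

#' Stratified positive predictive values for inherited variants
#'
#' Recomputes case/control burden metrics within variant strata defined by
#' score thresholds (e.g. MPC > 2, CADD bands, MAF tiers). Strata are given
#' as named one-sided formulas evaluated within the variant tables; empty
#' strata (no proband variants) are omitted. PPV monotonicity across nested
#' strata is not enforced — observed data may violate it.
#'
#' @param proband_variants,father_variants Per-variant tibbles carrying the
#'   columns the strata refer to (e.g. `cadd`, `mpc`, `maf`).
#' @param n_probands,n_fathers Cohort sizes.
#' @param strata Named list of one-sided formulas, e.g.
#'   `list(mpc_gt2 = ~ mpc > 2, cadd_gt25 = ~ cadd > 25)`.
#' @param ... Passed to [burden_metrics()].
#' @return A `burden_result` tibble, one row per non-empty stratum, with a
#'   `stratum` column; PPV point estimates below 0 are reported as 0.
#' @export
stratified_ppv <- function(proband_variants, father_variants,
                           n_probands, n_fathers, strata, ...) {
  stopifnot(is.list(strata), !is.null(names(strata)))
  rows <- purrr::imap(strata, function(f, nm) {
    keep_p <- rlang::eval_tidy(rlang::f_rhs(f), data = proband_variants)
    keep_f <- rlang::eval_tidy(rlang::f_rhs(f), data = father_variants)
    obs_p <- sum(keep_p, na.rm = TRUE)
    obs_f <- sum(keep_f, na.rm = TRUE)
    if (obs_p == 0) {
      return(NULL)
    }
    bm <- burden_metrics(obs_p, n_probands,
                         observed_fathers = obs_f, n_fathers = n_fathers, ...)
    dplyr::bind_cols(tibble::tibble(stratum = nm), bm)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$ppv <- pmax(out$ppv, 0)
  class(out) <- c("burden_result", class(out))
  out
}
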