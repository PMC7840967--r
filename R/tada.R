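# Per-gene discovery: female-only and combined-sex Poisson DNM tests, and a
# de novo + transmission Bayesian test in males (Bayes factors with
# Gamma-distributed relative risks, Bayesian FDR, sampling p-values).

#' Per-gene Poisson de novo enrichment test over class sets
#'
#' Upper-tailed Poisson tests are applied per gene to PTVs alone and to
#' PTVs plus missense/inframe combined; the per-gene minimum over the class
#' sets is reported alongside both components.
#'
#' @param observed Tibble `gene_id`, `class`, `count` of observed DNMs for
#'   one sex stratum (female-only, or both sexes pooled).
#' @param expected Tibble `gene_id`, `class`, `expected` (sum the two sexes
#'   first for a combined test); from [expected_dnm_counts()].
#' @param class_sets Named list of class vectors tested (default PTV alone
#'   and PTV + missense/inframe).
#' @return A tibble: `gene_id`, one `p_<set>` column per class set, and
#'   `p_min`. Genes with zero total expectation get p = 1 with a warning.
#' @export
poisson_gene_test <- function(observed, expected,
                              class_sets = list(
                                ptv = "ptv",
                                ptv_missense = c("ptv", "missense_inframe")
                              )) {
  stopifnot(all(c("gene_id", "class", "count") %in% names(observed)))
  stopifnot(all(c("gene_id", "class", "expected") %in% names(expected)))
  any_nonpos <- FALSE
  per_set <- purrr::imap(class_sets, function(classes, nm) {
    e <- expected |>
      dplyr::filter(.data$class %in% classes) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(expected = sum(.data$expected), .groups = "drop")
    o <- observed |>
      dplyr::filter(.data$class %in% classes) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
    res <- dplyr::left_join(e, o, by = "gene_id") |>
      dplyr::mutate(count = dplyr::coalesce(.data$count, 0))
    if (any(res$expected <= 0)) any_nonpos <<- TRUE
    res$p <- ifelse(res$expected > 0,
                    poisson_enrichment(res$count, pmax(res$expected, 1e-300)),
                    1)
    res$p[res$expected <= 0] <- 1
    stats::setNames(res[c("gene_id", "p")], c("gene_id", paste0("p_", nm)))
  })
  if (any_nonpos) warn("gene(s) with non-positive expectation: p set to 1")
  out <- purrr::reduce(per_set, dplyr::full_join, by = "gene_id")
  pcols <- grep("^p_", names(out), value = TRUE)
  out$p_min <- do.call(pmin, out[pcols])
  out
}

#' De novo Bayes factor with a Gamma relative-risk prior
#'
#' Model: the de novo count is Poisson with mean `expected_null * gamma`;
#' under the alternative `gamma ~ Gamma(gamma_mean * beta, rate = beta)`,
#' under the null `gamma = 1`. Marginalising the Gamma prior gives a
#' negative-binomial marginal, so
#' `BF = dnbinom(x, size = gamma_mean * beta, prob = beta / (beta +
#' expected_null)) / dpois(x, expected_null)`. For `gamma_mean > 1`,
#' `BF(0) < 1` and BF is strictly increasing in the count.
#'
#' @param x Observed de novo count (vectorised).
#' @param expected_null Null expectation from the mutation model (> 0).
#' @param gamma_mean Prior mean relative risk (> 0).
#' @param beta Prior rate parameter (> 0); larger concentrates the prior.
#' @return Bayes factor(s), alternative vs null.
#' @export
tada_bf_denovo <- function(x, expected_null, gamma_mean, beta = 1) {
  if (any(expected_null <= 0)) abort("`expected_null` must be positive")
  if (gamma_mean <= 0 || beta <= 0) abort("priors must be positive")
  dnbinom(x, size = gamma_mean * beta,
          prob = beta / (beta + expected_null)) /
    dpois(x, expected_null)
}

#' Case/control (transmission) Bayes factor for inherited counts
#'
#' Haploid-exposure model for male X counts: father variants
#' `x_fathers ~ Poisson(n_fathers * q)` and proband variants
#' `x_probands ~ Poisson(n_probands * q * gamma)`, with allele-frequency
#' prior `q ~ Gamma(rho, rate = nu)` and, under the alternative,
#' `gamma ~ Gamma(gamma_mean * beta, rate = beta)`. `q` is marginalised
#' analytically (Gamma–Poisson conjugacy); the remaining one-dimensional
#' integral over `gamma` is evaluated by adaptive quadrature. The null fixes
#' `gamma = 1`.
#'
#' @param x_probands,x_fathers Observed counts.
#' @param n_probands,n_fathers Haploid exposures (number of males; one X
#'   each).
#' @param gamma_mean,beta Relative-risk prior (alternative).
#' @param rho,nu Allele-frequency Gamma prior (defaults: `nu = 100` with
#'   `rho = 0.618` for PTVs; use `rho = 11.749` for missense/inframe).
#' @return The Bayes factor, alternative vs null.
#' @export
tada_bf_cc <- function(x_probands, x_fathers, n_probands, n_fathers,
                       gamma_mean, beta = 1, rho = 0.618, nu = 100) {
  if (n_probands <= 0 || n_fathers <= 0) abort("exposures must be positive")
  if (gamma_mean <= 0 || beta <= 0 || rho <= 0 || nu <= 0) {
    abort("priors must be positive")
  }
  # P(x | gamma) / P(x | gamma = 1) after integrating q analytically:
  # gamma^x_p * ((n_p + n_f + nu) / (n_p gamma + n_f + nu))^(x_p + x_f + rho)
  s <- x_probands + x_fathers + rho
  ratio <- function(g) {
    exp(x_probands * log(g) +
          s * (log(n_probands + n_fathers + nu) -
                 log(n_probands * g + n_fathers + nu)))
  }
  # integrate over the prior's effective support: quadrature on (0, Inf)
  # can miss the mass entirely when the prior is sharply concentrated
  shape <- gamma_mean * beta
  g_lo <- qgamma(1e-12, shape, rate = beta)
  g_hi <- qgamma(1 - 1e-12, shape, rate = beta)
  integrate(function(g) ratio(g) * dgamma(g, shape, rate = beta),
            g_lo, g_hi, rel.tol = 1e-10, subdivisions = 200L)$value
}

#' Combine Bayes factors and compute Bayesian FDR q-values
#'
#' The per-gene posterior probability of the null is
#' `(1 - pi) / ((1 - pi) + pi * BF)`; genes are ranked by decreasing Bayes
#' factor (ties broken by gene id for determinism) and the q-value of the
#' i-th gene is the running mean of the posterior null probabilities over
#' the top i genes — the Bayesian FDR of declaring the top i significant.
#'
#' @param results Tibble with `gene_id` and `bf` (total per-gene Bayes
#'   factor, i.e. the product over classes of de novo x case/control BFs).
#' @param pi Prior fraction of risk genes, in (0, 1) (default 0.15, the
#'   midpoint of the 0.05–0.25 sweep).
#' @return The input with `posterior_null` and `q_value` columns added, in
#'   the original row order.
#' @export
tada_combine_and_fdr <- function(results, pi = 0.15) {
  stopifnot(all(c("gene_id", "bf") %in% names(results)))
  if (pi <= 0 || pi >= 1) abort("`pi` must be in (0, 1)")
  ord <- order(-results$bf, results$gene_id)
  p0 <- (1 - pi) / ((1 - pi) + pi * results$bf[ord])
  q <- cumsum(p0) / seq_along(p0)
  out <- results
  out$posterior_null <- NA_real_
  out$q_value <- NA_real_
  out$posterior_null[ord] <- p0
  out$q_value[ord] <- q
  out
}

#' Sampling-based p-value for an observed Bayes factor
#'
#' `p = (1 + #{null BF >= observed}) / (1 + n_samples)` against Bayes
#' factors computed on data simulated from the null model.
#'
#' @param bf_observed Observed Bayes factor(s).
#' @param null_bf Vector of Bayes factors from null-simulated genes (e.g.
#'   from [tada_null_bf()]), or a generator `function(n)` returning them.
#' @param n_samples Number of null draws when `null_bf` is a generator.
#' @param seed Optional seed.
#' @return p-value(s), one per observed Bayes factor.
#' @export
tada_pvalue <- function(bf_observed, null_bf, n_samples = 10000,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.function(null_bf)) null_bf <- null_bf(n_samples)
  if (length(null_bf) < 1000) {
    warn("fewer than 1000 null samples: sampling p-values are coarse")
  }
  vapply(bf_observed, function(b) {
    (1 + sum(null_bf >= b)) / (1 + length(null_bf))
  }, numeric(1))
}

#' Null Bayes factors for the sampling p-value
#'
#' Simulates genes from the null (relative risk 1): de novo counts Poisson
#' at the null expectation, and inherited counts from the Gamma–Poisson
#' allele-frequency model shared by cases and controls, then computes the
#' total Bayes factor with the same priors used for the observed data.
#'
#' @param n Number of null genes to draw.
#' @param expected_dn Null de novo expectation per gene (recycled).
#' @param n_probands,n_fathers Haploid exposures.
#' @param gamma_mean_dn,beta_dn,gamma_mean_cc,beta_cc,rho,nu Priors as in
#'   [tada_bf_denovo()] and [tada_bf_cc()].
#' @return Numeric vector of `n` null total Bayes factors.
#' @export
tada_null_bf <- function(n, expected_dn, n_probands, n_fathers,
                         gamma_mean_dn, beta_dn = 1,
                         gamma_mean_cc, beta_cc = 1,
                         rho = 0.618, nu = 100) {
  expected_dn <- rep_len(expected_dn, n)
  x_dn <- rpois(n, expected_dn)
  q <- rgamma(n, rho, rate = nu)
  x_f <- rpois(n, n_fathers * q)
  x_p <- rpois(n, n_probands * q)
  bf_dn <- tada_bf_denovo(x_dn, expected_dn, gamma_mean_dn, beta_dn)
  bf_cc <- vapply(seq_len(n), function(i) {
    tada_bf_cc(x_p[i], x_f[i], n_probands, n_fathers,
               gamma_mean_cc, beta_cc, rho, nu)
  }, numeric(1))
  bf_dn * bf_cc
}

#' Default relative-risk priors from class-level burden
#'
#' With the prior risk-gene fraction `pi` and a class-level burden ratio
#' `observed/expected`, the prior mean relative risk in risk genes solves
#' `pi * gamma_mean + (1 - pi) = observed/expected`, i.e.
#' `gamma_mean = 1 + (observed/expected - 1) / pi`, floored at 1.
#'
#' The rate parameter `beta` defaults to the smallest power of two at which
#' the prior puts at most 5% mass on relative risks below 1
#' (`pgamma(1, gamma_mean * beta, beta) <= 0.05`, capped at 2^20). A
#' risk-gene alternative is a hypothesis of *enrichment*; a diffuse prior
#' with large mass below 1 would also reward depleted genes with Bayes
#' factors above 1, inverting the ranking. When `gamma_mean` is large the
#' constraint is already met at `beta = 1`; when it is 1 (no burden) the cap
#' concentrates the prior at 1 and the Bayes factor becomes neutral.
#'
#' @param observed_total,expected_total Class-level totals.
#' @param pi Prior fraction of risk genes.
#' @param beta Prior rate parameter; `NULL` (default) selects it by the
#'   one-sidedness rule above.
#' @return A list with `gamma_mean` and `beta`.
#' @export
tada_default_priors <- function(observed_total, expected_total, pi = 0.15,
                                beta = NULL) {
  if (expected_total <= 0) abort("`expected_total` must be positive")
  gamma_mean <- max(1, 1 + (observed_total / expected_total - 1) / pi)
  if (is.null(beta)) {
    beta <- 1
    while (pgamma(1, gamma_mean * beta, rate = beta) > 0.05 && beta < 2^20) {
      beta <- beta * 2
    }
  }
  list(gamma_mean = gamma_mean, beta = beta)
}

#' Genome-wide significance threshold for the X-linked testing strategy
#'
#' The improved strategy applies six tests per X gene (PTV alone and
#' PTV + missense/inframe for each of the female-only Poisson, combined-sex
#' Poisson and male de novo + transmission tests) and the usual two de novo
#' tests per autosomal gene; the old strategy applied two tests to every
#' gene. The Bonferroni threshold is 0.05 divided by the total test count.
#'
#' @param strategy `"new"` (six X tests) or `"old"` (two tests everywhere).
#' @param n_x_genes Number of X-linked genes tested (default 804).
#' @param n_genome_genes Total genes genome-wide (default 19685).
#' @return A list with `n_tests` and `alpha`.
#' @export
#' @examples
#' significance_threshold("new")$alpha # ~1.17e-6
#' significance_threshold("old")$alpha # ~1.27e-6
significance_threshold <- function(strategy = c("new", "old"),
                                   n_x_genes = 804, n_genome_genes = 19685) {
  strategy <- match.arg(strategy)
  n_tests <- if (strategy == "new") {
    6 * n_x_genes + 2 * (n_genome_genes - n_x_genes)
  } else {
    2 * n_genome_genes
  }
  list(n_tests = n_tests, alpha = 0.05 / n_tests)
}

#' Run the three-pronged per-gene discovery strategy
#'
#' Applies (1) the female-only Poisson DNM test, (2) the combined-sex
#' Poisson DNM test, and (3) the male de novo + transmission Bayesian test,
#' each on PTVs alone and PTV + missense/inframe combined, then attaches
#' Bayesian-FDR q-values to the total Bayes factor and flags significance at
#' the strategy threshold (Poisson arms) using the per-gene minimum p.
#'
#' @param dnm_counts Tibble `gene_id`, `sex`, `class`, `count` of filtered
#'   DNMs.
#' @param inherited_counts Tibble `gene_id`, `class`, `x_probands`,
#'   `x_fathers` of inherited variant counts in male probands (DNMs
#'   removed) and fathers.
#' @param expected Expected DNM counts from [expected_dnm_counts()].
#' @param n_probands,n_fathers Male case/control cohort sizes.
#' @param pi Prior fraction of risk genes.
#' @param priors Named list per class (`ptv`, `missense_inframe`) of lists
#'   with `gamma_mean_dn`, `beta_dn`, `gamma_mean_cc`, `beta_cc`, `rho`,
#'   `nu`. Defaults use `rho` 0.618 (PTV) / 11.749 (missense), `nu` 100 and
#'   burden-derived `gamma_mean`s via [tada_default_priors()].
#' @param strategy Significance accounting, see [significance_threshold()].
#' @return A tibble, one row per gene: `p_poisson_female`,
#'   `p_poisson_combined`, `bf_total`, `q_value`, `significant`.
#' @export
run_gene_discovery <- function(dnm_counts, inherited_counts, expected,
                               n_probands, n_fathers, pi = 0.15,
                               priors = NULL, strategy = "new") {
  classes <- c("ptv", "missense_inframe")
  # Poisson arms
  obs_female <- dnm_counts |>
    dplyr::filter(.data$sex == "female") |>
    dplyr::group_by(.data$gene_id, .data$class) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  exp_female <- expected |>
    dplyr::filter(.data$sex == "female")
  obs_comb <- dnm_counts |>
    dplyr::group_by(.data$gene_id, .data$class) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  exp_comb <- expected |>
    dplyr::group_by(.data$gene_id, .data$class) |>
    dplyr::summarise(expected = sum(.data$expected), .groups = "drop")
  p_f <- poisson_gene_test(obs_female, exp_female)
  p_c <- poisson_gene_test(obs_comb, exp_comb)

  # male TADA arm
  exp_male <- expected |>
    dplyr::filter(.data$sex == "male", .data$class %in% classes)
  obs_male <- dnm_counts |>
    dplyr::filter(.data$sex == "male", .data$class %in% classes) |>
    dplyr::group_by(.data$gene_id, .data$class) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  male <- exp_male |>
    dplyr::left_join(obs_male, by = c("gene_id", "class")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0)) |>
    dplyr::left_join(inherited_counts, by = c("gene_id", "class")) |>
    dplyr::mutate(
      x_probands = dplyr::coalesce(.data$x_probands, 0),
      x_fathers = dplyr::coalesce(.data$x_fathers, 0)
    )

  if (is.null(priors)) {
    priors <- purrr::map(stats::setNames(classes, classes), function(cl) {
      sub <- male[male$class == cl, ]
      dn <- tada_default_priors(sum(sub$count), sum(sub$expected), pi)
      rate_f <- sum(sub$x_fathers) / n_fathers
      cc <- tada_default_priors(sum(sub$x_probands),
                                max(rate_f * n_probands, 1e-12), pi)
      list(
        gamma_mean_dn = dn$gamma_mean, beta_dn = dn$beta,
        gamma_mean_cc = cc$gamma_mean, beta_cc = cc$beta,
        rho = if (cl == "ptv") 0.618 else 11.749, nu = 100
      )
    })
  }

  male$bf <- vapply(seq_len(nrow(male)), function(i) {
    pr <- priors[[male$class[i]]]
    bf_dn <- tada_bf_denovo(male$count[i], pmax(male$expected[i], 1e-12),
                            pr$gamma_mean_dn, pr$beta_dn)
    bf_cc <- tada_bf_cc(male$x_probands[i], male$x_fathers[i],
                        n_probands, n_fathers,
                        pr$gamma_mean_cc, pr$beta_cc, pr$rho, pr$nu)
    bf_dn * bf_cc
  }, numeric(1))
  bf_total <- male |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(bf = prod(.data$bf), .groups = "drop")
  fdr <- tada_combine_and_fdr(bf_total, pi)

  thr <- significance_threshold(strategy)$alpha
  out <- tibble::tibble(gene_id = sort(unique(expected$gene_id))) |>
    dplyr::left_join(
      stats::setNames(p_f[c("gene_id", "p_min")],
                      c("gene_id", "p_poisson_female")),
      by = "gene_id"
    ) |>
    dplyr::left_join(
      stats::setNames(p_c[c("gene_id", "p_min")],
                      c("gene_id", "p_poisson_combined")),
      by = "gene_id"
    ) |>
    dplyr::left_join(
      stats::setNames(fdr[c("gene_id", "bf", "q_value")],
                      c("gene_id", "bf_total", "q_value")),
      by = "gene_id"
    ) |>
    dplyr::mutate(
      significant = pmin(.data$p_poisson_female,
                         .data$p_poisson_combined, na.rm = TRUE) < thr
    )
  attr(out, "threshold") <- thr
  class(out) <- c("gene_test_result", class(out))
  out
}
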