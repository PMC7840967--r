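# Mutation-selection-balance models for the de novo versus inherited split
# in X-linked recessive disease, the per-gene sex-bias test, the carrier
# fertility analysis and small proportion derivations.

#' Haldane's expected de novo fraction in X-linked recessive males
#'
#' At mutation-selection balance, the fraction of affected hemizygous males
#' whose pathogenic allele arose de novo is `m * mu / (2 * mu + nu)`, where
#' `m` is the reproductive loss in affected males, `mu` the egg mutation
#' rate and `nu` the sperm mutation rate. Parameterised here by the
#' sperm:egg ratio `nu_over_mu`, giving `m / (2 + nu_over_mu)`. With equal
#' rates and complete male reproductive loss this is the classical
#' one-third; with `nu_over_mu = 3.5` it falls to about 18%.
#'
#' @param m Reproductive loss in affected males, in \[0, 1\] (default 1:
#'   reproductively lethal).
#' @param nu_over_mu Sperm:egg SNV mutation-rate ratio (default 3.5).
#' @return Expected de novo fraction, in \[0, 1/2\].
#' @export
#' @examples
#' haldane_fraction(1, 1) # 1/3
#' haldane_fraction(1, 3.5) # ~0.18
haldane_fraction <- function(m = 1, nu_over_mu = 3.5) {
  check_haldane_params(m, 0, nu_over_mu)
  m / (2 + nu_over_mu)
}

check_haldane_params <- function(m, f, nu_over_mu) {
  if (any(m < 0 | m > 1)) abort("`m` must be in [0, 1]")
  if (any(f < 0 | f > 1)) abort("`f` must be in [0, 1]")
  if (any(nu_over_mu <= 0)) abort("`nu_over_mu` must be positive")
  invisible(NULL)
}

#' Sherman extension: de novo fraction with carrier-female selection
#'
#' Extends the mutation-selection balance to a reproductive loss `f` in
#' heterozygous carrier females: the expected de novo fraction becomes
#' `mu * (2f + m - m*f) / (2*mu + nu - nu*f)`, i.e.
#' `(2*f + m - m*f) / (2 + nu_over_mu * (1 - f))`. Reduces to
#' [haldane_fraction()] at `f = 0` and to 1 at `f = m = 1` (no transmission
#' at all: every case is de novo). Strictly increasing and continuous in
#' `f`.
#'
#' @inheritParams haldane_fraction
#' @param f Reproductive loss in carrier females, in \[0, 1\].
#' @return Expected de novo fraction.
#' @export
#' @examples
#' sherman_fraction(m = 1, f = 1 - 0.742, nu_over_mu = 3.5) # ~0.273
sherman_fraction <- function(m = 1, f = 0, nu_over_mu = 3.5) {
  check_haldane_params(m, f, nu_over_mu)
  (2 * f + m - m * f) / (2 + nu_over_mu * (1 - f))
}

#' Invert the Sherman model for the carrier-female reproductive loss
#'
#' Solves `sherman_fraction(m, f, nu_over_mu) = p_dn` for `f`. The model is
#' linear in `f` after clearing the denominator, giving the closed form
#' `f = (p_dn * (2 + nu_over_mu) - m) / (2 - m + p_dn * nu_over_mu)`.
#' A `p_dn` outside the range achievable for the given `(m, nu_over_mu)`
#' (below the Haldane value or above the `f = 1` value) is an error.
#'
#' @param p_dn Target de novo fraction.
#' @inheritParams sherman_fraction
#' @return The unique `f` in \[0, 1\].
#' @export
#' @examples
#' invert_sherman_for_f(0.22) # ~0.12
#' invert_sherman_for_f(0.44) # ~0.56
invert_sherman_for_f <- function(p_dn, m = 1, nu_over_mu = 3.5) {
  check_haldane_params(m, 0, nu_over_mu)
  lo <- sherman_fraction(m, 0, nu_over_mu)
  hi <- sherman_fraction(m, 1, nu_over_mu)
  if (any(p_dn < lo - 1e-12 | p_dn > hi + 1e-12)) {
    abort(sprintf("`p_dn` outside the achievable range [%.4f, %.4f]", lo, hi))
  }
  f <- (p_dn * (2 + nu_over_mu) - m) / (2 - m + p_dn * nu_over_mu)
  pmin(pmax(f, 0), 1)
}

#' Consistency of an observed de novo proportion with a theoretical value
#'
#' One-sample equality-of-proportions chi-square test with continuity
#' correction (as `prop.test()` applies by default), plus the set of null
#' proportions consistent with the data: the interval of `p0` values (on a
#' grid of width `grid`) whose two-sided p-value exceeds `alpha`.
#'
#' @param x_denovo Number of de novo cases among the excess.
#' @param n_excess Total excess cases.
#' @param p0 Null proportion to test (e.g. the Haldane expectation);
#'   optional.
#' @param alpha Consistency level (default 0.05).
#' @param grid Grid resolution for the consistency set (default 0.01,
#'   matching two-decimal reporting).
#' @return A list with `p_value` (NA when `p0` is NULL), `estimate`
#'   (`x/n`), and `consistency_interval` (`c(lo, hi)` of consistent `p0`).
#' @export
#' @examples
#' proportion_consistency(22, 69, p0 = 1 / 5.5)
proportion_consistency <- function(x_denovo, n_excess, p0 = NULL,
                                   alpha = 0.05, grid = 0.01) {
  if (n_excess <= 0 || x_denovo < 0 || x_denovo > n_excess) {
    abort("need 0 <= x_denovo <= n_excess and n_excess > 0")
  }
  if (!is.null(p0) && (p0 <= 0 || p0 >= 1)) {
    abort("`p0` must be strictly inside (0, 1)")
  }
  p_value <- if (is.null(p0)) {
    NA_real_
  } else {
    suppressWarnings(prop.test(x_denovo, n_excess, p = p0)$p.value)
  }
  p0_grid <- seq(grid, 1 - grid, by = grid)
  pv <- vapply(p0_grid, function(p) {
    suppressWarnings(prop.test(x_denovo, n_excess, p = p)$p.value)
  }, numeric(1))
  consistent <- p0_grid[pv > alpha]
  list(
    p_value = p_value,
    estimate = x_denovo / n_excess,
    consistency_interval = if (length(consistent)) {
      range(consistent)
    } else {
      c(NA_real_, NA_real_)
    }
  )
}

#' Per-gene sex-bias test for de novo mutations
#'
#' Compares the observed male share of a gene's DNMs to the expected share
#' under the null mutation model (see [expected_male_fraction()]) with a
#' lower-tailed binomial test — the alternative of interest is depletion of
#' male DNMs, as expected for semi-dominant, male-lethal genes.
#'
#' @param male_dnms,female_dnms Observed DNM counts by sex.
#' @param expected_male_fraction Null male share, in (0, 1).
#' @param randomize If `TRUE`, return the randomized (fuzzy) p-value
#'   `P(X < x) + U * P(X = x)`, which is exactly uniform under the null;
#'   used for calibration experiments, never for reporting.
#' @return Lower-tailed binomial p-value.
#' @export
#' @examples
#' sex_bias_test(1, 24, 0.2301)
sex_bias_test <- function(male_dnms, female_dnms, expected_male_fraction,
                          randomize = FALSE) {
  if (any(expected_male_fraction <= 0 | expected_male_fraction >= 1)) {
    abort("`expected_male_fraction` must be in (0, 1)")
  }
  n <- male_dnms + female_dnms
  p <- pbinom(male_dnms, n, expected_male_fraction)
  p[n == 0] <- 1
  if (randomize) {
    p <- pbinom(male_dnms - 1, n, expected_male_fraction) +
      runif(length(p)) * dbinom(male_dnms, n, expected_male_fraction)
    p[n == 0] <- runif(sum(n == 0))
  }
  p
}

#' Ratio-of-means fertility test for carrier females
#'
#' Tests whether carrier females have fewer live births than non-carriers
#' via the ratio of group means with a Fieller-type confidence interval and
#' a t-test of the mean difference (Welch variances). Covariates (age, age
#' squared, ancestry components) are optionally removed first by
#' residualising the live-birth count on them and re-centring at the grand
#' mean, after which the ratio test is applied to the adjusted values.
#'
#' @param data Per-female tibble.
#' @param carrier Name of the logical carrier column (default `"carrier"`).
#' @param births Name of the live-birth count column (default `"births"`).
#' @param covariates Character vector of covariate columns; `"age"` also
#'   adds `age^2`, following the standard phenotype ~ N_VAR + age + age^2 +
#'   PCs adjustment.
#' @param level Confidence level.
#' @return A one-row tibble: `ratio` (carrier:non-carrier mean), `lo`, `hi`
#'   (Fieller interval), `p_value`, `n_carrier`, `n_noncarrier`.
#' @export
fertility_ratio_test <- function(data, carrier = "carrier", births = "births",
                                 covariates = NULL, level = 0.95) {
  stopifnot(carrier %in% names(data), births %in% names(data))
  y <- data[[births]]
  g <- as.logical(data[[carrier]])
  ok <- !is.na(y) & !is.na(g)
  if (!is.null(covariates)) {
    X <- data[covariates]
    ok <- ok & complete.cases(X)
  }
  y <- y[ok]
  g <- g[ok]
  if (sum(g) < 2 || sum(!g) < 2) {
    abort("need at least 2 carriers and 2 non-carriers")
  }
  if (!is.null(covariates)) {
    df <- data[ok, covariates, drop = FALSE]
    if ("age" %in% covariates) df$age2 <- df$age^2
    df$y <- y
    fit <- lm(y ~ ., data = df)
    y <- mean(y) + stats::residuals(fit)
  }
  mx <- mean(y[g]); vx <- var(y[g]); nx <- sum(g)
  my <- mean(y[!g]); vy <- var(y[!g]); ny <- sum(!g)
  if (my <= 0) abort("non-carrier mean must be positive")
  ratio <- mx / my
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  dfree <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p_value <- 2 * pt(-abs(tstat), dfree)
  # Fieller: roots of (mx - r my)^2 = t^2 (vx/nx + r^2 vy/ny)
  tq <- qt(1 - (1 - level) / 2, dfree)
  a <- my^2 - tq^2 * vy / ny
  b <- -2 * mx * my
  cc <- mx^2 - tq^2 * vx / nx
  disc <- b^2 - 4 * a * cc
  if (a <= 0 || disc < 0) {
    warn("Fieller interval unbounded; reporting (0, Inf)")
    ci <- c(0, Inf)
  } else {
    ci <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  }
  tibble::tibble(
    ratio = ratio, lo = ci[1], hi = ci[2], p_value = p_value,
    n_carrier = nx, n_noncarrier = ny
  )
}

#' Proportion with an exact binomial confidence interval
#'
#' Percentage and 95% Clopper–Pearson interval for a count out of a total,
#' as used for reporting clinician-rating proportions.
#'
#' @param numerator,denominator Counts, `0 <= numerator <= denominator`.
#' @param level Confidence level.
#' @return A one-row tibble with `percent`, `lo`, `hi` (all in %).
#' @export
#' @examples
#' printed_proportion(56, 272)
printed_proportion <- function(numerator, denominator, level = 0.95) {
  if (denominator <= 0 || numerator < 0 || numerator > denominator) {
    abort("need 0 <= numerator <= denominator, denominator > 0")
  }
  ci <- binom.test(numerator, denominator, conf.level = level)$conf.int
  tibble::tibble(
    percent = 100 * numerator / denominator,
    lo = 100 * ci[1],
    hi = 100 * ci[2]
  )
}

#' Fraction of true missense/inframe diagnoses missing from classifications
#'
#' Assuming every diagnostic PTV is identified, the missense-per-PTV odds in
#' pathogenic classifications divided by the same odds in the burden
#' estimate gives the fraction of true missense/inframe diagnoses that are
#' being classified; one minus that is the missed fraction:
#' `1 - [(1 - s_clinvar)/s_clinvar] / [(1 - s_burden)/s_burden]`, where the
#' `s` are the PTV shares. A negative value means missense variants are
#' over-called relative to the burden.
#'
#' @param clinvar_ptv_share PTV share among pathogenic classifications,
#'   in (0, 1).
#' @param burden_ptv_share PTV share of the burden estimate, in (0, 1).
#' @return The missed fraction (may be negative).
#' @export
#' @examples
#' missed_missense_fraction(0.606, 0.389) # ~0.586
missed_missense_fraction <- function(clinvar_ptv_share, burden_ptv_share) {
  if (any(c(clinvar_ptv_share, burden_ptv_share) <= 0) ||
      any(c(clinvar_ptv_share, burden_ptv_share) >= 1)) {
    abort("shares must be strictly inside (0, 1)")
  }
  1 - ((1 - clinvar_ptv_share) / clinvar_ptv_share) /
    ((1 - burden_ptv_share) / burden_ptv_share)
}
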