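test_that("de novo Bayes factor matches direct numerical marginalisation", {
  x <- 3; e <- 0.4; gm <- 10; beta <- 1
  # oracle: integrate the Poisson likelihood over the Gamma prior
  num <- integrate(function(g) dpois(x, e * g) * dgamma(g, gm * beta, rate = beta),
                   0, Inf, rel.tol = 1e-10)$value
  expect_equal(tada_bf_denovo(x, e, gm, beta), num / dpois(x, e),
               tolerance = 1e-6)
  # BF(0) < 1 < BF(large) and strictly increasing in the count
  bfs <- tada_bf_denovo(0:6, e, gm, beta)
  expect_lt(bfs[1], 1)
  expect_true(all(diff(bfs) > 0))
  expect_gt(bfs[7], 1)
  # a prior concentrated at relative risk 1 gives BF ~ 1 for any count
  expect_equal(tada_bf_denovo(2, 0.5, 1, 1e8), 1, tolerance = 1e-3)
})

test_that("case/control Bayes factor matches brute-force double integration", {
  xp <- 3; xf <- 1; np <- 50; nf <- 60
  gm <- 5; beta <- 1; rho <- 0.618; nu <- 100
  marg <- function(fix_gamma = NULL) {
    inner <- function(g) {
      vapply(g, function(gg) {
        integrate(function(q) {
          dpois(xp, np * q * gg) * dpois(xf, nf * q) *
            dgamma(q, rho, rate = nu)
        }, 0, Inf, rel.tol = 1e-10)$value
      }, numeric(1))
    }
    if (!is.null(fix_gamma)) return(inner(fix_gamma))
    integrate(function(g) inner(g) * dgamma(g, gm * beta, rate = beta),
              0, Inf, rel.tol = 1e-8)$value
  }
  oracle <- marg() / marg(fix_gamma = 1)
  expect_equal(tada_bf_cc(xp, xf, np, nf, gm, beta, rho, nu), oracle,
               tolerance = 1e-4)
})

test_that("balanced case/control counts with a null-concentrated prior give BF near 1", {
  bf <- tada_bf_cc(5, 5, 100, 100, gamma_mean = 1, beta = 1e6,
                   rho = 0.618, nu = 100)
  expect_equal(bf, 1, tolerance = 0.1)
  # enrichment in probands raises the BF; depletion lowers it
  bf_hi <- tada_bf_cc(15, 5, 100, 100, gamma_mean = 5)
  bf_lo <- tada_bf_cc(1, 10, 100, 100, gamma_mean = 5)
  expect_gt(bf_hi, 1)
  expect_lt(bf_lo, 1)
})

test_that("Bayesian FDR is the running mean of posterior null down the BF ranking", {
  res <- tibble::tibble(gene_id = c("a", "b", "c"), bf = c(0.1, 10, 1))
  out <- tada_combine_and_fdr(res, pi = 0.5)
  # with pi = 0.5 the posterior null is 1 / (1 + bf)
  expect_equal(out$posterior_null, 1 / (1 + res$bf))
  # ranking b (10), c (1), a (0.1): q is the cumulative mean in that order
  p0 <- 1 / (1 + c(10, 1, 0.1))
  expect_equal(out$q_value[match(c("b", "c", "a"), out$gene_id)],
               cumsum(p0) / 1:3)
  # q-values are non-decreasing down the ranking (property)
  set.seed(21)
  res2 <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                         bf = rlnorm(100, 0, 2))
  out2 <- tada_combine_and_fdr(res2)
  ord <- order(-out2$bf, out2$gene_id)
  expect_true(all(diff(out2$q_value[ord]) >= -1e-12))
  expect_error(tada_combine_and_fdr(res, pi = 1.5), "in \\(0, 1\\)")
})

test_that("sampling p-values have the add-one form and a positive floor", {
  null_bf <- 1:2000
  expect_equal(tada_pvalue(5000, null_bf), 1 / 2001)
  expect_equal(tada_pvalue(0.5, null_bf), 1)
  expect_equal(tada_pvalue(1000.5, null_bf), (1 + 1000) / 2001)
  # generator form is seeded and reproducible
  gen <- function(n) tada_null_bf(n, expected_dn = 0.05,
                                  n_probands = 100, n_fathers = 120,
                                  gamma_mean_dn = 10, gamma_mean_cc = 5)
  p1 <- tada_pvalue(2, gen, n_samples = 1500, seed = 4)
  p2 <- tada_pvalue(2, gen, n_samples = 1500, seed = 4)
  expect_equal(p1, p2)
  expect_true(p1 > 0 && p1 <= 1)
  expect_warning(tada_pvalue(1, 1:10), "fewer than 1000")
})

test_that("significance thresholds follow the old and new test accounting", {
  new <- significance_threshold("new")
  expect_equal(new$n_tests, 6 * 804 + 2 * (19685 - 804))
  expect_equal(new$alpha, 0.05 / 42586)
  old <- significance_threshold("old")
  expect_equal(old$n_tests, 2 * 19685)
  expect_equal(old$alpha, 0.05 / 39370)
  # the refined strategy is slightly more stringent
  expect_lt(new$alpha, old$alpha)
})

test_that("per-gene Poisson test evaluates both class sets and their minimum", {
  observed <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"),
    class = c("ptv", "missense_inframe", "ptv"),
    count = c(3, 2, 0)
  )
  expected <- tidyr::expand_grid(
    gene_id = c("g1", "g2"),
    class = c("ptv", "missense_inframe")
  ) |>
    dplyr::mutate(expected = c(0.1, 0.4, 0.1, 0.4))
  out <- poisson_gene_test(observed, expected)
  expect_equal(out$p_ptv[out$gene_id == "g1"],
               ppois(2, 0.1, lower.tail = FALSE))
  expect_equal(out$p_ptv_missense[out$gene_id == "g1"],
               ppois(4, 0.5, lower.tail = FALSE))
  expect_equal(out$p_min, pmin(out$p_ptv, out$p_ptv_missense))
  expect_equal(out$p_ptv[out$gene_id == "g2"], 1)
  # zero expectation is tolerated with a warning, p = 1
  expected0 <- dplyr::mutate(expected, expected = 0)
  expect_warning(out0 <- poisson_gene_test(observed, expected0),
                 "non-positive")
  expect_true(all(out0$p_min == 1))
})

test_that("burden-derived default priors solve the mixture identity", {
  pr <- tada_default_priors(200, 100, pi = 0.15)
  expect_equal(pr$gamma_mean, 1 + (2 - 1) / 0.15)
  # depleted classes floor at 1 rather than going sub-null
  expect_equal(tada_default_priors(50, 100)$gamma_mean, 1)
})

test_that("run_gene_discovery ranks an injected strong gene first", {
  set.seed(44)
  genes <- sprintf("g%02d", 1:12)
  expected <- tidyr::expand_grid(
    gene_id = genes, sex = c("female", "male"),
    class = c("synonymous", "missense_inframe", "ptv")
  ) |>
    dplyr::mutate(expected = 0.05)
  dnm_counts <- tibble::tibble(
    gene_id = c("g01", "g01", "g01", "g02"),
    sex = c("female", "male", "male", "female"),
    class = c("ptv", "ptv", "missense_inframe", "synonymous"),
    count = c(4, 5, 3, 1)
  )
  inherited_counts <- tidyr::expand_grid(
    gene_id = genes, class = c("ptv", "missense_inframe")
  ) |>
    dplyr::mutate(
      x_probands = ifelse(gene_id == "g01", 12L, 1L),
      x_fathers = 1L
    )
  res <- run_gene_discovery(dnm_counts, inherited_counts, expected,
                            n_probands = 500, n_fathers = 600)
  expect_s3_class(res, "gene_test_result")
  expect_equal(nrow(res), 12)
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  td <- tidy(res)
  expect_equal(td$gene_id[1], "g01")
  expect_true(res$significant[res$gene_id == "g01"])
  expect_false(any(res$significant[res$gene_id != "g01"]))
  gl <- glance(res)
  expect_equal(gl$n_significant, 1L)
  expect_equal(gl$threshold, significance_threshold("new")$alpha)
  # the autoplot method returns a ggplot object without error
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
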