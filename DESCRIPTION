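Package: xlburden
Title: Sex-Aware Burden and Inheritance-Mode Analysis of X-Linked Coding Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical framework for quantifying the contribution of X-linked
    coding variation to severe developmental disorders. Implements sex-aware
    expected de novo mutation counts on the non-pseudoautosomal X (depth
    correction and parental-origin scaling), post-calling variant and de novo
    candidate filters, burden / attributable-fraction / positive-predictive-value
    estimation with exact-Poisson, MOVER and bootstrap confidence intervals,
    Haldane and Sherman mutation-selection-balance models of the de novo versus
    inherited split in X-linked recessive genes, per-gene sex-bias tests, a
    transmission-and-de-novo Bayesian association test with Bayesian FDR, and a
    synthetic trio-cohort generator with recorded ground truth so the whole
    pipeline is testable without managed-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
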