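test_that("case/control filter applies genotype and site rules with a closed ledger", {
  sites <- tibble::tibble(
    variant_id = paste0("v", 1:6),
    chrom = "X",
    pos = c(3e6, 60002, 5e6, 6e6, 7e6, 8e6), # v2 in PAR1
    strand_bias_p = c(0.5, 0.5, 1e-4, 0.5, 0.5, 0.5), # v3 strand-biased
    gnomad_hemi = c(0, 0, 0, 0, 0, 2), # v6 has hemizygotes
    maf_gnomad = c(0, 0, 0, 0.01, 0, 0) # v4 too common
  )
  genotypes <- tidyr::expand_grid(
    sample_id = c("s1", "s2", "s3", "s4"),
    variant_id = sites$variant_id
  ) |>
    dplyr::mutate(gt = "hom_ref", gq = 99, dp = 30)
  # v5: 3/4 genotypes fail QC -> missingness > 0.5
  genotypes$gq[genotypes$variant_id == "v5" &
                 genotypes$sample_id != "s1"] <- 5
  # carriers at the one clean site v1, plus one het (impossible in males)
  genotypes$gt[genotypes$variant_id == "v1" & genotypes$sample_id == "s1"] <- "hemi"
  genotypes$gt[genotypes$variant_id == "v1" & genotypes$sample_id == "s2"] <- "het"
  # low-depth call
  genotypes$dp[genotypes$variant_id == "v1" & genotypes$sample_id == "s3"] <- 3

  res <- filter_case_control(genotypes, sites)
  expect_s3_class(res, "filter_result")
  # only the clean hemizygous call at v1 survives
  expect_equal(nrow(res$retained), 1)
  expect_equal(res$retained$sample_id, "s1")
  expect_equal(res$retained$variant_id, "v1")

  led <- res$dropped
  expect_equal(led$n[led$rule == "par"], 1L)
  expect_equal(led$n[led$rule == "strand_bias"], 1L)
  expect_equal(led$n[led$rule == "missingness"], 1L)
  expect_equal(led$n[led$rule == "maf"], 1L)
  expect_equal(led$n[led$rule == "gnomad_hemizygotes"], 1L)
  # genotype rule: one het + three low-GQ at v5 + one low-DP
  expect_equal(led$n[led$rule == "genotype_missing"], 5L)
  # site ledger closes: sites in = sites passing + site drops
  expect_equal(sum(led$n[led$rule != "genotype_missing"]), 6L - 1L)
})

test_that("pooled strand-bias test matches a Fisher test on summed counts", {
  cand <- tibble::tibble(
    chrom = "X", pos = c(100, 100, 200),
    ref = "A", alt = "G",
    ref_fwd = c(10, 14, 5), ref_rev = c(12, 9, 6),
    alt_fwd = c(8, 2, 4), alt_rev = c(1, 9, 5)
  )
  out <- pooled_strand_bias(cand)
  expect_equal(nrow(out), 3)
  m <- matrix(c(10 + 14, 12 + 9, 8 + 2, 1 + 9), nrow = 2, byrow = TRUE)
  expect_equal(out$strand_bias_p[out$pos == 100],
               rep(fisher.test(m)$p.value, 2))
})

test_that("mosaic flag requires departure from het balance above error rate", {
  # clearly mosaic: 10 alt reads of 100
  expect_true(mosaic_flag(10, 100))
  # balanced het: not mosaic
  expect_false(mosaic_flag(50, 100))
  # consistent with sequencing error: not mosaic
  expect_false(mosaic_flag(0, 100))
  # missing data: not flagged
  expect_false(mosaic_flag(NA, 100))
})

test_that("DNM candidate filter applies each rule in order and keeps the ledger closed", {
  base <- tibble::tibble(
    chrom = "X", ref = "A", alt = "T", indel_len = 0L,
    child_dp = 40L, child_ad_alt = 38L,
    mother_dp = 40L, mother_ad_alt = 0L, father_dp = 30L,
    pp_dnm = 0.9, in_segdup = FALSE, strand_bias_p = 0.8,
    maf_gnomad = 0, gnomad_hemi = 0
  )
  mk <- function(n, ...) {
    out <- base[rep(1, n), ]
    dots <- list(...)
    for (nm in names(dots)) out[[nm]] <- dots[[nm]]
    out
  }
  cand <- dplyr::bind_rows(
    mk(2, pos = c(1.1e7, 1.2e7)),                      # clean, retained
    mk(1, pos = 60005),                                # PAR
    mk(1, pos = 3e6, child_ad_alt = 2L),               # depth rule
    mk(1, pos = 4e6, strand_bias_p = 1e-4),            # strand bias
    mk(1, pos = 5e6, mother_ad_alt = 20L),             # maternal het
    mk(1, pos = 6e6, mother_ad_alt = 4L,
       child_ad_alt = 5L, in_segdup = TRUE),           # segdup double-mosaic
    mk(1, pos = 7e6, pp_dnm = 0.001),                  # pp_dnm threshold
    mk(1, pos = 8e6, pp_dnm = NA_real_),               # uncallable
    mk(1, pos = 9e6, maf_gnomad = 0.01),               # population frequency
    mk(1, pos = 1e7, mother_ad_alt = 4L)               # mosaic mother, retained
  )
  res <- filter_dnm_candidates(cand, sex = "male")
  expect_equal(nrow(res$retained) + sum(res$dropped$n), nrow(cand))
  expect_setequal(res$retained$pos, c(1.1e7, 1.2e7, 1e7))
  expect_equal(res$dropped$n[res$dropped$rule == "par"], 1L)
  expect_equal(res$dropped$n[res$dropped$rule == "depth"], 1L)
  expect_equal(res$dropped$n[res$dropped$rule == "strand_bias"], 1L)
  expect_equal(res$dropped$n[res$dropped$rule == "maternal_het"], 1L)
  expect_equal(res$dropped$n[res$dropped$rule == "segdup_mosaic"], 1L)
  expect_equal(res$dropped$n[res$dropped$rule == "pp_dnm"], 1L)
  expect_equal(res$dropped$n[res$dropped$rule == "uncallable"], 1L)
  expect_equal(res$dropped$n[res$dropped$rule == "population_frequency"], 1L)
  # the retained maternal-mosaic candidate is flagged, the clean ones not
  expect_true(res$retained$mother_mosaic[res$retained$pos == 1e7])
  expect_false(any(res$retained$mother_mosaic[res$retained$pos != 1e7]))

  expect_error(filter_dnm_candidates(base[-3], "male"), "lacks column")
})

test_that("female-specific DNM rules: stricter depths and small-indel screen", {
  base <- tibble::tibble(
    chrom = "X", ref = "A", alt = "TA", indel_len = 1L,
    child_dp = 40L, child_ad_alt = 20L,
    mother_dp = 40L, mother_ad_alt = 0L, father_dp = 30L,
    pp_dnm = 0.9, strand_bias_p = NA_real_, maf_gnomad = 0
  )
  cand <- dplyr::bind_rows(
    dplyr::mutate(base, pos = 3e6),                     # good indel, VAF 0.5
    dplyr::mutate(base, pos = 4e6, child_ad_alt = 8L),  # VAF 0.2 < 0.3
    dplyr::mutate(base, pos = 5e6, maf_gnomad = 1e-5),  # seen in population
    dplyr::mutate(base, pos = 6e6, child_dp = 7L,
                  child_ad_alt = 4L),                   # child depth <= 7
    dplyr::mutate(base, pos = 7e6, father_dp = 1L)      # father depth <= 1
  )
  res <- filter_dnm_candidates(cand, sex = "female")
  expect_setequal(res$retained$pos, 3e6)
  expect_equal(res$dropped$n[res$dropped$rule == "depth"], 2L)
  expect_equal(res$dropped$n[res$dropped$rule == "small_indel"], 2L)

  # indels are exempt from the strand-bias requirement; males skip the
  # small-indel rule entirely
  res_m <- filter_dnm_candidates(
    dplyr::mutate(cand, pos = pos + 1), sex = "male"
  )
  expect_equal(res_m$dropped$n[res_m$dropped$rule == "small_indel"], 0L)
})

test_that("pp_dnm calibration matches the female synonymous expectation", {
  cand <- tibble::tibble(
    consequence = "synonymous",
    pp_dnm = c(0.1, 0.2, 0.3, 0.4, 0.5)
  )
  # keep at most 2: the smallest threshold with #{pp > t} <= 2 is 0.3
  expect_equal(calibrate_ppdnm(cand, 2), 0.3)
  # everything fits within expectation: any threshold below min works
  expect_equal(calibrate_ppdnm(cand, 10), 0.05)
  # retained count at the returned threshold never exceeds the budget (property)
  set.seed(11)
  pp <- runif(200)
  cand2 <- tibble::tibble(consequence = "synonymous", pp_dnm = pp)
  for (budget in c(1, 7, 50, 150)) {
    t <- calibrate_ppdnm(cand2, budget)
    expect_lte(sum(pp > t), budget)
  }
  expect_warning(
    out <- calibrate_ppdnm(tibble::tibble(consequence = "ptv", pp_dnm = 1), 2),
    "no synonymous"
  )
  expect_equal(out, 0.00247679)
})

test_that("XLR carrier ascertainment keeps only qualifying female-only variants", {
  v <- tibble::tibble(
    sample_id = c("f1", "f1", "f2", "f3", "f4", "f5", "f6"),
    gene_id = paste0("G", 1:7),
    inheritance_class = c("XLR", "XLR", "XLD", "XLR", "XLR", "XLR", "XLR"),
    consequence = c("ptv", "missense_inframe", "ptv", "ptv",
                    "missense_inframe", "ptv", "ptv"),
    cadd = c(30, 30, 30, 30, 30, 10, 30),
    mpc = c(NA, 3, NA, NA, 1, NA, NA),
    ptv_hc = c(TRUE, NA, TRUE, TRUE, NA, TRUE, FALSE),
    ref_maf = 0, cohort_af = 1e-4,
    in_males = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  res <- filter_xlr_carriers(v)
  # G1 passes (HC PTV, CADD 30); G2 passes (MPC 3);
  # G3 is XLD; G4 seen in males; G5 MPC too low; G6 CADD too low;
  # G7 is not a high-confidence PTV
  expect_setequal(res$retained$gene_id, c("G1", "G2"))
  expect_equal(res$carrier_counts$n_qualifying[
    res$carrier_counts$sample_id == "f1"], 2L)
  # missing MPC on a missense variant is a skip with a warning
  v2 <- v
  v2$mpc[2] <- NA
  expect_warning(res2 <- filter_xlr_carriers(v2), "missing annotations")
  expect_equal(res2$dropped$n[res2$dropped$rule == "missing_annotation"], 1L)
  expect_setequal(res2$retained$gene_id, "G1")
})
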