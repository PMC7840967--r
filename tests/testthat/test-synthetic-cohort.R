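test_that("gene-model simulation is calibrated, labelled and reproducible", {
  cfg <- small_config()
  gm <- simulate_gene_models(cfg, seed = 10)
  expect_equal(nrow(gm), cfg$n_genes)
  # calibration: cohort-wide expected female synonymous DNMs hit the target
  params <- sex_rate_params(cfg$n_female_trios, cfg$n_male_trios, cfg$alpha)
  e <- expected_dnm_counts(gm, params)
  tot_syn_f <- sum(e$expected[e$sex == "female" & e$class == "synonymous"])
  expect_equal(tot_syn_f, cfg$target_syn_female,
               tolerance = 0.05 * cfg$target_syn_female)
  # risk architecture counts match the configuration
  expect_equal(sum(gm$risk_class == "xlr"), cfg$n_xlr)
  expect_equal(sum(gm$risk_class == "xld"), cfg$n_xld)
  expect_equal(sum(gm$risk_class == "semidom"), cfg$n_semidom)
  expect_true(all(gm$p_syn > 0 & gm$p_mis > 0 & gm$p_ptv > 0))
  # deterministic under the seed
  expect_equal(simulate_gene_models(cfg, seed = 10), gm)
  expect_false(isTRUE(all.equal(simulate_gene_models(cfg, seed = 11), gm)))
})

test_that("DNM simulation respects sex rosters and the risk architecture", {
  cfg <- small_config(rr_dnm = 30)
  gm <- simulate_gene_models(cfg, seed = 2)
  dnms <- simulate_dnms(gm, cfg, seed = 2)
  expect_true(all(dnms$sex %in% c("male", "female")))
  expect_true(all(grepl("^PM", dnms$proband_id[dnms$sex == "male"])))
  expect_true(all(grepl("^PF", dnms$proband_id[dnms$sex == "female"])))
  expect_true(all(dnms$gene_id %in% gm$gene_id))
  # semi-dominant genes never produce male PTV de novo mutations
  semidom <- gm$gene_id[gm$risk_class == "semidom"]
  expect_equal(sum(dnms$sex == "male" & dnms$class == "ptv" &
                     dnms$gene_id %in% semidom), 0)
  # risk multipliers inflate damaging counts relative to the null call
  null_dnms <- simulate_dnms(gm, cfg, seed = 2, use_risk_multipliers = FALSE)
  risk <- gm$gene_id[gm$risk_class != "none"]
  n_risk <- sum(dnms$gene_id %in% risk & dnms$class != "synonymous")
  n_null <- sum(null_dnms$gene_id %in% risk & null_dnms$class != "synonymous")
  expect_gt(n_risk, n_null)
})

test_that("the transmission mechanism converges to the Sherman fraction", {
  # the de novo share implied by the iterated equilibrium equals the closed
  # form for a grid of parameter combinations (mechanism-level oracle)
  for (m in c(0.5, 1)) {
    for (f in c(0, 0.258, 0.497)) {
      load <- xlburden:::xlr_equilibrium_q(m, f, 3.5)
      expect_equal(1 / (1 + load), sherman_fraction(m, f, 3.5),
                   tolerance = 1e-9)
    }
  }
  # simulated cases: realised share near the theoretical value
  cases <- simulate_xlr_cases(20000, m = 1, f = 0.258, nu_over_mu = 3.5,
                              seed = 9)
  share <- mean(cases$mechanism == "de_novo")
  p <- sherman_fraction(1, 0.258, 3.5)
  expect_lt(abs(share - p), 3 * sqrt(p * (1 - p) / 20000))
})

test_that("inherited simulation hits the attributable-fraction target and labels origins", {
  cfg <- small_config(target_af_male = 0.10)
  gm <- simulate_gene_models(cfg, seed = 5)
  inh <- simulate_inherited(gm, cfg, seed = 5)
  n_p <- cfg$n_male_trios + cfg$n_male_caseonly
  expect_true(all(inh$fathers$origin == "background"))
  expect_true(all(inh$probands$origin %in%
                    c("background", "inherited_pathogenic",
                      "denovo_pathogenic")))
  # pathogenic variants only land in XLR risk genes
  path <- inh$probands[inh$probands$origin != "background", ]
  xlr <- gm$gene_id[gm$risk_class == "xlr"]
  expect_true(all(path$gene_id %in% xlr))
  expect_true(all(path$class %in% c("ptv", "missense_inframe")))
  # realised AF within binomial noise of the target
  gt <- inh$ground_truth
  se <- sqrt(0.10 * 0.90 / n_p)
  expect_lt(abs(gt$realised_af_male - 0.10), 4 * se)
  expect_equal(gt$n_pathogenic, nrow(path))
  # trio membership encoded consistently
  expect_true(all(
    inh$probands$in_trio ==
      (as.integer(sub("^PM", "", inh$probands$sample_id)) <=
         cfg$n_male_trios)
  ))
})

test_that("candidate decoration produces filterable truth and artefacts", {
  cfg <- small_config()
  gm <- simulate_gene_models(cfg, seed = 3)
  dnms <- simulate_dnms(gm, cfg, seed = 3)
  male <- dnms[dnms$sex == "male", ]
  cand <- simulate_dnm_candidates(male, sex = "male", n_artifacts = 80,
                                  seed = 3)
  expect_equal(nrow(cand), nrow(male) + 80)
  res <- filter_dnm_candidates(cand, sex = "male")
  # every inherited-het contaminant is removed ...
  expect_false(any(!res$retained$true_dnm))
  # ... while most true DNMs survive
  expect_gt(nrow(res$retained) / nrow(male), 0.85)
  # maternal-mosaic truth is retained and flagged rather than dropped
  if (any(res$retained$mother_mosaic)) {
    expect_true(all(res$retained$true_dnm[res$retained$mother_mosaic]))
  }
})

test_that("cohorts are written to disk as plain text with a manifest", {
  cfg <- small_config()
  cohort <- simulate_cohort(cfg, seed = 6)
  dir <- withr::local_tempdir()
  paths <- emit_cohort(cohort, dir)
  expect_true(all(file.exists(paths)))
  gm2 <- readr::read_tsv(paths[["gene_models"]], show_col_types = FALSE)
  expect_equal(nrow(gm2), cfg$n_genes)
  dn2 <- readr::read_tsv(paths[["dnms"]], show_col_types = FALSE)
  expect_equal(nrow(dn2), nrow(cohort$dnms))
  gt <- jsonlite::read_json(paths[["ground_truth"]])
  expect_true(all(c("realised_af_male", "theoretical_de_novo_share") %in%
                    names(gt)))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_setequal(names(man), names(paths))
})

test_that("the orchestrated cohort merges pathogenic de novo events coherently", {
  cfg <- small_config(target_af_male = 0.15)
  cohort <- simulate_cohort(cfg, seed = 13)
  # every pathogenic de novo event in a trio male appears in the DNM table
  path_dn <- cohort$probands[
    cohort$probands$origin == "denovo_pathogenic" & cohort$probands$in_trio, ]
  for (i in seq_len(nrow(path_dn))) {
    expect_true(any(
      cohort$dnms$proband_id == path_dn$sample_id[i] &
        cohort$dnms$gene_id == path_dn$gene_id[i] &
        cohort$dnms$class == path_dn$class[i]
    ))
  }
  # ground truth records the theoretical share for the configured f
  expect_equal(cohort$ground_truth$theoretical_de_novo_share,
               sherman_fraction(cfg$m, cfg$fertility_f, cfg$nu_over_mu))
  # reproducible
  cohort2 <- simulate_cohort(cfg, seed = 13)
  expect_equal(cohort$dnms, cohort2$dnms)
  expect_equal(cohort$probands, cohort2$probands)
})
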