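# Synthetic trio-cohort generator with recorded ground truth. Emulates the
# statistical structure the analysis assumes: ~800 X-linked genes with
# lognormally dispersed mutation rates, sex-specific DNM counts under the
# parental-origin scaling, rare hemizygous inherited variants in fathers and
# male probands, injected risk genes, and a carrier-female fertility deficit
# that raises the de novo share of X-linked recessive cases.

#' Simulation configuration
#'
#' Defaults reproduce the analysed cohort scale: 5138 male and 3908 female
#' trio probands, 7136 male probands in total, 8551 unaffected fathers, 804
#' X-linked genes, paternal:maternal rate ratio 3.4 and sperm:egg ratio 3.5.
#' The risk architecture defaults to the 63 X-linked recessive and 12
#' dominant genes of the consensus classification plus 2 semi-dominant
#' (male-lethal) genes, and the attributable-fraction targets default to the
#' 6.0% (male) and 6.9% (female) estimates.
#'
#' @param n_genes Number of non-PAR X genes.
#' @param n_male_trios,n_female_trios Trio proband counts.
#' @param n_male_caseonly Additional male probands without parents (the
#'   case/control analysis uses all males).
#' @param n_fathers Unaffected father controls.
#' @param alpha Paternal:maternal SNV rate ratio.
#' @param nu_over_mu Sperm:egg rate ratio for the inheritance models.
#' @param m Reproductive loss in affected males.
#' @param fertility_f Reproductive loss in carrier females (thins risk-gene
#'   transmissions).
#' @param n_xlr,n_xld,n_semidom Risk-gene counts per inheritance mode.
#' @param rr_dnm,rr_cc De novo and case/control relative risks in risk
#'   genes.
#' @param target_af_male,target_af_female Attributable fractions to inject.
#' @param target_syn_female Genome-wide expected female synonymous DNM count
#'   the mutation rates are calibrated to.
#' @param bg_rate Background rare-variant rate per male X per class
#'   (post-filter scale), named by class.
#' @param mis_to_syn,ptv_to_syn Mean class rate ratios.
#' @param rate_sdlog Lognormal dispersion of per-gene mutation rates.
#' @param depth_male_mean,depth_male_sd,depth_female_mean,depth_female_sd
#'   Per-gene depth distribution (mean of per-exon median depths).
#' @param mosaic_mother_frac,mosaic_child_frac Fractions of male DNMs
#'   flagged as maternal-mosaic and post-zygotic, for filter exercises.
#' @param inherited_undersampling Ascertainment knob in (0, 1]: probability
#'   an inherited-cause case enters the cohort (1 = no bias).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 804,
                          n_male_trios = 5138, n_female_trios = 3908,
                          n_male_caseonly = 1998, n_fathers = 8551,
                          alpha = 3.4, nu_over_mu = 3.5, m = 1,
                          fertility_f = 0,
                          n_xlr = 63, n_xld = 12, n_semidom = 2,
                          rr_dnm = 20, rr_cc = 5,
                          target_af_male = 0.060, target_af_female = 0.069,
                          target_syn_female = 25,
                          bg_rate = c(synonymous = 0.25,
                                      missense_inframe = 0.40, ptv = 0.05),
                          mis_to_syn = 2.2, ptv_to_syn = 0.3,
                          rate_sdlog = 0.6,
                          depth_male_mean = 40, depth_male_sd = 8,
                          depth_female_mean = 55, depth_female_sd = 10,
                          mosaic_mother_frac = 0.06,
                          mosaic_child_frac = 0.09,
                          inherited_undersampling = 1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_genes >= 1, cfg$alpha > 0, cfg$nu_over_mu > 0,
    cfg$fertility_f >= 0, cfg$fertility_f <= 1,
    cfg$m >= 0, cfg$m <= 1,
    cfg$target_af_male >= 0, cfg$target_af_male <= 1,
    cfg$inherited_undersampling > 0, cfg$inherited_undersampling <= 1
  )
  structure(cfg, class = "cohort_config")
}

#' Simulate per-gene mutation models
#'
#' Haploid per-gene mutation probabilities are drawn lognormally per class
#' and rescaled so that the cohort-wide expected female synonymous DNM count
#' matches the configured target; per-sex depths are drawn normally
#' (truncated at 5x); risk labels are assigned to a random subset of genes.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; every downstream table is reproducible from it.
#' @return A gene-model tibble (see [read_gene_models()]) with extra columns
#'   `risk_class` (`"none"`, `"xlr"`, `"xld"`, `"semidom"`), `rr_dnm`,
#'   `rr_cc`.
#' @export
simulate_gene_models <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_genes
  p_syn <- rlnorm(n, log(4e-6), config$rate_sdlog)
  p_mis <- p_syn * config$mis_to_syn * rlnorm(n, 0, 0.2)
  p_ptv <- p_syn * config$ptv_to_syn * rlnorm(n, 0, 0.3)
  depth_m <- pmax(rnorm(n, config$depth_male_mean, config$depth_male_sd), 5)
  depth_f <- pmax(rnorm(n, config$depth_female_mean, config$depth_female_sd), 5)

  params <- sex_rate_params(config$n_female_trios, config$n_male_trios,
                            config$alpha)
  f_fem <- sex_scaling_factors(params)$f_females
  tot_syn_f <- sum(f_fem * depth_adjust(p_syn, depth_f, "female"))
  scale <- config$target_syn_female / tot_syn_f
  p_syn <- p_syn * scale
  p_mis <- p_mis * scale
  p_ptv <- p_ptv * scale

  n_risk <- config$n_xlr + config$n_xld + config$n_semidom
  if (n_risk > n) abort("more risk genes than genes")
  risk_class <- rep("none", n)
  idx <- sample.int(n, n_risk)
  risk_class[idx] <- rep(c("xlr", "xld", "semidom"),
                         c(config$n_xlr, config$n_xld, config$n_semidom))
  tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(n)),
    p_syn = p_syn, p_mis = p_mis, p_ptv = p_ptv,
    depth_male = depth_m, depth_female = depth_f,
    known_dd = risk_class != "none",
    inheritance_class = dplyr::case_when(
      risk_class == "xlr" ~ "XLR",
      risk_class == "xld" ~ "XLD",
      .default = "both_or_uncertain"
    ),
    risk_class = risk_class,
    rr_dnm = ifelse(risk_class == "none", 1, config$rr_dnm),
    rr_cc = ifelse(risk_class == "none", 1, config$rr_cc)
  )
}

#' Simulate de novo mutations
#'
#' Null counts per gene, sex and class are Poisson at the expectations from
#' the mutation model (parental-origin scaling plus depth adjustment). When
#' `use_risk_multipliers` is `TRUE`, risk genes multiply damaging-class
#' rates in the susceptible sex(es): XLR genes in males, XLD genes in both
#' sexes, semi-dominant genes in females with male PTVs suppressed. A
#' configurable fraction of male DNMs is flagged maternal-mosaic or
#' post-zygotic for filter exercises.
#'
#' @param gene_models From [simulate_gene_models()].
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param use_risk_multipliers Apply the risk-gene relative risks (set
#'   `FALSE` for a pure null cohort or when pathogenic de novo events are
#'   generated by the inheritance mechanism instead).
#' @return A DNM tibble: `proband_id`, `sex`, `gene_id`, `class`,
#'   `mother_mosaic`, `child_mosaic`.
#' @export
simulate_dnms <- function(gene_models, config = cohort_config(), seed = 1,
                          use_risk_multipliers = TRUE) {
  set.seed(seed + 1L)
  params <- sex_rate_params(config$n_female_trios, config$n_male_trios,
                            config$alpha)
  expected <- expected_dnm_counts(gene_models, params)
  expected <- dplyr::left_join(
    expected,
    gene_models[c("gene_id", "risk_class", "rr_dnm")],
    by = "gene_id"
  )
  damaging <- expected$class %in% c("ptv", "missense_inframe")
  mult <- rep(1, nrow(expected))
  if (use_risk_multipliers) {
    mult[damaging & expected$risk_class == "xlr" & expected$sex == "male"] <-
      config$rr_dnm
    mult[damaging & expected$risk_class == "xld"] <- config$rr_dnm
    mult[damaging & expected$risk_class == "semidom" &
           expected$sex == "female"] <- config$rr_dnm
    mult[expected$class == "ptv" & expected$risk_class == "semidom" &
           expected$sex == "male"] <- 0
  }
  counts <- rpois(nrow(expected), expected$expected * mult)
  rows <- expected[rep(seq_len(nrow(expected)), counts),
                   c("gene_id", "sex", "class")]
  n_m <- config$n_male_trios
  n_f <- config$n_female_trios
  rows$proband_id <- ifelse(
    rows$sex == "male",
    sprintf("PM%05d", sample.int(n_m, nrow(rows), replace = TRUE)),
    sprintf("PF%05d", sample.int(n_f, nrow(rows), replace = TRUE))
  )
  is_male <- rows$sex == "male"
  rows$mother_mosaic <- FALSE
  rows$child_mosaic <- FALSE
  rows$mother_mosaic[is_male] <- runif(sum(is_male)) < config$mosaic_mother_frac
  rows$child_mosaic[is_male] <- !rows$mother_mosaic[is_male] &
    runif(sum(is_male)) < config$mosaic_child_frac
  tibble::as_tibble(rows[c("proband_id", "sex", "gene_id", "class",
                           "mother_mosaic", "child_mosaic")])
}

# Equilibrium inherited pathogenic load in eggs (relative to the egg
# mutation rate) under mutation-selection balance with male loss m and
# carrier-female loss f, found by iterating the one-generation recursion of
# the egg and sperm allele frequencies rather than by the closed form, so
# that convergence to the Haldane/Sherman fractions is a genuine check of
# the generator. A random egg draws from a female's two Xs, thinned by the
# carrier deficit, plus new mutation; a random sperm carries the male's
# single maternal X, thinned by male selection, plus new mutation. The de
# novo fraction among affected males is mu / q_egg = 1 / (1 + load).
xlr_equilibrium_q <- function(m, f, nu_over_mu, tol = 1e-12, max_iter = 1e5) {
  mu <- 1
  nu <- nu_over_mu
  q_e <- mu + nu
  q_s <- mu + nu
  for (i in seq_len(max_iter)) {
    q_e_new <- (1 - f) * (q_e + q_s) / 2 + mu
    q_s_new <- (1 - m) * q_e + nu
    if (abs(q_e_new - q_e) < tol && abs(q_s_new - q_s) < tol) break
    q_e <- q_e_new
    q_s <- q_s_new
  }
  q_e - mu # inherited load per egg, in units of mu
}

#' Simulate the origin mechanism of X-linked recessive male cases
#'
#' Each affected male's pathogenic allele is either a new mutation in the
#' egg (rate proportional to the egg rate mu) or a transmission from a
#' carrier mother (carrier frequency at the mutation-selection equilibrium,
#' thinned by the carrier fertility deficit `f`). The equilibrium frequency
#' is obtained by iterating the one-generation recursion, so the realised de
#' novo share converges to the Haldane (`f = 0`) or Sherman fraction.
#'
#' @param n_cases Number of affected males to simulate.
#' @param m,f,nu_over_mu Model parameters, see [sherman_fraction()].
#' @param seed Integer seed.
#' @return A tibble `case_id`, `mechanism` (`"de_novo"` / `"inherited"`).
#' @export
simulate_xlr_cases <- function(n_cases, m = 1, f = 0, nu_over_mu = 3.5,
                               seed = 1) {
  set.seed(seed + 2L)
  load <- xlr_equilibrium_q(m, f, nu_over_mu)
  p_dn <- 1 / (1 + load) # mu = 1 scale
  tibble::tibble(
    case_id = sprintf("C%06d", seq_len(n_cases)),
    mechanism = ifelse(runif(n_cases) < p_dn, "de_novo", "inherited")
  )
}

#' Simulate inherited rare variants in fathers and male probands
#'
#' Fathers carry background rare variants at the configured per-class rates
#' (genes weighted by their mutation probabilities); male probands carry the
#' same background (maternally transmitted neutral variation reaches the
#' case/control MAF filter at the same per-person rate) plus pathogenic
#' variants in XLR risk genes at the target attributable fraction. Each
#' pathogenic case's mechanism (de novo in the egg versus transmission from
#' a carrier mother, thinned by the fertility deficit) follows the
#' mutation-selection equilibrium, so the realised de novo share of XLR
#' cases converges to the Sherman fraction.
#'
#' @param gene_models From [simulate_gene_models()].
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A list: `fathers` and `probands` variant tibbles (`sample_id`,
#'   `gene_id`, `class`, `origin`, `in_trio`), and `ground_truth` (risk
#'   labels, realised attributable fraction and de novo share).
#' @export
simulate_inherited <- function(gene_models, config = cohort_config(),
                               seed = 1) {
  set.seed(seed + 3L)
  classes <- c("synonymous", "missense_inframe", "ptv")
  rate_cols <- c(synonymous = "p_syn", missense_inframe = "p_mis",
                 ptv = "p_ptv")
  n_p <- config$n_male_trios + config$n_male_caseonly
  n_f <- config$n_fathers

  draw_background <- function(n_people, prefix) {
    purrr::map_dfr(classes, function(cl) {
      total <- rpois(1, n_people * config$bg_rate[[cl]])
      w <- gene_models[[rate_cols[[cl]]]]
      tibble::tibble(
        sample_id = sprintf("%s%05d", prefix,
                            sample.int(n_people, total, replace = TRUE)),
        gene_id = sample(gene_models$gene_id, total, replace = TRUE,
                         prob = w / sum(w)),
        class = cl,
        origin = "background"
      )
    })
  }
  fathers <- draw_background(n_f, "F")
  probands <- draw_background(n_p, "PM")

  # pathogenic burden in male probands
  if (config$target_af_male > 1) abort("target attributable fraction > 1")
  n_path <- rbinom(1, n_p, config$target_af_male)
  xlr_genes <- gene_models$gene_id[gene_models$risk_class == "xlr"]
  path <- NULL
  de_novo_share <- NA_real_
  if (n_path > 0 && length(xlr_genes)) {
    load <- xlr_equilibrium_q(config$m, config$fertility_f, config$nu_over_mu)
    p_dn <- 1 / (1 + load)
    mech <- ifelse(runif(n_path) < p_dn, "denovo_pathogenic",
                   "inherited_pathogenic")
    keep <- mech == "denovo_pathogenic" |
      runif(n_path) < config$inherited_undersampling
    mech <- mech[keep]
    n_path <- length(mech)
    w <- gene_models$p_mis[gene_models$risk_class == "xlr"] +
      gene_models$p_ptv[gene_models$risk_class == "xlr"]
    carriers <- sample.int(n_p, n_path, replace = FALSE)
    path_gene <- sample(xlr_genes, n_path, replace = TRUE, prob = w / sum(w))
    gm <- gene_models[match(path_gene, gene_models$gene_id), ]
    path_class <- ifelse(
      runif(n_path) < gm$p_ptv / (gm$p_ptv + gm$p_mis),
      "ptv", "missense_inframe"
    )
    path <- tibble::tibble(
      sample_id = sprintf("PM%05d", carriers),
      gene_id = path_gene,
      class = path_class,
      origin = mech
    )
    de_novo_share <- mean(mech == "denovo_pathogenic")
  }
  probands <- dplyr::bind_rows(probands, path)
  probands$in_trio <- as.integer(sub("^PM", "", probands$sample_id)) <=
    config$n_male_trios
  fathers$in_trio <- FALSE

  realised_af <- n_path / n_p
  list(
    fathers = fathers,
    probands = probands,
    ground_truth = list(
      risk_genes = gene_models[gene_models$risk_class != "none",
                               c("gene_id", "risk_class", "rr_dnm", "rr_cc")],
      n_pathogenic = n_path,
      realised_af_male = realised_af,
      realised_de_novo_share = de_novo_share,
      theoretical_de_novo_share = sherman_fraction(
        config$m, config$fertility_f, config$nu_over_mu
      )
    )
  )
}

#' Decorate DNMs as caller candidates, with artefact contamination
#'
#' Adds read-level fields to true DNMs (high posterior probability, clean
#' strand balance, homozygous-reference mothers — or low-level maternal
#' alternate reads for the injected maternal-mosaic fraction) and appends
#' inherited-heterozygous-mother contaminants with low caller posterior
#' probabilities, producing a candidate table for [filter_dnm_candidates()].
#'
#' @param dnms From [simulate_dnms()] (one sex at a time).
#' @param sex Proband sex of the table.
#' @param n_artifacts Number of inherited-het contaminants to append.
#' @param mean_dp Mean read depth.
#' @param seed Integer seed.
#' @return A candidate tibble.
#' @export
simulate_dnm_candidates <- function(dnms, sex = c("male", "female"),
                                    n_artifacts = 100, mean_dp = 40,
                                    seed = 1) {
  sex <- match.arg(sex)
  set.seed(seed + 4L)
  n <- nrow(dnms)
  dp <- function(k, lambda = mean_dp) pmax(rpois(k, lambda), 8)
  child_dp <- dp(n)
  child_vaf <- if (sex == "male") 0.97 else 0.5
  truth <- tibble::tibble(
    chrom = "X",
    pos = sample(3e6:1.5e8, n + n_artifacts, replace = FALSE)[seq_len(n)],
    ref = "A", alt = "T",
    proband_id = dnms$proband_id,
    consequence = dnms$class,
    child_dp = child_dp,
    child_ad_alt = rbinom(n, child_dp, child_vaf),
    mother_dp = dp(n),
    pp_dnm = runif(n, 0.5, 1),
    indel_len = 0L,
    in_segdup = FALSE,
    strand_bias_p = runif(n, 0.1, 1),
    maf_gnomad = 0, gnomad_hemi = 0L,
    true_dnm = TRUE
  )
  truth$mother_ad_alt <- ifelse(
    dnms$mother_mosaic,
    rbinom(n, truth$mother_dp, 0.08),
    rbinom(n, truth$mother_dp, 0.002)
  )
  if (n_artifacts > 0) {
    a_dp <- dp(n_artifacts)
    m_dp <- dp(n_artifacts)
    art <- tibble::tibble(
      chrom = "X",
      pos = sample(3e6:1.5e8, n_artifacts),
      ref = "A", alt = "T",
      proband_id = sprintf("ART%04d", seq_len(n_artifacts)),
      consequence = sample(c("synonymous", "missense_inframe", "ptv"),
                           n_artifacts, replace = TRUE),
      child_dp = a_dp,
      child_ad_alt = rbinom(n_artifacts, a_dp, child_vaf),
      mother_dp = m_dp,
      mother_ad_alt = rbinom(n_artifacts, m_dp, 0.5),
      pp_dnm = runif(n_artifacts, 0, 0.002),
      indel_len = 0L,
      in_segdup = FALSE,
      strand_bias_p = runif(n_artifacts, 0.1, 1),
      maf_gnomad = 0, gnomad_hemi = 0L,
      true_dnm = FALSE
    )
    truth <- dplyr::bind_rows(truth, art)
  }
  truth$father_dp <- dp(nrow(truth))
  truth
}

#' Write a simulated cohort to disk
#'
#' Emits the tab-separated inputs consumed by the filter, burden and
#' discovery stages plus a ground-truth JSON and a manifest.
#'
#' @param cohort A list as returned by [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest (named vector of file paths).
#' @export
emit_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gene_models = file.path(dir, "gene_models.tsv"),
    dnms = file.path(dir, "dnms.tsv"),
    proband_variants = file.path(dir, "proband_variants.tsv"),
    father_variants = file.path(dir, "father_variants.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_tsv(cohort$gene_models, paths[["gene_models"]])
  readr::write_tsv(cohort$dnms, paths[["dnms"]])
  readr::write_tsv(cohort$probands, paths[["proband_variants"]])
  readr::write_tsv(cohort$fathers, paths[["father_variants"]])
  gt <- cohort$ground_truth
  gt$risk_genes <- as.data.frame(gt$risk_genes)
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(as.list(paths), manifest, auto_unbox = TRUE)
  invisible(paths)
}

#' Simulate a full cohort
#'
#' Orchestrates the generators into one coherent cohort: gene models, null
#' DNMs plus risk-gene DNM excess in females (dominant and semi-dominant
#' architecture), pathogenic male events split between de novo and inherited
#' by the mutation-selection mechanism, and background inherited variation
#' in fathers and male probands. Pathogenic de novo events in trio males are
#' merged into the DNM table so the DNM and case/control views agree.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A list: `gene_models`, `dnms`, `probands`, `fathers`,
#'   `ground_truth`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  gm <- simulate_gene_models(config, seed)
  # female-side architecture through rate multipliers; male XLR pathogenic
  # events come from the inheritance mechanism below, so suppress the male
  # XLR multiplier by relabelling for this call.
  gm_female_arch <- gm
  gm_female_arch$risk_class[gm_female_arch$risk_class == "xlr"] <- "none"
  dnms <- simulate_dnms(gm_female_arch, config, seed)
  inh <- simulate_inherited(gm, config, seed)

  set.seed(seed + 5L)
  path_dn <- inh$probands[
    inh$probands$origin == "denovo_pathogenic" & inh$probands$in_trio, ]
  if (nrow(path_dn)) {
    dnms <- dplyr::bind_rows(
      dnms,
      tibble::tibble(
        proband_id = path_dn$sample_id, sex = "male",
        gene_id = path_dn$gene_id, class = path_dn$class,
        mother_mosaic = FALSE, child_mosaic = FALSE
      )
    )
  }
  list(
    gene_models = gm,
    dnms = dnms,
    probands = inh$probands,
    fathers = inh$fathers,
    ground_truth = inh$ground_truth
  )
}
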