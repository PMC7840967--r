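# Post-calling filter rules for case/control calls, de novo candidates,
# and carrier ascertainment. Each filter returns the retained rows plus a
# drop ledger (tibble of rule, n) so that input = output + sum(ledger).

new_filter_result <- function(retained, ledger) {
  structure(list(retained = retained, dropped = ledger),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> ", nrow(x$retained), " rows retained\n", sep = "")
  print(x$dropped)
  invisible(x)
}

ledger_row <- function(rule, n) tibble::tibble(rule = rule, n = as.integer(n))

#' Case/control genotype and site filters for hemizygous calls in males
#'
#' Genotype-level: calls are set to missing if genotype quality (GQ) < 20,
#' depth (DP) < 7, or the call is heterozygous (impossible for a true
#' hemizygous male X call outside the PARs). Site-level: a site is removed
#' if it lies in a pseudoautosomal region, shows strand bias (p < 0.001),
#' has more than 50% missing genotypes after genotype filtering, has minor
#' allele frequency above `max_maf` in any annotated population (reference
#' or internal parental), or has any hemizygote in the population reference.
#'
#' @param genotypes Tibble of per-sample calls: `sample_id`, `variant_id`,
#'   `gt` (one of `"hom_ref"`, `"het"`, `"hemi"`/`"hom_alt"`), `gq`, `dp`.
#' @param sites Tibble of per-site annotations: `variant_id`, `chrom`, `pos`,
#'   `strand_bias_p`, `gnomad_hemi`, population frequency columns matched by
#'   `maf_cols` (missing frequencies are treated as 0), and optionally
#'   `missing_frac` (recomputed from `genotypes` when absent).
#' @param max_maf Population MAF ceiling (default 0.001).
#' @param max_missing Maximum fraction of missing genotypes (default 0.5).
#' @param min_gq,min_dp Genotype-quality and depth floors (20, 7).
#' @param maf_cols Regular expression selecting frequency columns
#'   (default `"^maf_"`).
#' @param par PAR table (see [par_regions()]).
#' @return A `filter_result` list: `retained` — alt-carrying calls at passing
#'   sites, `dropped` — per-rule drop ledger (site-level rules count sites;
#'   the genotype rule counts calls set to missing).
#' @export
filter_case_control <- function(genotypes, sites,
                                max_maf = 0.001, max_missing = 0.5,
                                min_gq = 20, min_dp = 7,
                                maf_cols = "^maf_", par = par_regions()) {
  stopifnot(all(c("sample_id", "variant_id", "gt", "gq", "dp") %in% names(genotypes)))
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(sites)))

  miss <- genotypes$gq < min_gq | genotypes$dp < min_dp | genotypes$gt == "het"
  miss[is.na(miss)] <- TRUE
  gt_ok <- genotypes[!miss, , drop = FALSE]

  missing_frac <- genotypes |>
    dplyr::mutate(miss = miss) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(missing_frac_obs = mean(.data$miss), .groups = "drop")
  sites2 <- dplyr::left_join(sites, missing_frac, by = "variant_id")
  if (!"missing_frac" %in% names(sites2)) {
    sites2$missing_frac <- sites2$missing_frac_obs
  } else {
    sites2$missing_frac <- dplyr::coalesce(
      sites2$missing_frac, sites2$missing_frac_obs
    )
  }
  sites2$missing_frac[is.na(sites2$missing_frac)] <- 0

  fcols <- grep(maf_cols, names(sites2), value = TRUE)
  max_freq <- if (length(fcols)) {
    do.call(pmax, c(lapply(fcols, function(cl) {
      dplyr::coalesce(sites2[[cl]], 0)
    }), list(na.rm = TRUE)))
  } else {
    rep(0, nrow(sites2))
  }

  rules <- list(
    par = in_par(sites2$chrom, sites2$pos, par),
    strand_bias = dplyr::coalesce(sites2$strand_bias_p < 0.001, FALSE),
    missingness = sites2$missing_frac > max_missing,
    maf = max_freq > max_maf,
    gnomad_hemizygotes = dplyr::coalesce(sites2$gnomad_hemi > 0, FALSE)
  )
  # A site is attributed to the first rule it violates, so the ledger sums
  # to sites-in minus sites-out.
  dropped_by <- rep(NA_character_, nrow(sites2))
  for (rn in names(rules)) {
    hit <- rules[[rn]] & is.na(dropped_by)
    dropped_by[hit] <- rn
  }
  ledger <- dplyr::bind_rows(
    ledger_row("genotype_missing", sum(miss)),
    dplyr::bind_rows(lapply(names(rules), function(rn) {
      ledger_row(rn, sum(dropped_by == rn, na.rm = TRUE))
    }))
  )
  keep_sites <- sites2$variant_id[is.na(dropped_by)]
  retained <- gt_ok |>
    dplyr::filter(.data$variant_id %in% keep_sites,
                  .data$gt %in% c("hemi", "hom_alt"))
  new_filter_result(retained, ledger)
}

# Binomial mosaic screen: significantly below heterozygous balance (lower
# tail vs 0.5) yet significantly above the sequencing error rate.
mosaic_flag <- function(ad_alt, dp, error_rate = 0.002, alpha = 0.01) {
  ok <- !is.na(ad_alt) & !is.na(dp) & dp > 0
  p_low <- rep(NA_real_, length(dp))
  p_err <- rep(NA_real_, length(dp))
  p_low[ok] <- pbinom(ad_alt[ok], dp[ok], 0.5)
  p_err[ok] <- pbinom(ad_alt[ok] - 1, dp[ok], error_rate, lower.tail = FALSE)
  dplyr::coalesce(p_low < alpha & p_err < alpha, FALSE)
}

binom_two_sided <- function(x, n, p) {
  ok <- !is.na(x) & !is.na(n) & n > 0
  out <- rep(NA_real_, length(x))
  out[ok] <- vapply(
    which(ok),
    function(i) binom.test(x[i], n[i], p)$p.value,
    numeric(1)
  )
  out
}

#' Pooled Fisher strand-bias test across trios sharing a site
#'
#' Forward/reverse read counts for reference and alternate alleles are summed
#' across all trios in which the candidate was called at the same site, and a
#' Fisher exact test is applied to the pooled 2x2 table.
#'
#' @param candidates Tibble with `chrom`, `pos`, `ref`, `alt` and strand
#'   count columns `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`.
#' @return The input with a `strand_bias_p` column added (per site).
#' @export
pooled_strand_bias <- function(candidates) {
  cols <- c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")
  stopifnot(all(cols %in% names(candidates)))
  pooled <- candidates |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), ~ sum(.x, na.rm = TRUE)),
                     .groups = "drop")
  pooled$strand_bias_p <- vapply(seq_len(nrow(pooled)), function(i) {
    m <- matrix(c(pooled$ref_fwd[i], pooled$ref_rev[i],
                  pooled$alt_fwd[i], pooled$alt_rev[i]), nrow = 2, byrow = TRUE)
    fisher.test(m)$p.value
  }, numeric(1))
  dplyr::left_join(
    dplyr::select(candidates, -dplyr::any_of("strand_bias_p")),
    dplyr::select(pooled, "chrom", "pos", "ref", "alt", "strand_bias_p"),
    by = c("chrom", "pos", "ref", "alt")
  )
}

#' Filter de novo mutation candidates
#'
#' Applies, in order: PAR exclusion; caller genotype requirements (child
#' called het/hemizygous, parents homozygous reference, when `child_gt` /
#' `mother_gt` / `father_gt` columns are present); sex-specific read-depth
#' rules (males: child alt depth > 2 and depth > 2, mother depth > 5;
#' females: child alt depth > 2 and depth > 7, mother depth > 5, father
#' depth > 1); pooled Fisher strand test (SNVs require p > 1e-3); the female
#' small-indel rule (indels < 5 bp dropped when VAF < 0.3 or population
#' MAF > 0); the maternal heterozygosity screen (two-sided binomial of
#' mother alt reads vs 0.5 — candidates with p_het > 0.01 look truly
#' heterozygous in the mother, i.e. inherited, and are discarded); mosaic
#' flagging of mother and child (lower-tailed p_het < 0.01 and upper-tailed
#' binomial vs error rate 0.002 with p < 0.01); removal of
#' segmental-duplication variants where both child and mother are flagged
#' mosaic; the caller posterior-probability threshold (`pp_dnm`, candidates
#' lacking it are rejected as uncallable); and population-frequency rules
#' (MAF <= 0.001 everywhere, zero gnomAD hemizygotes).
#'
#' @param candidates Candidate tibble; required columns: `chrom`, `pos`,
#'   `ref`, `alt`, `child_ad_alt`, `child_dp`, `mother_dp`, `mother_ad_alt`,
#'   `pp_dnm`, `indel_len` (0 for SNVs). Used when present: `father_dp`,
#'   `vaf`, `in_segdup`, `strand_bias_p` (or strand count columns, see
#'   [pooled_strand_bias()]), `gnomad_hemi`, `child_gt`, `mother_gt`,
#'   `father_gt`, frequency columns matching `maf_cols`.
#' @param sex Proband sex, `"male"` or `"female"`.
#' @param pp_dnm_threshold Posterior-probability cutoff (default 0.00247679,
#'   the value at which retained female synonymous DNMs match expectation;
#'   see [calibrate_ppdnm()]).
#' @param max_maf Population MAF ceiling (default 0.001).
#' @param error_rate Per-base sequencing error rate for the mosaic screen.
#' @param maf_cols Regular expression selecting frequency columns.
#' @param par PAR table.
#' @return A `filter_result`: `retained` with logical `mother_mosaic` and
#'   `child_mosaic` columns added, and the per-rule `dropped` ledger.
#' @export
filter_dnm_candidates <- function(candidates, sex = c("male", "female"),
                                  pp_dnm_threshold = 0.00247679,
                                  max_maf = 0.001, error_rate = 0.002,
                                  maf_cols = "^maf_", par = par_regions()) {
  sex <- match.arg(sex)
  req <- c("chrom", "pos", "ref", "alt", "child_ad_alt", "child_dp",
           "mother_dp", "mother_ad_alt", "pp_dnm", "indel_len")
  missing_cols <- setdiff(req, names(candidates))
  if (length(missing_cols)) {
    abort(paste0("candidate table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- candidates
  if (!"strand_bias_p" %in% names(x) &&
      all(c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev") %in% names(x))) {
    x <- pooled_strand_bias(x)
  }
  ledger <- list()
  drop_rule <- function(x, keep, rule) {
    keep[is.na(keep)] <- FALSE
    ledger[[rule]] <<- ledger_row(rule, sum(!keep))
    x[keep, , drop = FALSE]
  }

  x <- drop_rule(x, !in_par(x$chrom, x$pos, par), "par")

  if ("child_gt" %in% names(x)) {
    want_child <- if (sex == "male") c("het", "hemi") else "het"
    keep <- x$child_gt %in% want_child
    if ("mother_gt" %in% names(x)) keep <- keep & x$mother_gt == "hom_ref"
    if ("father_gt" %in% names(x) && sex == "female") {
      keep <- keep & x$father_gt == "hom_ref"
    }
    x <- drop_rule(x, keep, "caller_genotype")
  }

  keep <- if (sex == "male") {
    x$child_ad_alt > 2 & x$child_dp > 2 & x$mother_dp > 5
  } else {
    fd <- if ("father_dp" %in% names(x)) x$father_dp else Inf
    x$child_ad_alt > 2 & x$child_dp > 7 & x$mother_dp > 5 & fd > 1
  }
  x <- drop_rule(x, keep, "depth")

  is_snv <- x$indel_len == 0
  sbp <- if ("strand_bias_p" %in% names(x)) x$strand_bias_p else NA_real_
  x <- drop_rule(x, !is_snv | is.na(sbp) | sbp > 1e-3, "strand_bias")

  max_freq_of <- function(x) {
    fcols <- grep(maf_cols, names(x), value = TRUE)
    if (!length(fcols)) return(rep(0, nrow(x)))
    do.call(pmax, c(lapply(fcols, function(cl) dplyr::coalesce(x[[cl]], 0)),
                    list(na.rm = TRUE)))
  }
  if (sex == "female") {
    vaf <- if ("vaf" %in% names(x)) {
      dplyr::coalesce(x$vaf, x$child_ad_alt / x$child_dp)
    } else {
      x$child_ad_alt / x$child_dp
    }
    small_indel <- x$indel_len != 0 & abs(x$indel_len) < 5
    bad <- small_indel & (vaf < 0.3 | max_freq_of(x) > 0)
    x <- drop_rule(x, !bad, "small_indel")
  } else {
    ledger[["small_indel"]] <- ledger_row("small_indel", 0L)
  }

  p_het <- binom_two_sided(x$mother_ad_alt, x$mother_dp, 0.5)
  x <- drop_rule(x, is.na(p_het) | p_het <= 0.01, "maternal_het")

  x$mother_mosaic <- mosaic_flag(x$mother_ad_alt, x$mother_dp, error_rate)
  x$child_mosaic <- mosaic_flag(x$child_ad_alt, x$child_dp, error_rate)
  segdup <- if ("in_segdup" %in% names(x)) {
    dplyr::coalesce(x$in_segdup, FALSE)
  } else {
    rep(FALSE, nrow(x))
  }
  x <- drop_rule(x, !(segdup & x$child_mosaic & x$mother_mosaic),
                 "segdup_mosaic")

  x <- drop_rule(x, !is.na(x$pp_dnm), "uncallable")
  x <- drop_rule(x, x$pp_dnm > pp_dnm_threshold, "pp_dnm")

  hemi <- if ("gnomad_hemi" %in% names(x)) {
    dplyr::coalesce(x$gnomad_hemi, 0)
  } else {
    rep(0, nrow(x))
  }
  x <- drop_rule(x, max_freq_of(x) <= max_maf & hemi == 0,
                 "population_frequency")

  new_filter_result(x, dplyr::bind_rows(ledger))
}

#' Calibrate the de novo posterior-probability threshold
#'
#' The caller's posterior-probability cutoff is set so that the number of
#' retained synonymous DNMs in females matches the number expected under the
#' null mutation model — synonymous variants carry no burden, so any excess
#' above expectation is artefact. Returns the smallest threshold at which
#' the retained female synonymous count is at most the expectation.
#'
#' @param candidates_female Female candidates that already passed all hard
#'   filters; columns `consequence` and `pp_dnm`.
#' @param expected_syn_female Expected number of female synonymous DNMs.
#' @param default Returned (with a warning) when no synonymous candidates
#'   are available.
#' @return A single numeric threshold.
#' @export
calibrate_ppdnm <- function(candidates_female, expected_syn_female,
                            default = 0.00247679) {
  if (expected_syn_female <= 0) abort("`expected_syn_female` must be positive")
  pp <- candidates_female$pp_dnm[
    candidates_female$consequence == "synonymous" & !is.na(candidates_female$pp_dnm)
  ]
  if (!length(pp)) {
    warn("no synonymous candidates; returning the default pp_dnm threshold")
    return(default)
  }
  if (length(pp) <= expected_syn_female) {
    # everything can be retained: any threshold below the smallest pp works
    return(min(pp) / 2)
  }
  # retained(t) = #{pp > t} is a step function decreasing in t; scan the
  # sorted pp values for the smallest threshold meeting the budget.
  grid <- sort(unique(c(0, pp)))
  retained <- vapply(grid, function(t) sum(pp > t), numeric(1))
  ok <- retained <= expected_syn_female
  grid[which(ok)[1]]
}

#' Qualifying heterozygous carrier variants in X-linked recessive genes
#'
#' Ascertainment filters for carrier females: variants must lie in
#' XLR-only genes; PTVs must be high-confidence loss-of-function calls with
#' CADD > 25; missense variants need CADD > 25 and MPC > 2; the reference
#' population frequency must be below `max_ref_maf` and the cohort allele
#' frequency at most `max_cohort_af`; and the variant must be absent from
#' all male cohort members. Rows with missing required annotations are
#' skipped with a warning.
#'
#' @param variants Tibble with `sample_id`, `gene_id`, `inheritance_class`,
#'   `consequence` (`"ptv"`, `"missense_inframe"` or `"synonymous"`),
#'   `cadd`, `mpc`, `ptv_hc` (logical, high-confidence PTV), `ref_maf`,
#'   `cohort_af`, `in_males` (logical).
#' @param min_cadd,min_mpc Score floors (strict: retained if score exceeds
#'   the floor).
#' @param max_ref_maf,max_cohort_af Frequency ceilings.
#' @return A `filter_result` whose `retained` element carries the passing
#'   variants and an extra `carrier_counts` element (per-sample counts).
#' @export
filter_xlr_carriers <- function(variants, min_cadd = 25, min_mpc = 2,
                                max_ref_maf = 0.001, max_cohort_af = 1e-3) {
  req <- c("sample_id", "gene_id", "inheritance_class", "consequence",
           "cadd", "ref_maf", "cohort_af", "in_males")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols)) {
    abort(paste0("variant table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- variants
  need <- x$consequence %in% c("ptv", "missense_inframe")
  ann_ok <- !is.na(x$cadd) & !is.na(x$ref_maf) & !is.na(x$cohort_af) &
    !is.na(x$in_males)
  mis <- x$consequence == "missense_inframe"
  if ("mpc" %in% names(x)) {
    ann_ok[mis] <- ann_ok[mis] & !is.na(x$mpc[mis])
  } else {
    ann_ok[mis] <- FALSE
  }
  skipped <- need & !ann_ok
  if (any(skipped)) {
    warn(paste0(sum(skipped), " variant(s) skipped for missing annotations"))
  }
  x <- x[!skipped, , drop = FALSE]

  keep <- x$inheritance_class == "XLR" &
    x$consequence %in% c("ptv", "missense_inframe") &
    x$cadd > min_cadd &
    x$ref_maf < max_ref_maf &
    x$cohort_af <= max_cohort_af &
    !x$in_males
  is_ptv <- x$consequence == "ptv"
  if ("ptv_hc" %in% names(x)) {
    keep[is_ptv] <- keep[is_ptv] & dplyr::coalesce(x$ptv_hc[is_ptv], FALSE)
  }
  mis <- x$consequence == "missense_inframe"
  keep[mis] <- keep[mis] & x$mpc[mis] > min_mpc
  keep[is.na(keep)] <- FALSE

  retained <- x[keep, , drop = FALSE]
  out <- new_filter_result(
    retained,
    dplyr::bind_rows(
      ledger_row("missing_annotation", sum(skipped)),
      ledger_row("ascertainment", sum(!keep))
    )
  )
  out$carrier_counts <- retained |>
    dplyr::count(.data$sample_id, name = "n_qualifying")
  out
}
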