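# End-to-end pipeline and file IO: read variant tables (TSV or VCF), run
# simulate -> filter -> burden -> inheritance -> discovery, write results.

#' Read a variant table
#'
#' Reads either a tab-separated table (passed through as-is, with column
#' names checked) or a VCF (via the vcfR package when installed), returning
#' one row per sample-variant call with `chrom`, `pos`, `ref`, `alt`,
#' `sample_id`, `gt`, and `gq`/`dp`/`ad_alt` when derivable from the FORMAT
#' fields. Genotypes are normalised to allele-count strings (`"0/1"` etc.,
#' phasing separators unified).
#'
#' @param path File path; format inferred from the extension (`.vcf` /
#'   `.vcf.gz` versus anything else) unless `format` is given.
#' @param format `"auto"`, `"tsv"` or `"vcf"`.
#' @return A tibble of calls.
#' @export
read_variant_table <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    out <- readr::read_tsv(path, show_col_types = FALSE)
    return(tibble::as_tibble(out))
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  base <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(base, tibble::as_tibble(gt, .name_repair = "minimal")),
    cols = -c("chrom", "pos", "ref", "alt"),
    names_to = "sample_id", values_to = "gt"
  )
  long$gt <- gsub("\\|", "/", long$gt)
  pull_num <- function(el) {
    m <- tryCatch(vcfR::extract.gt(v, element = el, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    as.numeric(t(m))
  }
  gq <- pull_num("GQ")
  dp <- pull_num("DP")
  if (!is.null(gq)) long$gq <- gq
  if (!is.null(dp)) long$dp <- dp
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  if (!is.null(ad)) {
    ad_flat <- as.character(t(ad))
    long$ad_alt <- suppressWarnings(
      as.numeric(purrr::map_chr(strsplit(ad_flat, ","), function(x) {
        if (length(x) >= 2) x[[2]] else NA_character_
      }))
    )
  }
  long
}

#' Write pipeline results
#'
#' Tables are written as TSV, scalar/list results as JSON (bare numbers).
#'
#' @param results Named list; data frames become `<name>.tsv`, everything
#'   else `<name>.json`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the written paths.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(results, function(x, nm) {
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      readr::write_tsv(x, p)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA)
    }
    p
  })
  invisible(paths)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates a cohort, computes sex-aware expected DNM counts, class-level
#' burden metrics for de novo (by sex) and case/control (male) views,
#' inheritance-model summaries (de novo share of the excess, Sherman
#' fraction at the configured fertility deficit, sex-bias of the observed
#' DNM excess), and per-gene discovery statistics. Deterministic given
#' `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   there via [write_results()] and [emit_cohort()].
#' @return A list with elements `simulate`, `filter`, `burden`,
#'   `inheritance`, `discover`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1,
                         out_dir = NULL) {
  cohort <- simulate_cohort(config, seed)
  params <- sex_rate_params(config$n_female_trios, config$n_male_trios,
                            config$alpha)
  expected <- expected_dnm_counts(cohort$gene_models, params)

  # --- filter stage: summarise the DNM table (already call-level clean in
  # simulation; mosaic flags are carried through as annotations)
  dnms <- cohort$dnms
  filter_summary <- dnms |>
    dplyr::count(.data$sex, .data$class, name = "observed")

  # --- burden stage
  exp_by <- expected |>
    dplyr::group_by(.data$sex, .data$class) |>
    dplyr::summarise(expected = sum(.data$expected), .groups = "drop")
  n_trio <- c(male = config$n_male_trios, female = config$n_female_trios)
  burden_dnm <- dplyr::left_join(exp_by, filter_summary,
                                 by = c("sex", "class")) |>
    dplyr::mutate(observed = dplyr::coalesce(.data$observed, 0L))
  burden_dnm <- purrr::pmap_dfr(burden_dnm, function(sex, class, expected,
                                                     observed) {
    dplyr::bind_cols(
      tibble::tibble(sex = sex, class = class),
      burden_metrics(observed, n_trio[[sex]], expected = expected)
    )
  })

  n_p <- config$n_male_trios + config$n_male_caseonly
  cc_counts <- function(tab, cl) {
    sum(tab$class %in% cl)
  }
  burden_cc <- purrr::map_dfr(
    list(ptv = "ptv", missense_inframe = "missense_inframe",
         synonymous = "synonymous"),
    function(cl) {
      burden_metrics(
        observed = cc_counts(cohort$probands, cl),
        n_probands = n_p,
        observed_fathers = cc_counts(cohort$fathers, cl),
        n_fathers = config$n_fathers
      )
    },
    .id = "class"
  )

  # --- inheritance stage
  obs_m <- sum(dnms$sex == "male" & dnms$class != "synonymous")
  obs_f <- sum(dnms$sex == "female" & dnms$class != "synonymous")
  emf <- expected_male_fraction(expected)$male_fraction
  sexbias <- sex_bias_test(obs_m, obs_f, emf)
  inheritance <- list(
    sherman_de_novo_fraction = sherman_fraction(
      config$m, config$fertility_f, config$nu_over_mu
    ),
    realised_de_novo_share = cohort$ground_truth$realised_de_novo_share,
    expected_male_dnm_fraction = emf,
    sex_bias = sexbias
  )

  # --- discovery stage
  dnm_counts <- dnms |>
    dplyr::count(.data$gene_id, .data$sex, .data$class, name = "count")
  inh_counts <- dplyr::full_join(
    cohort$probands |>
      dplyr::count(.data$gene_id, .data$class, name = "x_probands"),
    cohort$fathers |>
      dplyr::count(.data$gene_id, .data$class, name = "x_fathers"),
    by = c("gene_id", "class")
  ) |>
    dplyr::mutate(
      x_probands = dplyr::coalesce(.data$x_probands, 0L),
      x_fathers = dplyr::coalesce(.data$x_fathers, 0L)
    )
  discover <- run_gene_discovery(
    dnm_counts = dnm_counts,
    inherited_counts = inh_counts,
    expected = expected,
    n_probands = n_p,
    n_fathers = config$n_fathers
  )

  out <- list(
    simulate = cohort,
    filter = list(dnms = dnms, summary = filter_summary),
    burden = list(dnm = burden_dnm, case_control = burden_cc),
    inheritance = inheritance,
    discover = discover
  )
  if (!is.null(out_dir)) {
    emit_cohort(cohort, file.path(out_dir, "cohort"))
    write_results(
      list(
        filter_summary = filter_summary,
        burden_dnm = burden_dnm,
        burden_case_control = burden_cc,
        inheritance = inheritance,
        gene_results = discover
      ),
      out_dir
    )
  }
  out
}
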