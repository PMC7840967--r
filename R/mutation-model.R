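#' Sex-specific mutation-rate scaling parameters
#'
#' On the non-pseudoautosomal X, a male proband receives his single X from
#' his mother, while a female proband receives one X from each parent.
#' Because the paternal germline SNV mutation rate exceeds the maternal rate
#' by a factor `alpha`, per-transmission rates must be adjusted before
#' haploid mutation probabilities can be turned into expected de novo counts.
#' The adjustment factors are
#' `lambda_female = 2 / (1 + alpha)` and `lambda_male = 2 / (1 + 1/alpha)`,
#' which satisfy `lambda_female + lambda_male = 2` for every `alpha > 0`.
#'
#' @param n_female,n_male Numbers of female and male trio probands.
#' @param alpha Paternal:maternal SNV mutation-rate ratio (default 3.4,
#'   estimated from phased de novo mutations in the DDD cohort).
#' @return An object of class `sex_rate_params`: a list with `alpha`,
#'   `lambda_female`, `lambda_male`, `n_female`, `n_male`.
#' @export
#' @examples
#' p <- sex_rate_params(n_female = 3908, n_male = 5138)
#' p$lambda_female + p$lambda_male # exactly 2
sex_rate_params <- function(n_female, n_male, alpha = 3.4) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    abort("`alpha` must be a single positive number")
  }
  if (n_female < 0 || n_male < 0) abort("proband counts must be non-negative")
  structure(
    list(
      alpha = alpha,
      lambda_female = 2 / (1 + alpha),
      lambda_male = 2 / (1 + 1 / alpha),
      n_female = n_female,
      n_male = n_male
    ),
    class = "sex_rate_params"
  )
}

#' Cohort scaling factors for expected X-linked de novo counts
#'
#' Converts per-transmission adjustment factors into the multipliers applied
#' to haploid per-gene mutation probabilities. Female probands carry two X
#' transmissions (one maternal, one paternal), so
#' `f_females = n_female * (lambda_female + lambda_male) = 2 * n_female`;
#' male probands carry a single maternal transmission, so
#' `f_males = n_male * lambda_female`.
#'
#' @param params A [sex_rate_params()] object.
#' @return A one-row tibble with columns `f_females` and `f_males`.
#' @export
#' @examples
#' sex_scaling_factors(sex_rate_params(3908, 5138, alpha = 3.4))
sex_scaling_factors <- function(params) {
  stopifnot(inherits(params, "sex_rate_params"))
  tibble::tibble(
    f_females = params$n_female * (params$lambda_female + params$lambda_male),
    f_males = params$n_male * params$lambda_female
  )
}

# Printed coefficients of the logarithmic depth-calibration curve,
# ratio ~ a * ln(depth) + b, and the depth caps above which no correction
# is applied (males are hemizygous so saturate at lower coverage).
depth_curve_defaults <- function(sex) {
  switch(sex,
    male = list(a = 0.2778, b = 0.0279, cap = 30, bin_max = 40),
    female = list(a = 0.2464, b = 0.035, cap = 50, bin_max = 80),
    abort("`sex` must be 'male' or 'female'")
  )
}

#' Fit the depth-sensitivity calibration curve
#'
#' Sensitivity to call variants falls off at low coverage. The correction is
#' calibrated on rare synonymous variants: exons with mean-median depth of at
#' least 30 anchor a regression of observed synonymous counts on the
#' synonymous mutation probability (giving depth-uncorrected expectations),
#' then the ratio of observed to uncorrected-expected counts is computed in
#' 2x depth bins and a logarithmic curve `ratio ~ a * ln(depth) + b` is
#' fitted to the binned ratios.
#'
#' With no exon table the curve defaults to the fixed coefficients
#' (0.2778, 0.0279) for males and (0.2464, 0.035) for females.
#'
#' @param exon_table Optional per-exon tibble with columns `depth`
#'   (mean of per-sample median depths), `obs_syn` (observed rare synonymous
#'   count) and `p_syn` (haploid synonymous mutation probability). `NULL`
#'   requests the default coefficients.
#' @param sex `"male"` or `"female"`; sets the 2x binning range (up to 40x
#'   in males, 80x in females) and the default coefficients.
#' @return A list with coefficients `a` (slope on ln depth) and `b`
#'   (intercept).
#' @export
fit_depth_curve <- function(exon_table = NULL, sex = c("male", "female")) {
  sex <- match.arg(sex)
  def <- depth_curve_defaults(sex)
  if (is.null(exon_table)) {
    return(list(a = def$a, b = def$b))
  }
  stopifnot(all(c("depth", "obs_syn", "p_syn") %in% names(exon_table)))
  if (nrow(exon_table) == 0) abort("`exon_table` is empty")

  anchor <- dplyr::filter(exon_table, .data$depth >= 30)
  if (nrow(anchor) < 2) {
    abort("depth-curve calibration failure: fewer than 2 exons with depth >= 30")
  }
  # Depth-uncorrected expected count per exon is k * p_syn, with k the
  # through-the-origin regression slope on well-covered exons.
  k <- coef(lm(obs_syn ~ p_syn - 1, data = anchor))[["p_syn"]]

  binned <- exon_table |>
    dplyr::filter(.data$depth >= 1, .data$depth <= def$bin_max) |>
    dplyr::mutate(bin = floor(.data$depth / 2) * 2 + 1) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      ratio = sum(.data$obs_syn) / (k * sum(.data$p_syn)),
      .groups = "drop"
    ) |>
    dplyr::filter(is.finite(.data$ratio))
  if (nrow(binned) < 2) {
    abort("depth-curve calibration failure: fewer than 2 usable depth bins")
  }
  fit <- lm(ratio ~ log(bin), data = binned)
  list(a = unname(coef(fit)[["log(bin)"]]), b = unname(coef(fit)[["(Intercept)"]]))
}

#' Depth-adjust an expected variant count
#'
#' Applies the piecewise calibration: an expected count at depth below 1x is
#' zeroed (no sensitivity); between 1x and the sex-specific cap (30x in
#' males, 50x in females) it is multiplied by `a * ln(depth) + b`; at or
#' above the cap it is returned unchanged. Note the curve does not reach 1
#' at the cap (0.2778 ln 30 + 0.0279 = 0.973 in males): the discontinuity is
#' part of the published calibration and is reproduced as printed.
#'
#' @param expected Non-negative expected count (vectorised).
#' @param depth Non-negative sequencing depth (vectorised).
#' @param sex `"male"` or `"female"`.
#' @param coefs Optional list with `a` and `b` overriding the defaults,
#'   e.g. from [fit_depth_curve()].
#' @return Adjusted expected counts, never negative.
#' @export
#' @examples
#' depth_adjust(1, 10, "male") # 0.2778 * log(10) + 0.0279
#' depth_adjust(1, 60, "female") # above cap: unchanged
depth_adjust <- function(expected, depth, sex = c("male", "female"),
                         coefs = NULL) {
  sex <- match.arg(sex)
  if (any(expected < 0, na.rm = TRUE) || any(depth < 0, na.rm = TRUE)) {
    abort("`expected` and `depth` must be non-negative")
  }
  def <- depth_curve_defaults(sex)
  a <- (coefs %||% def)$a
  b <- (coefs %||% def)$b
  n <- max(length(expected), length(depth))
  expected <- rep_len(expected, n)
  depth <- rep_len(depth, n)
  out <- expected
  low <- depth < 1
  mid <- depth >= 1 & depth < def$cap
  out[low] <- 0
  out[mid] <- expected[mid] * (a * log(depth[mid]) + b)
  pmax(out, 0)
}

#' Expected de novo mutation counts per gene, sex and consequence class
#'
#' Multiplies the cohort scaling factors by the depth-adjusted haploid
#' mutation probabilities to give expected de novo counts for each gene,
#' sex and consequence class.
#'
#' @param genes Gene model tibble with columns `gene_id`, `p_syn`, `p_mis`,
#'   `p_ptv` (haploid per-generation mutation probabilities), `depth_male`,
#'   `depth_female` (mean of per-exon median depths). Extra columns are
#'   ignored. See [read_gene_models()].
#' @param params A [sex_rate_params()] object.
#' @param classes Consequence classes to compute; any of `"synonymous"`,
#'   `"missense_inframe"`, `"ptv"`.
#' @param depth_correct Apply the depth calibration (default `TRUE`).
#' @return A tibble with columns `gene_id`, `sex`, `class`, `expected`.
#' @export
expected_dnm_counts <- function(genes, params,
                                classes = c("synonymous", "missense_inframe", "ptv"),
                                depth_correct = TRUE) {
  stopifnot(inherits(params, "sex_rate_params"))
  class_cols <- c(
    synonymous = "p_syn", missense_inframe = "p_mis", ptv = "p_ptv"
  )
  classes <- match.arg(classes, several.ok = TRUE)
  if (nrow(genes) == 0) {
    return(tibble::tibble(
      gene_id = character(), sex = character(),
      class = character(), expected = double()
    ))
  }
  missing_cols <- setdiff(unname(class_cols[classes]), names(genes))
  if (length(missing_cols)) {
    abort(paste0("missing mutation-rate column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in class_cols[classes]) {
    if (any(is.na(genes[[col]]))) {
      bad <- genes$gene_id[is.na(genes[[col]])]
      abort(paste0("missing ", col, " rate for gene(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  sf <- sex_scaling_factors(params)

  long <- genes |>
    dplyr::select("gene_id", dplyr::all_of(unname(class_cols[classes])),
                  dplyr::any_of(c("depth_male", "depth_female"))) |>
    tidyr::pivot_longer(
      dplyr::all_of(unname(class_cols[classes])),
      names_to = "rate_col", values_to = "p"
    ) |>
    dplyr::mutate(class = names(class_cols)[match(.data$rate_col, class_cols)])

  per_sex <- function(sex_label, factor, depth_col) {
    depth <- if (depth_col %in% names(long)) long[[depth_col]] else Inf
    p_adj <- if (depth_correct) {
      depth_adjust(long$p, depth, sex_label)
    } else {
      long$p
    }
    tibble::tibble(
      gene_id = long$gene_id, sex = sex_label, class = long$class,
      expected = factor * p_adj
    )
  }
  dplyr::bind_rows(
    per_sex("female", sf$f_females, "depth_female"),
    per_sex("male", sf$f_males, "depth_male")
  ) |>
    dplyr::arrange(.data$gene_id, .data$sex, .data$class)
}

#' Expected male share of de novo mutations
#'
#' The expected fraction of DNMs occurring in males, per gene or aggregated,
#' is `E_male / (E_male + E_female)` where the expectations incorporate
#' coverage, ploidy and the paternal:maternal rate ratio. Its complement is
#' the expected female share. Used as the null proportion of the per-gene
#' sex-bias binomial test.
#'
#' @param expected Expected-count tibble from [expected_dnm_counts()]
#'   (columns `gene_id`, `sex`, `class`, `expected`).
#' @param by_gene If `TRUE`, return one row per gene; otherwise a single
#'   aggregate over all genes supplied.
#' @param classes Consequence classes to include (default damaging classes,
#'   PTV plus missense/inframe).
#' @return A tibble with column `male_fraction` (plus `gene_id` when
#'   `by_gene = TRUE`).
#' @export
expected_male_fraction <- function(expected, by_gene = FALSE,
                                   classes = c("ptv", "missense_inframe")) {
  dat <- dplyr::filter(expected, .data$class %in% classes)
  grp <- if (by_gene) dplyr::group_by(dat, .data$gene_id) else dat
  out <- grp |>
    dplyr::summarise(
      e_male = sum(.data$expected[.data$sex == "male"]),
      e_female = sum(.data$expected[.data$sex == "female"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(male_fraction = .data$e_male / (.data$e_male + .data$e_female))
  if (any(!is.finite(out$male_fraction))) {
    abort("expected male fraction undefined: zero total expected count")
  }
  dplyr::select(out, dplyr::any_of("gene_id"), "male_fraction")
}

#' Read a gene-model table
#'
#' Tab-separated with header columns `gene_id`, `p_syn`, `p_mis`, `p_ptv`,
#' `depth_male`, `depth_female`, `known_dd`, `inheritance_class`.
#'
#' @param path File path.
#' @return A tibble; `known_dd` is logical and `inheritance_class` one of
#'   `"XLR"`, `"XLD"`, `"both_or_uncertain"`.
#' @export
read_gene_models <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("gene_id", "p_syn", "p_mis", "p_ptv",
                "depth_male", "depth_female")
  missing_cols <- setdiff(required, names(g))
  if (length(missing_cols)) {
    abort(paste0("gene model table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if ("known_dd" %in% names(g)) g$known_dd <- as.logical(g$known_dd)
  if ("inheritance_class" %in% names(g)) {
    ok <- g$inheritance_class %in% c("XLR", "XLD", "both_or_uncertain")
    if (!all(ok)) abort("invalid inheritance_class values")
  }
  g
}
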