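# A small, fast cohort configuration shared across tests.
small_config <- function(...) {
  cohort_config(
    n_genes = 40, n_male_trios = 300, n_female_trios = 250,
    n_male_caseonly = 100, n_fathers = 400,
    n_xlr = 4, n_xld = 2, n_semidom = 1,
    target_syn_female = 5, ...
  )
}

# A three-gene model table with depths above both caps so the depth
# adjustment is the identity and expectations can be computed by hand.
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("GA", "GB", "GC"),
    p_syn = c(2e-6, 4e-6, 1e-6),
    p_mis = c(5e-6, 8e-6, 3e-6),
    p_ptv = c(1e-6, 2e-6, 5e-7),
    depth_male = c(35, 40, 33),
    depth_female = c(55, 60, 52)
  )
}
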