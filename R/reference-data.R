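# Bundled reference datasets (plain CSV under inst/extdata).

#' Reported placental clonality summary statistics
#'
#' Group-level summaries of placental allelic-score distributions reported
#' for a cohort of in vitro and in vivo conceived newborns: the mean and
#' dispersion (SD for the X-inactivation assay, variance for the IGF2/H19
#' M/P methylation assay) of scores pooled over five placenta sections per
#' individual, together with the per-cell probability `p` each assay
#' assumes. Feeding each row's dispersion into [moment_n()] reproduces the
#' reported founder stem-cell counts.
#'
#' @return A tibble with columns `assay`, `tissue_class`, `group`,
#'   `n_individuals`, `n_sections`, `mean`, `dispersion`,
#'   `dispersion_type`, `p`.
#' @export
reference_clonality_summary <- function() {
  readr::read_csv(
    system.file("extdata", "placenta_clonality_summary.csv",
                package = "epifounder", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Reported allelic expression percentages
#'
#' Minor-allele expression percentages (maternal IGF2 or paternal H19
#' transcript share) measured in placenta samples with non-zero maternal
#' IGF2/H19 DMR methylation, from the same cohort as
#' [reference_clonality_summary()]. Applying [classify_loi()] to these
#' percentages tests the observation that biallelic DMR methylation did not
#' disrupt monoallelic expression (no value reaches the 3:1 biallelic
#' threshold).
#'
#' @return A tibble with columns `group`, `mp_ratio`, `gene`,
#'   `minor_allele_pct`.
#' @export
reference_allelic_expression <- function() {
  readr::read_csv(
    system.file("extdata", "allelic_expression_ratios.csv",
                package = "epifounder", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}
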