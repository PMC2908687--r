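# Relative expression quantification by the delta-delta-Ct method.

#' Delta-delta-Ct fold change between conception groups
#'
#' Computes the relative expression of a target gene in the in vitro group
#' compared with the in vivo (reference) group:
#' per sample `dCt = Ct(target) - Ct(housekeeping)`;
#' `ddCt = mean dCt(in vitro) - mean dCt(in vivo)`; fold change
#' `2^(-ddCt)`. The p-value is a two-sided Welch t-test on the per-sample
#' `dCt` values.
#'
#' @param ct_records A Ct table (see [read_ct_table()]): columns
#'   `individual_id`, `group`, `tissue`, `gene`, `ct`.
#' @param target_gene Target gene name.
#' @param housekeeping_gene Housekeeping gene name (default `"GAPDH"`).
#'   Samples without a housekeeping measurement are dropped with a warning.
#' @param tissues Optional tissue labels to restrict to (e.g. the placenta
#'   sections); default uses all rows.
#' @param reference_group The denominator group (default `"in_vivo"`).
#' @return A one-row tibble: `gene`, `tissue`, `n_in_vitro`, `n_in_vivo`,
#'   `fold_change`, `p_value`. `p_value` is `NA` (with a warning) when the
#'   per-sample dCt values carry no variation, as when the target is tested
#'   against itself.
#' @export
ddct <- function(ct_records, target_gene, housekeeping_gene = "GAPDH",
                 tissues = NULL, reference_group = "in_vivo") {
  ct_records <- validate_ct(ct_records)
  if (!reference_group %in% ef_groups()) {
    abort(paste0("`reference_group` must be one of: ",
                 paste(ef_groups(), collapse = ", ")))
  }
  if (!is.null(tissues)) {
    ct_records <- ct_records |> dplyr::filter(.data$tissue %in% tissues)
  }

  target <- ct_records |> dplyr::filter(.data$gene == target_gene)
  hk <- ct_records |>
    dplyr::filter(.data$gene == housekeeping_gene) |>
    dplyr::select("individual_id", "group", "tissue", hk_ct = "ct")
  if (nrow(target) == 0) abort(sprintf("no Ct records for gene %s", target_gene))
  if (nrow(hk) == 0) {
    abort(sprintf("no Ct records for housekeeping gene %s", housekeeping_gene))
  }

  joined <- target |>
    dplyr::inner_join(hk, by = c("individual_id", "group", "tissue")) |>
    dplyr::mutate(dct = .data$ct - .data$hk_ct)
  n_dropped <- nrow(target) - nrow(joined)
  if (n_dropped > 0) {
    warn(sprintf("%d sample(s) without a %s measurement dropped",
                 n_dropped, housekeeping_gene))
  }

  by_group <- split(joined$dct, joined$group)
  if (length(by_group) < 2 || any(lengths(by_group) < 2)) {
    abort("need at least 2 samples with both genes in each group")
  }
  other_group <- setdiff(ef_groups(), reference_group)
  ddct_value <- mean(by_group[[other_group]]) - mean(by_group[[reference_group]])

  if (var(joined$dct) == 0) {
    warn("per-sample dCt values carry no variation; p-value undefined")
    p <- NA_real_
  } else {
    p <- t.test(by_group[[other_group]], by_group[[reference_group]])$p.value
  }

  tibble(
    gene = target_gene,
    tissue = if (is.null(tissues)) "all" else paste(unique(ef_tissue_class(tissues)), collapse = "+"),
    n_in_vitro = length(by_group[["in_vitro"]]),
    n_in_vivo = length(by_group[["in_vivo"]]),
    fold_change = 2^(-ddct_value),
    p_value = p
  )
}

#' Fold-change table across genes and tissue classes
#'
#' Applies [ddct()] to every combination of target gene and tissue class
#' present in a Ct table, producing the machine-readable twin of a
#' transcript-level comparison table.
#'
#' @inheritParams ddct
#' @param targets Target genes (default: every gene except the
#'   housekeeping gene).
#' @return A tibble with one row per (tissue class, gene).
#' @export
ddct_table <- function(ct_records, targets = NULL,
                       housekeeping_gene = "GAPDH",
                       reference_group = "in_vivo") {
  ct_records <- validate_ct(ct_records)
  targets <- targets %||%
    setdiff(unique(ct_records$gene), housekeeping_gene)
  classes <- unique(ef_tissue_class(ct_records$tissue))
  purrr::map(classes, function(cl) {
    tis <- unique(ct_records$tissue[ef_tissue_class(ct_records$tissue) == cl])
    purrr::map(targets, function(g) {
      ddct(ct_records, g, housekeeping_gene = housekeeping_gene,
           tissues = tis, reference_group = reference_group)
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()
}
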