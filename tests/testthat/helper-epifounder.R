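# Builders for small in-memory fixtures.

make_intensity_tbl <- function() {
  # ind1: allele "C" is the weaker (less methylated) band overall, but one
  # placenta section has it stronger, so its ratio exceeds 1.
  tibble::tibble(
    individual_id = c(rep("ind1", 3), rep("ind2", 2), "ind3"),
    group = c(rep("in_vitro", 3), rep("in_vivo", 2), "in_vivo"),
    tissue = c("cord_blood", "placenta_1", "placenta_2",
               "cord_blood", "placenta_1", "placenta_1"),
    locus = c(rep("IGF2_H19", 5), "AR"),
    allele_a_label = c(rep("C", 5), "upper"),
    allele_b_label = c(rep("T", 5), "lower"),
    intensity_a = c(100, 50, 660, 900, 800, 300),
    intensity_b = c(1000, 1000, 600, 90, 100, 100)
  )
}

make_ratio_tbl <- function(values, group = "in_vivo", score_kind = "MP",
                           tissue = "placenta_1") {
  n <- length(values)
  tibble::tibble(
    individual_id = sprintf("i%03d", seq_len(n)),
    group = rep_len(group, n),
    tissue = rep_len(tissue, n),
    locus = dplyr::case_match(rep_len(score_kind, n),
                              "MP" ~ "IGF2_H19", "PM" ~ "IGF2R", "XI" ~ "AR"),
    score_kind = rep_len(score_kind, n),
    value = values
  )
}

make_ct_tbl <- function(dct_a, dct_b, gene = "IGF2", tissue = "placenta_1") {
  # builds matched target + GAPDH records with the given per-sample dCt
  hk <- 20
  build <- function(dct, group, prefix) {
    n <- length(dct)
    ids <- sprintf("%s%03d", prefix, seq_len(n))
    dplyr::bind_rows(
      tibble::tibble(individual_id = ids, group = group, tissue = tissue,
                     gene = gene, ct = hk + dct),
      tibble::tibble(individual_id = ids, group = group, tissue = tissue,
                     gene = "GAPDH", ct = hk)
    )
  }
  dplyr::bind_rows(build(dct_a, "in_vitro", "a"), build(dct_b, "in_vivo", "b"))
}
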