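# Scalar allelic scores computed from densitometry band intensities.
#
# All intensities are net signals in arbitrary densitometry units; background
# subtraction is assumed to have happened upstream in the imaging software.

#' Allelic methylation ratio
#'
#' Ratio of the band intensity of a designated numerator allele to that of the
#' reference allele after methylation-sensitive digestion and hot-stop PCR.
#' For a maternally unmethylated imprint control region (e.g. the IGF2/H19
#' DMR) the numerator is the maternal allele and the score is the M/P ratio:
#' 0 means the queried CpG is methylated exclusively on the paternal allele,
#' 1 means it is methylated on an equal number of maternal and paternal
#' alleles. For a maternally methylated DMR (e.g. IGF2R) the roles are
#' reversed and the score is the P/M ratio. Values above 1 (numerator allele
#' more methylated than the reference) are preserved, not clipped.
#'
#' @param numerator_intensity,denominator_intensity Non-negative band
#'   intensities (arbitrary units). Vectorised.
#' @return Numeric vector of ratios, `numerator / denominator`.
#' @examples
#' allelic_ratio(0, 1000)     # exclusive reference-allele methylation
#' allelic_ratio(500, 500)    # equal allelic methylation
#' @export
allelic_ratio <- function(numerator_intensity, denominator_intensity) {
  check_intensity(numerator_intensity, "numerator_intensity")
  check_intensity(denominator_intensity, "denominator_intensity")
  if (any(denominator_intensity == 0)) {
    abort("reference allele signal absent (denominator intensity is zero)")
  }
  numerator_intensity / denominator_intensity
}

#' X-inactivation skew score
#'
#' Degree of X-chromosome inactivation skewing from a methylation-sensitive
#' PCR assay at a polymorphic X-linked locus (HUMARA-style): the intensity of
#' the upper gel allele divided by the summed intensity of both alleles.
#' 0.5 is balanced inactivation; 0 and 1 are complete skewing. The score is
#' not reflected about 0.5, so `xi_score(a, b) + xi_score(b, a) == 1`.
#'
#' @param upper_intensity,lower_intensity Non-negative band intensities of
#'   the upper and lower allele. Vectorised.
#' @return Numeric vector in \[0, 1\].
#' @export
xi_score <- function(upper_intensity, lower_intensity) {
  check_intensity(upper_intensity, "upper_intensity")
  check_intensity(lower_intensity, "lower_intensity")
  total <- upper_intensity + lower_intensity
  if (any(total == 0)) {
    abort("both allele intensities are zero; skew score undefined")
  }
  upper_intensity / total
}

#' Digestion-efficiency control
#'
#' Evaluates the homozygote cleavage control of a methylation-sensitive
#' restriction assay: in individuals homozygous for the cleavable allele, any
#' residual uncleaved signal measures incomplete digestion. The assay is
#' accepted when the cleaved fraction reaches the threshold (default 0.99,
#' i.e. >99% cleavage).
#'
#' @param uncleaved_intensity,cleaved_intensity Non-negative band intensities.
#' @param threshold Minimum acceptable cleaved fraction, in \[0, 1\].
#' @return A one-row tibble with columns `efficiency`, `passed`, `threshold`.
#' @export
digestion_efficiency <- function(uncleaved_intensity, cleaved_intensity,
                                 threshold = 0.99) {
  check_intensity(uncleaved_intensity, "uncleaved_intensity")
  check_intensity(cleaved_intensity, "cleaved_intensity")
  stopifnot(length(threshold) == 1, threshold >= 0, threshold <= 1)
  total <- uncleaved_intensity + cleaved_intensity
  if (any(total == 0)) {
    abort("both intensities are zero; digestion efficiency undefined")
  }
  efficiency <- cleaved_intensity / total
  tibble(
    efficiency = efficiency,
    passed = efficiency >= threshold,
    threshold = threshold
  )
}

#' Predicted total methylation from an M/P ratio
#'
#' Consistency prediction linking the allelic ratio assay to bisulfite
#' pyrosequencing: if all paternal alleles are methylated and a fraction
#' `m = M/P` of maternal alleles is also methylated, the fraction of all
#' molecules that are methylated is `(1 + m) / 2`. Any non-negative M/P ratio
#' therefore predicts at least 50% total methylation at the queried CpGs.
#'
#' @param mp_ratio M/P methylation ratio in \[0, 1\]. Vectorised.
#' @return Numeric vector in \[0.5, 1\].
#' @export
predicted_total_methylation <- function(mp_ratio) {
  if (!is.numeric(mp_ratio) || any(!is.finite(mp_ratio))) {
    abort("`mp_ratio` must be finite numeric")
  }
  if (any(mp_ratio < 0 | mp_ratio > 1)) {
    abort("`mp_ratio` must lie in [0, 1]; the biallelic-methylation model is undefined outside it")
  }
  (1 + mp_ratio) / 2
}

#' Loss-of-imprinting call from allelic expression intensities
#'
#' Classifies a transcript as showing loss of imprinting (biallelic
#' expression) when the ratio between the more-abundant and less-abundant
#' allele falls below 3:1 (strict inequality: exactly 3:1 is not called).
#' The call is insensitive to argument order and to common scaling of the
#' two intensities; a silent minor allele is never LOI.
#'
#' @param major_allele_intensity,minor_allele_intensity Non-negative allele
#'   signal intensities (swapped internally if given in the wrong order).
#'   Vectorised.
#' @param threshold Ratio below which biallelic expression is called
#'   (default 3).
#' @return Logical vector: `TRUE` = loss of imprinting.
#' @examples
#' classify_loi(600, 400)   # 1.5:1  -> TRUE
#' classify_loi(750, 250)   # 3:1    -> FALSE (strict)
#' @export
classify_loi <- function(major_allele_intensity, minor_allele_intensity,
                         threshold = 3) {
  check_intensity(major_allele_intensity, "major_allele_intensity")
  check_intensity(minor_allele_intensity, "minor_allele_intensity")
  major <- pmax(major_allele_intensity, minor_allele_intensity)
  minor <- pmin(major_allele_intensity, minor_allele_intensity)
  if (any(major == 0)) {
    abort("both allele intensities are zero; expression call undefined")
  }
  ifelse(minor == 0, FALSE, major / minor < threshold)
}

#' Compute allelic scores from an intensity table
#'
#' Converts a table of per-sample allele band intensities into the scalar
#' scores used downstream. The score kind is chosen by locus:
#'
#' * `IGF2_H19` -> `MP` (maternal/paternal methylation ratio),
#' * `IGF2R` -> `PM` (paternal/maternal methylation ratio),
#' * `AR` -> `XI` (X-inactivation skew, `intensity_a / (intensity_a + intensity_b)`
#'   with allele a taken as the upper gel allele).
#'
#' Parental origin is not observed (no parental DNA); following the standard
#' assumption for these DMRs, the *less methylated* allele of each individual
#' is designated maternal at IGF2_H19 and paternal at IGF2R. The designation
#' is made once per individual and locus, from the allele label with the
#' smaller mean intensity share across that individual's samples, so
#' individual tissue samples may still yield ratios above 1. The result
#' carries an `origin_assumed` attribute recording that this is an
#' assumption, not an inference.
#'
#' @param measurements A data frame with columns `individual_id`, `group`,
#'   `tissue`, `locus`, `allele_a_label`, `allele_b_label`, `intensity_a`,
#'   `intensity_b` (the intensity-table dialect of [read_intensity_table()]).
#' @return A tibble with columns `individual_id`, `group`, `tissue`, `locus`,
#'   `score_kind`, `value` (the ratio-table dialect).
#' @export
compute_ratios <- function(measurements) {
  measurements <- validate_intensity(measurements)
  if (any(measurements$intensity_a + measurements$intensity_b == 0)) {
    abort("rows with both allele intensities zero cannot be scored")
  }

  scored <- measurements |>
    dplyr::group_by(.data$individual_id, .data$locus) |>
    dplyr::mutate(
      .share_a = mean(.data$intensity_a /
                        (.data$intensity_a + .data$intensity_b))
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      score_kind = dplyr::case_match(
        .data$locus,
        "IGF2_H19" ~ "MP",
        "IGF2R" ~ "PM",
        "AR" ~ "XI"
      ),
      # numerator = the allele designated as less methylated for this
      # individual (maternal at IGF2_H19, paternal at IGF2R)
      .num = ifelse(.data$.share_a <= 0.5, .data$intensity_a, .data$intensity_b),
      .den = ifelse(.data$.share_a <= 0.5, .data$intensity_b, .data$intensity_a),
      value = dplyr::if_else(
        .data$score_kind == "XI",
        .data$intensity_a / (.data$intensity_a + .data$intensity_b),
        .data$.num / .data$.den
      )
    )

  if (any(scored$score_kind != "XI" & scored$.den == 0)) {
    abort("reference allele signal absent (denominator intensity is zero)")
  }

  out <- scored |>
    dplyr::select("individual_id", "group", "tissue", "locus",
                  "score_kind", "value")
  attr(out, "origin_assumed") <- TRUE
  out
}

check_intensity <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(paste0("`", name, "` must be finite numeric"))
  }
  if (any(x < 0)) {
    abort(paste0("`", name, "` must be non-negative (densitometry signal)"))
  }
  invisible(x)
}
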