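# Between-group comparisons: rank-sum location tests, variance-equality
# tests, group summary tables, and delta-delta-Ct fold changes.

#' Wilcoxon rank-sum test
#'
#' Two-sided two-sample rank-sum test. `exact` mode enumerates every
#' assignment of the combined midranks to the first group and reports the
#' probability of a rank sum at least as far from its null expectation as
#' the observed one (the rank-sum null distribution is symmetric, so this
#' equals the doubled tail). `normal_approx` uses the tie-corrected normal
#' approximation with continuity correction (via [stats::wilcox.test()]).
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param mode `"auto"` (exact when the combined n is at most 20),
#'   `"exact"`, or `"normal_approx"`.
#' @return A one-row tibble with `statistic` (rank sum of `a`), `p_value`
#'   and `method`. If every value is identical across both groups the test
#'   is vacuous: `p_value = 1` with a warning.
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 1, length(b) >= 1,
            all(is.finite(a)), all(is.finite(b)))
  n_a <- length(a)
  n <- n_a + length(b)
  if (mode == "auto") mode <- if (n <= 20) "exact" else "normal_approx"
  if (mode == "exact" && n > 20) {
    abort("exact mode is limited to a combined sample size of 20")
  }

  r <- rank(c(a, b))
  w <- sum(r[seq_len(n_a)])
  if (length(unique(c(a, b))) == 1) {
    warn("all values identical across both groups; rank-sum test is vacuous")
    return(tibble(statistic = w, p_value = 1, method = mode))
  }

  if (mode == "exact") {
    sums <- colSums(matrix(r[combn(n, n_a)], nrow = n_a))
    mu <- n_a * (n + 1) / 2
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
  }
  tibble(statistic = w, p_value = p, method = mode)
}

#' Variance-equality test
#'
#' Two-sided test of equal variances between two groups.
#' `levene_median` (the Brown–Forsythe variant of Levene's test, on absolute
#' deviations from the group medians) is the default for robustness to the
#' skewed ratio distributions this package deals in; `f_test` is the
#' classical normal-theory variance-ratio test.
#'
#' @param a,b Numeric vectors (each with at least 3 values).
#' @param method `"levene_median"` or `"f_test"`.
#' @return A one-row tibble with `statistic`, `p_value`, `method`.
#' @export
variance_equality_test <- function(a, b, method = c("levene_median", "f_test")) {
  method <- match.arg(method)
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 3, length(b) >= 3,
            all(is.finite(a)), all(is.finite(b)))
  dev_a <- abs(a - median(a))
  dev_b <- abs(b - median(b))
  if (all(dev_a == 0) && all(dev_b == 0)) {
    abort("degenerate: no within-group deviation in either group")
  }

  if (method == "levene_median") {
    g <- factor(rep(c("a", "b"), c(length(a), length(b))))
    res <- car::leveneTest(c(a, b), g, center = median)
    statistic <- res[["F value"]][1]
    p <- res[["Pr(>F)"]][1]
    if (!is.finite(statistic)) { # identical deviation sets in both groups
      statistic <- 0
      p <- 1
    }
  } else {
    res <- var.test(a, b)
    statistic <- unname(res$statistic)
    p <- res$p.value
  }
  tibble(statistic = statistic, p_value = p, method = method)
}

#' Group summary table of allelic scores
#'
#' Builds the per-tissue and pooled summary of one score kind: for each
#' tissue set and conception group, the score mean, variance and sample
#' count, together with a rank-sum test on the group means (`p_means`) and a
#' variance-equality test (`p_variances`). The default tissue sets are
#' cord blood, cord, the five placenta sections pooled, and a "total" row
#' pooling every sample.
#'
#' @param ratios A ratio table (see [compute_ratios()]).
#' @param assay `"MP"`, `"PM"` or `"XI"`.
#' @param tissue_sets Named list of tissue-label vectors; each entry becomes
#'   one summary block.
#' @param var_method Variance-equality test passed to
#'   [variance_equality_test()].
#' @param ddof Variance denominator offset.
#' @return A tibble with one row per (tissue set, group): `tissue_set`,
#'   `group`, `n`, `mean`, `variance`, `p_means`, `p_variances`. Test
#'   p-values are `NA` when only one group is present; empty cells are
#'   omitted with a warning.
#' @export
summarize_groups <- function(ratios, assay = c("MP", "PM", "XI"),
                             tissue_sets = NULL,
                             var_method = c("levene_median", "f_test"),
                             ddof = 1) {
  assay <- match.arg(assay)
  var_method <- match.arg(var_method)
  ratios <- validate_ratio(ratios)
  if (is.null(tissue_sets)) {
    tissue_sets <- list(
      cord_blood = "cord_blood",
      cord = "cord",
      placenta = ef_placenta_tissues(),
      total = ef_tissues()
    )
  }

  selected <- ratios |> dplyr::filter(.data$score_kind == assay)
  purrr::imap(tissue_sets, function(tset, set_name) {
    cell <- selected |> dplyr::filter(.data$tissue %in% tset)
    if (nrow(cell) == 0) {
      warn(sprintf("tissue set '%s': no %s records; row omitted",
                   set_name, assay))
      return(NULL)
    }
    by_group <- split(cell$value, cell$group)
    p_means <- NA_real_
    p_variances <- NA_real_
    if (length(by_group) == 2 && all(lengths(by_group) >= 3)) {
      p_means <- wilcoxon_rank_sum(by_group[[1]], by_group[[2]],
                                   mode = "normal_approx")$p_value
      p_variances <- variance_equality_test(by_group[[1]], by_group[[2]],
                                            method = var_method)$p_value
    }
    cell |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data$value),
        variance = sample_variance(.data$value, ddof = ddof),
        .groups = "drop"
      ) |>
      dplyr::mutate(tissue_set = set_name, p_means = p_means,
                    p_variances = p_variances) |>
      dplyr::select("tissue_set", "group", "n", "mean", "variance",
                    "p_means", "p_variances")
  }) |>
    dplyr::bind_rows()
}
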