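# ggplot2 figures for the main result types.

#' Plot a founder_fit: empirical scores vs fitted binomial distribution
#'
#' Histogram of the pooled allelic scores per group with the fitted
#' founder-fraction distribution (`k / n_fit` masses) overlaid, the visual
#' analogue of comparing an observed X-inactivation or methylation-ratio
#' distribution with its closest binomial fit.
#'
#' @param object A `founder_fit` from [estimate_founders()].
#' @param bins Number of histogram bins (default 10, the fitting default).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot founder_fit
#' @export
autoplot.founder_fit <- function(object, bins = 10, ...) {
  scores <- attr(object, "scores")
  emp <- purrr::imap(scores, function(v, g) tibble(group = g, value = v)) |>
    dplyr::bind_rows()
  est <- tidy(object)
  fitted <- est |>
    dplyr::filter(!is.na(.data$n_fit)) |>
    dplyr::rowwise() |>
    dplyr::reframe(group = .data$group,
                   binomial_score_pmf(.data$n_fit, .data$p))

  p <- ggplot2::ggplot(emp, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      breaks = seq(0, 1, length.out = bins + 1),
      fill = "grey70", colour = "white"
    ) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(
      x = sprintf("%s score", est$assay[1]),
      y = "Density",
      title = sprintf("Observed %s scores and fitted founder distribution",
                      est$assay[1]),
      subtitle = paste(
        sprintf("%s: N_moment = %.2f, N_fit = %s", est$group,
                est$n_moment, est$n_fit),
        collapse = "; "
      )
    )
  if (nrow(fitted) > 0) {
    p <- p + ggplot2::geom_segment(
      data = fitted,
      ggplot2::aes(x = .data$score, xend = .data$score,
                   y = 0, yend = .data$mass * bins),
      colour = "firebrick", linewidth = 0.7
    )
  }
  p
}

#' Histogram of allelic scores by group
#'
#' @param ratios A ratio table.
#' @param assay `"MP"`, `"PM"` or `"XI"`.
#' @param tissues Tissue labels to include (default: the five placenta
#'   sections).
#' @param bins Number of bins.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(ratios, assay = c("MP", "PM", "XI"),
                                    tissues = ef_placenta_tissues(),
                                    bins = 10) {
  assay <- match.arg(assay)
  ratios <- validate_ratio(ratios)
  dat <- ratios |>
    dplyr::filter(.data$score_kind == assay, .data$tissue %in% tissues)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, length.out = bins + 1),
                            position = "identity", alpha = 0.5) +
    ggplot2::labs(x = sprintf("%s score", assay), y = "Samples",
                  fill = "Group")
}

#' Fold-change dot plot
#'
#' @param fold_changes Output of [ddct_table()].
#' @return A ggplot object with one point per gene and tissue, on a log2
#'   fold-change axis; the dashed line marks no change.
#' @export
plot_fold_changes <- function(fold_changes) {
  ggplot2::ggplot(
    fold_changes,
    ggplot2::aes(x = .data$gene, y = .data$fold_change,
                 colour = .data$p_value < 0.05)
  ) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(y = "Fold change (in vitro / in vivo)", x = NULL,
                  colour = "P < 0.05")
}
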