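# broom-style accessors for fitted objects.

#' Tidy a founder_fit
#'
#' @param x A `founder_fit` from [estimate_founders()].
#' @param ... Unused.
#' @return A plain tibble with one row per group.
#' @method tidy founder_fit
#' @export
tidy.founder_fit <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "scores") <- NULL
  class(out) <- class(tibble())
  out
}

#' One-row summary of a founder_fit
#'
#' @param x A `founder_fit` from [estimate_founders()].
#' @param ... Unused.
#' @return A one-row tibble: assay, number of groups, total samples, fit
#'   metric, and the ratio of the in vitro to the in vivo moment estimate
#'   when both groups are present.
#' @method glance founder_fit
#' @export
glance.founder_fit <- function(x, ...) {
  tbl <- tidy(x)
  ratio <- if (all(ef_groups() %in% tbl$group)) {
    tbl$n_moment[tbl$group == "in_vitro"] /
      tbl$n_moment[tbl$group == "in_vivo"]
  } else {
    NA_real_
  }
  tibble(
    assay = tbl$assay[1],
    n_groups = nrow(tbl),
    n_samples = sum(tbl$n_samples),
    fit_metric = tbl$fit_metric[1],
    moment_ratio_vitro_vivo = ratio
  )
}
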