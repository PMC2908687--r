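# Founder (stem) cell number estimation from the variance of allelic scores.
#
# Model: a tissue descends from N founder cells whose epiallele states are
# independent Bernoulli(p) trials (p = 0.5 for which X is inactivated,
# p ~= 0.1 for maternal methylation at the IGF2/H19 DMR). The tissue-level
# score is the founder fraction k/N with k ~ Binomial(N, p), so
# Var(score) = p(1-p)/N and N can be estimated from the observed variance
# (moment matching) or by fitting the discrete score distribution directly.

#' Sample variance with configurable denominator
#'
#' @param values Numeric vector (at least 2 values, and more than `ddof`).
#' @param ddof Delta degrees of freedom: the divisor is `n - ddof`.
#'   `ddof = 1` (default) is the unbiased sample variance; `ddof = 0` the
#'   population variance.
#' @return Non-negative scalar.
#' @export
sample_variance <- function(values, ddof = 1) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be finite numeric")
  }
  n <- length(values)
  if (n < 2) abort("need at least 2 values to compute a variance")
  if (n <= ddof) abort("need more values than `ddof`")
  sum((values - mean(values))^2) / (n - ddof)
}

#' Moment estimator of the founder cell number
#'
#' Inverts the binomial variance relation `Var = p(1-p)/N`:
#' `N = p(1-p)/Var`. The estimate is continuous (not rounded); with p = 0.5
#' and the observed placental X-inactivation score variance this is the
#' classical variance-based stem-cell count.
#'
#' @param p Per-founder-cell "on" probability, in (0, 1). 0.5 for
#'   X-inactivation; about 0.1 for maternal IGF2/H19 DMR methylation.
#' @param variance Observed score variance (> 0). Vectorised.
#' @return Positive numeric: the estimated founder count.
#' @examples
#' moment_n(0.5, 0.1637^2)
#' @export
moment_n <- function(p, variance) {
  if (!is.numeric(p) || any(p <= 0 | p >= 1)) {
    abort("`p` must lie strictly inside (0, 1)")
  }
  if (!is.numeric(variance) || any(!is.finite(variance))) {
    abort("`variance` must be finite numeric")
  }
  if (any(variance == 0)) {
    abort("degenerate distribution; founder number unbounded")
  }
  if (any(variance < 0)) abort("`variance` must be positive")
  p * (1 - p) / variance
}

#' Distribution of founder fractions for N founder cells
#'
#' The discrete distribution of the score `k/n` with
#' `k ~ Binomial(n, p)`: mass `C(n,k) p^k (1-p)^(n-k)` at `k/n`.
#' Its mean is `p` and its variance `p(1-p)/n`.
#'
#' @param n Number of founder cells (positive integer).
#' @param p Per-cell "on" probability in (0, 1).
#' @return A tibble with columns `score` (= k/n) and `mass`.
#' @export
binomial_score_pmf <- function(n, p) {
  if (length(n) != 1 || n < 1 || n != as.integer(n)) {
    abort("`n` must be a single positive integer")
  }
  if (length(p) != 1 || p <= 0 || p >= 1) {
    abort("`p` must lie strictly inside (0, 1)")
  }
  k <- 0:n
  tibble(score = k / n, mass = dbinom(k, n, p))
}

# Shared binning rule for score histograms: equal-width bins over [0, 1],
# scores equal to 1 fall in the last bin.
score_bin_index <- function(x, n_bins) {
  pmin(floor(x * n_bins) + 1L, n_bins)
}

# Bin probabilities of the k/N score distribution, optionally convolved with
# Gaussian measurement noise (masses renormalised after convolution).
candidate_bin_probs <- function(n, p, n_bins, noise_sd = 0) {
  pmf <- binomial_score_pmf(n, p)
  if (noise_sd > 0) {
    edges <- seq(0, 1, length.out = n_bins + 1)
    probs <- vapply(seq_len(n_bins), function(b) {
      sum(pmf$mass * (pnorm(edges[b + 1], pmf$score, noise_sd) -
                        pnorm(edges[b], pmf$score, noise_sd)))
    }, numeric(1))
    probs / sum(probs)
  } else {
    idx <- score_bin_index(pmf$score, n_bins)
    as.numeric(tapply(pmf$mass, factor(idx, levels = seq_len(n_bins)), sum,
                      default = 0))
  }
}

#' Fit the founder cell number by distribution matching
#'
#' Searches an integer grid of candidate founder counts for the one whose
#' theoretical score distribution ([binomial_score_pmf()]) is closest to the
#' empirical distribution of observed scores. Two distances are offered:
#'
#' * `chi2_binned` (default): Pearson chi-square distance on scores binned
#'   into `n_bins` equal-width bins over \[0, 1\] (expected counts from the
#'   candidate pmf aggregated into the same bins; candidates that place zero
#'   mass in an occupied bin are ruled out);
#' * `ks`: Kolmogorov–Smirnov distance between the empirical CDF and the
#'   candidate CDF.
#'
#' Ties are broken toward the smaller candidate. Scores outside \[0, 1\] are
#' excluded from the fit with a warning. A zero-variance score set is
#' degenerate: ever-larger candidates fit ever better, so the fit returns
#' `n_max` flagged as degenerate.
#'
#' @param scores Numeric scores (at least 20 inside \[0, 1\]).
#' @param p Per-cell "on" probability in (0, 1).
#' @param n_min,n_max Integer search bounds (defaults 1 and 100).
#' @param metric `"chi2_binned"` or `"ks"`.
#' @param noise_sd Optional Gaussian measurement-noise SD convolved into the
#'   candidate distributions (default 0: the pure clonal-sampling model).
#' @param n_bins Number of histogram bins for `chi2_binned` (default 10).
#' @return A list with elements `n_fit` (integer), `metric_value`, `metric`,
#'   and `degenerate` (logical).
#' @export
fit_n_distribution <- function(scores, p, n_min = 1, n_max = 100,
                               metric = c("chi2_binned", "ks"),
                               noise_sd = 0, n_bins = 10) {
  metric <- match.arg(metric)
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    abort("`scores` must be finite numeric")
  }
  if (length(p) != 1 || p <= 0 || p >= 1) {
    abort("`p` must lie strictly inside (0, 1)")
  }
  if (n_min > n_max || n_min < 1) abort("need 1 <= n_min <= n_max")

  outside <- scores < 0 | scores > 1
  if (any(outside)) {
    warn(sprintf("%d score(s) outside [0, 1] excluded from distribution fitting",
                 sum(outside)))
    scores <- scores[!outside]
  }
  if (length(scores) < 20) {
    abort("need at least 20 in-range scores to fit a distribution")
  }

  if (var(scores) == 0) {
    # zero observed variance implies an unbounded founder count; the largest
    # candidate is the flattest-variance fit on the grid
    return(list(n_fit = as.integer(n_max), metric_value = NA_real_,
                metric = metric, degenerate = TRUE))
  }
  grid <- n_min:n_max
  n_obs <- length(scores)

  if (metric == "chi2_binned") {
    observed <- tabulate(score_bin_index(scores, n_bins), nbins = n_bins)
    dist <- vapply(grid, function(n_cand) {
      expected <- n_obs * candidate_bin_probs(n_cand, p, n_bins, noise_sd)
      if (any(observed > 0 & expected == 0)) return(Inf)
      keep <- expected > 0
      sum((observed[keep] - expected[keep])^2 / expected[keep])
    }, numeric(1))
  } else {
    emp_cdf <- stats::ecdf(scores)
    dist <- vapply(grid, function(n_cand) {
      pmf <- binomial_score_pmf(n_cand, p)
      # both CDFs are right-continuous step functions, so the supremum is
      # attained on the union of their jump points
      points <- sort(unique(c(scores, pmf$score)))
      Fc <- if (noise_sd > 0) {
        vapply(points, function(t) sum(pmf$mass * pnorm(t, pmf$score, noise_sd)),
               numeric(1))
      } else {
        cumsum_mass <- cumsum(pmf$mass)
        cumsum_mass[findInterval(points + 1e-12, pmf$score)]
      }
      max(abs(emp_cdf(points) - Fc))
    }, numeric(1))
  }

  best <- which.min(dist) # first minimum -> smallest N on ties
  list(
    n_fit = as.integer(grid[best]),
    metric_value = dist[best],
    metric = metric,
    degenerate = FALSE
  )
}

#' Estimate founder cell numbers per group from a ratio table
#'
#' Pools the matching allelic scores of each conception group (by default all
#' five placenta sections across all individuals, treated as independent
#' draws from the founder-sampling model), then reports for each group the
#' score mean and variance, the moment estimate `p(1-p)/Var`, and the
#' distribution-fit estimate from [fit_n_distribution()]. This is the
#' machine-readable twin of a stem-cell-number summary table.
#'
#' @param ratios A ratio table (see [compute_ratios()]): columns
#'   `individual_id`, `group`, `tissue`, `locus`, `score_kind`, `value`.
#' @param assay Which score to analyse: `"XI"`, `"MP"` or `"PM"`.
#' @param p Per-cell probability; default 0.5 for `XI` and 0.1 for `MP`/`PM`.
#'   Set `p_from_mean = TRUE` to use each group's observed mean instead.
#' @param tissues Tissue samples to pool (default the five placenta sections).
#' @param ddof Variance denominator offset passed to [sample_variance()].
#' @param p_from_mean Take `p` from the group mean score (the observed
#'   probability that a molecule carries the scored mark).
#' @param pool `"sections"` (default) pools every tissue sample as an
#'   independent draw; `"individual_means"` first averages within individual.
#' @param n_min,n_max,metric,noise_sd,n_bins Passed to
#'   [fit_n_distribution()]. Groups with fewer than 20 in-range scores get
#'   `n_fit = NA` with a warning.
#' @return A `founder_fit` tibble with one row per group: `assay`, `group`,
#'   `p`, `n_samples`, `mean`, `variance`, `n_moment`, `n_fit`,
#'   `fit_metric`, `fit_value`. The pooled scores are attached for
#'   [autoplot.founder_fit()].
#' @export
estimate_founders <- function(ratios, assay = c("XI", "MP", "PM"), p = NULL,
                              tissues = ef_placenta_tissues(), ddof = 1,
                              p_from_mean = FALSE,
                              pool = c("sections", "individual_means"),
                              n_min = 1, n_max = 100,
                              metric = c("chi2_binned", "ks"),
                              noise_sd = 0, n_bins = 10) {
  assay <- match.arg(assay)
  pool <- match.arg(pool)
  metric <- match.arg(metric)
  ratios <- validate_ratio(ratios)

  selected <- ratios |>
    dplyr::filter(.data$score_kind == assay, .data$tissue %in% tissues)
  if (nrow(selected) == 0) {
    abort(sprintf("no %s records in the requested tissues", assay))
  }
  if (pool == "individual_means") {
    selected <- selected |>
      dplyr::group_by(.data$group, .data$individual_id) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }

  default_p <- if (assay == "XI") 0.5 else 0.1
  rows <- selected |>
    dplyr::group_by(.data$group) |>
    dplyr::group_map(function(df, key) {
      scores <- df$value
      m <- mean(scores)
      v <- sample_variance(scores, ddof = ddof)
      p_used <- if (p_from_mean) m else (p %||% default_p)
      fit <- if (sum(scores >= 0 & scores <= 1) >= 20) {
        fit_n_distribution(scores, p_used, n_min = n_min, n_max = n_max,
                           metric = metric, noise_sd = noise_sd,
                           n_bins = n_bins)
      } else {
        warn(sprintf("group %s: fewer than 20 in-range scores; n_fit set to NA",
                     key$group))
        list(n_fit = NA_integer_, metric_value = NA_real_, metric = metric,
             degenerate = FALSE)
      }
      tibble(
        assay = assay, group = key$group, p = p_used,
        n_samples = length(scores), mean = m, variance = v,
        n_moment = moment_n(p_used, v),
        n_fit = fit$n_fit, fit_metric = fit$metric,
        fit_value = fit$metric_value
      )
    }) |>
    dplyr::bind_rows()

  scores_by_group <- split(selected$value, selected$group)
  new_founder_fit(rows, scores = scores_by_group)
}

new_founder_fit <- function(rows, scores) {
  structure(rows, scores = scores,
            class = c("founder_fit", class(tibble())))
}

#' @export
print.founder_fit <- function(x, ...) {
  cat("Founder cell estimates (Var = p(1-p)/N)\n")
  NextMethod()
  invisible(x)
}
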