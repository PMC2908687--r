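test_that("sample_variance honours ddof and rejects degenerate input", {
  expect_equal(sample_variance(c(0, 0, 0)), 0)
  expect_equal(sample_variance(c(0, 1)), 0.5)
  expect_equal(sample_variance(c(0, 1), ddof = 0), 0.25)
  x <- c(2.1, 3.4, 0.7, 5.2, 4.4)
  expect_equal(sample_variance(x), var(x))
  expect_error(sample_variance(1), "at least 2")
  expect_error(sample_variance(c(1, 2), ddof = 2), "more values than")
})

test_that("sample variance of simulated founder scores approaches pq/N", {
  s <- simulate_founder_scores(10, 0.1, 10000, seed = 501)
  v <- sample_variance(s)
  # SE of the sample variance from the sample's own fourth moment
  n <- length(s)
  m4 <- mean((s - mean(s))^4)
  se <- sqrt((m4 - (n - 3) / (n - 1) * v^2) / n)
  expect_lt(abs(v - 0.009), 3 * se)
})

test_that("moment_n inverts the binomial variance relation", {
  expect_equal(moment_n(0.5, 0.25 / 12), 12)
  expect_equal(moment_n(0.5, 0.1637^2), 9.33, tolerance = 0.01 / 9.33)
  expect_equal(moment_n(0.1, 0.0091), 9.89, tolerance = 0.01 / 9.89)
  expect_error(moment_n(0.5, 0), "degenerate")
  expect_error(moment_n(1, 0.1), "strictly inside")
  expect_error(moment_n(0, 0.1), "strictly inside")
})

test_that("moment_n is strictly decreasing in variance at fixed p", {
  vs <- seq(0.001, 0.2, length.out = 40)
  est <- moment_n(0.3, vs)
  expect_true(all(diff(est) < 0))
})

test_that("binomial_score_pmf matches exact binomial masses and identities", {
  expect_equal(binomial_score_pmf(1, 0.5)$mass, c(0.5, 0.5))
  pmf2 <- binomial_score_pmf(2, 0.5)
  expect_equal(pmf2$score, c(0, 0.5, 1))
  expect_equal(pmf2$mass, c(0.25, 0.5, 0.25))
  pmf_var <- function(pmf) sum(pmf$mass * pmf$score^2) - sum(pmf$mass * pmf$score)^2
  expect_equal(pmf_var(binomial_score_pmf(10, 0.1)), 0.009)
  for (n in c(1, 3, 10, 50)) {
    for (p in c(0.1, 0.25, 0.5)) {
      pmf <- binomial_score_pmf(n, p)
      expect_lt(abs(sum(pmf$mass) - 1), 1e-12)
      expect_equal(sum(pmf$mass * pmf$score), p)
      expect_equal(pmf_var(pmf), p * (1 - p) / n)
      expect_equal(moment_n(p, pmf_var(pmf)), n)
    }
  }
})

test_that("fit_n_distribution recovers the generating founder count", {
  s <- simulate_founder_scores(9, 0.5, 5000, seed = 502)
  fit <- fit_n_distribution(s, 0.5)
  expect_identical(fit$n_fit, 9L)
  expect_false(fit$degenerate)

  s2 <- simulate_founder_scores(10, 0.1, 10000, seed = 503)
  expect_true(fit_n_distribution(s2, 0.1)$n_fit %in% 9:11)

  # the KS metric agrees on a clean case
  expect_identical(fit_n_distribution(s, 0.5, metric = "ks")$n_fit, 9L)
})

test_that("fit and moment estimators agree on large simulated samples", {
  for (setting in list(c(5, 0.5), c(12, 0.1))) {
    s <- simulate_founder_scores(setting[1], setting[2], 5000,
                                 seed = 504 + setting[1])
    nm <- moment_n(setting[2], sample_variance(s))
    nf <- fit_n_distribution(s, setting[2])$n_fit
    expect_lte(abs(nf - round(nm)), 1)
  }
})

test_that("fit_n_distribution handles degenerate and out-of-range scores", {
  flat <- rep(0.5, 30)
  fit <- fit_n_distribution(flat, 0.5, n_max = 40)
  expect_identical(fit$n_fit, 40L)
  expect_true(fit$degenerate)

  s <- c(simulate_founder_scores(9, 0.5, 50, seed = 505), 1.4, -0.2)
  expect_warning(fit_n_distribution(s, 0.5), "outside \\[0, 1\\]")
  expect_error(fit_n_distribution(rep(0.5, 10), 0.5), "at least 20")
})

test_that("estimate_founders reports per-group moment and fit estimates", {
  scores <- simulate_founder_scores(11, 0.5, 54 * 5, seed = 506)
  ratios <- make_ratio_tbl(scores, group = "in_vivo", score_kind = "XI")
  ratios$tissue <- rep_len(paste0("placenta_", 1:5), nrow(ratios))
  ff <- estimate_founders(ratios, assay = "XI")
  expect_s3_class(ff, "founder_fit")
  tbl <- tidy(ff)
  expect_equal(tbl$p, 0.5)
  expect_equal(tbl$n_samples, 270L)
  expect_lt(abs(tbl$n_moment - 11) / 11, 0.15)
  expect_equal(tbl$mean, mean(scores))

  g <- glance(ff)
  expect_equal(g$n_groups, 1L)
  expect_true(is.na(g$moment_ratio_vitro_vivo))

  # degenerate variance propagates the moment_n error
  flat <- make_ratio_tbl(rep(0.5, 30), score_kind = "XI")
  flat$tissue <- "placenta_1"
  expect_error(estimate_founders(flat, assay = "XI"), "degenerate")
})

test_that("estimate_founders supports p-from-mean and per-individual pooling", {
  set.seed(507)
  sim <- simulate_cohort(cohort_config(seed = 507))
  ff <- estimate_founders(sim$ratios, assay = "MP", p_from_mean = TRUE)
  tbl <- tidy(ff)
  expect_equal(tbl$p, tbl$mean)

  ff2 <- estimate_founders(sim$ratios, assay = "MP", pool = "individual_means")
  expect_equal(tidy(ff2)$n_samples, c(45L, 56L))

  expect_error(estimate_founders(sim$ratios, assay = "PM"), "no PM records")
})

test_that("autoplot on a founder_fit builds a ggplot", {
  sim <- simulate_cohort(cohort_config(seed = 508))
  ff <- estimate_founders(sim$ratios, assay = "MP")
  expect_s3_class(autoplot(ff), "ggplot")
})
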