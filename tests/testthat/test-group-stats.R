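test_that("exact rank-sum test matches brute-force enumeration semantics", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(res$statistic, 6)
  expect_equal(res$p_value, 0.1) # 2 of the 20 rank assignments are as extreme

  # agreement with the independent exact implementation on tie-free data
  set.seed(701)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    na <- sample(seq_len(n - 1), 1)
    x <- rnorm(n)
    mine <- wilcoxon_rank_sum(x[1:na], x[(na + 1):n], mode = "exact")$p_value
    ref <- wilcox.test(x[1:na], x[(na + 1):n], exact = TRUE)$p.value
    expect_equal(mine, ref)
  }
})

test_that("rank-sum p is symmetric in the two samples", {
  set.seed(702)
  a <- rnorm(7); b <- rnorm(5) + 1
  expect_equal(wilcoxon_rank_sum(a, b, mode = "exact")$p_value,
               wilcoxon_rank_sum(b, a, mode = "exact")$p_value)
  a2 <- rnorm(30); b2 <- rnorm(25) + 0.5
  expect_equal(wilcoxon_rank_sum(a2, b2)$p_value,
               wilcoxon_rank_sum(b2, a2)$p_value)
})

test_that("normal approximation tracks the exact test on small samples", {
  set.seed(703)
  deltas <- replicate(100, {
    n <- sample(10:20, 1)
    na <- sample(4:(n - 4), 1)
    x <- rnorm(n)
    abs(wilcoxon_rank_sum(x[1:na], x[(na + 1):n], mode = "exact")$p_value -
          wilcoxon_rank_sum(x[1:na], x[(na + 1):n], mode = "normal_approx")$p_value)
  })
  expect_lt(max(deltas), 0.05)

  # midranks with tie correction keep the approximation usable under ties
  y <- c(1, 1, 2, 2, 3, 3, 4, 5, 5, 6, 7, 7)
  expect_lt(
    abs(wilcoxon_rank_sum(y[1:6], y[7:12], mode = "exact")$p_value -
          wilcoxon_rank_sum(y[1:6], y[7:12], mode = "normal_approx")$p_value),
    0.05
  )
})

test_that("rank-sum edge cases behave", {
  expect_warning(res <- wilcoxon_rank_sum(c(2, 2), c(2, 2, 2)), "vacuous")
  expect_equal(res$p_value, 1)
  expect_error(wilcoxon_rank_sum(rnorm(15), rnorm(15), mode = "exact"),
               "limited")
  # identical lists differ in no location: p should be ~1
  x <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_rank_sum(x, x, mode = "exact")$p_value, 1)
})

test_that("variance_equality_test detects unequal spread and calibrates", {
  set.seed(704)
  a <- rnorm(100)
  b <- 3 * (a - mean(a)) + mean(a)
  for (m in c("levene_median", "f_test")) {
    expect_lt(variance_equality_test(a, b, method = m)$p_value, 0.05)
  }

  # boundary: identical samples give a null statistic
  x <- c(1, 2, 3, 6, 9)
  res <- variance_equality_test(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  expect_error(variance_equality_test(rep(1, 5), rep(2, 5)), "degenerate")

  # f_test mode is the classical variance-ratio test
  y <- rnorm(50, 0, 2)
  mine <- variance_equality_test(a, y, method = "f_test")
  ref <- var.test(a, y)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
})

test_that("summarize_groups mirrors the tissue-block summary layout", {
  sim <- simulate_cohort(cohort_config(seed = 705))
  smry <- summarize_groups(sim$ratios, assay = "MP")
  expect_setequal(unique(smry$tissue_set),
                  c("cord_blood", "cord", "placenta", "total"))
  expect_equal(nrow(smry), 8)
  expect_true(all(smry$variance >= 0))
  expect_true(all(smry$p_means >= 0 & smry$p_means <= 1))

  # the total row equals the pooled-sample statistics
  mp <- sim$ratios[sim$ratios$score_kind == "MP", ]
  pooled <- mp$value[mp$group == "in_vitro"]
  tot <- smry[smry$tissue_set == "total" & smry$group == "in_vitro", ]
  expect_equal(tot$mean, mean(pooled))
  expect_equal(tot$variance, var(pooled))
  expect_equal(tot$n, length(pooled))
})

test_that("summarize_groups handles single-group and empty cells", {
  one <- make_ratio_tbl(runif(10, 0, 0.3))
  msgs <- capture_warnings(smry <- summarize_groups(one, assay = "MP"))
  expect_match(msgs, "omitted", all = FALSE)
  expect_true(all(is.na(smry$p_means)))
  expect_false("cord_blood" %in% smry$tissue_set)
})

test_that("fewer founders produce larger placental variance in expectation", {
  sim <- simulate_cohort(cohort_config(founders_in_vitro = 8,
                                       founders_in_vivo = 10, seed = 706))
  smry <- summarize_groups(sim$ratios, assay = "MP")
  pl <- smry[smry$tissue_set == "placenta", ]
  expect_gt(pl$variance[pl$group == "in_vitro"],
            pl$variance[pl$group == "in_vivo"])
})

test_that("ddct computes 2^-ddCt fold changes with a Welch t-test", {
  # a one-cycle delta-Ct difference halves the relative expression
  set.seed(707)
  base <- rnorm(20, 5, 0.05)
  res <- ddct(make_ct_tbl(base + 1, rnorm(20, 5, 0.05)), "IGF2")
  expect_equal(res$fold_change, 0.5, tolerance = 0.02)
  expect_lt(res$p_value, 1e-6)

  # identical dCt distributions: fold exactly 1, p = 1
  same <- make_ct_tbl(c(4, 5, 6, 7), c(4, 5, 6, 7))
  res2 <- ddct(same, "IGF2")
  expect_equal(res2$fold_change, 1)
  expect_equal(res2$p_value, 1)
})

test_that("ddct of the housekeeping gene against itself is exactly 1", {
  ct <- make_ct_tbl(rnorm(10), rnorm(10))
  expect_warning(res <- ddct(ct, "GAPDH"), "no variation")
  expect_identical(res$fold_change, 1)
  expect_true(is.na(res$p_value))
})

test_that("ddct drops samples without housekeeping and validates groups", {
  ct <- make_ct_tbl(rnorm(10, 2), rnorm(10, 2))
  ct <- ct[!(ct$gene == "GAPDH" & ct$individual_id == "a001"), ]
  expect_warning(res <- ddct(ct, "IGF2"), "dropped")
  expect_equal(res$n_in_vitro, 9)

  only_one <- ct[ct$group == "in_vivo", ]
  expect_error(ddct(only_one, "IGF2"), "each group")
})

test_that("ddct_table covers every gene and tissue class", {
  sim <- simulate_cohort(cohort_config(n_expr_in_vitro = 20,
                                       n_expr_in_vivo = 20, seed = 708))
  tbl <- ddct_table(sim$ct)
  expect_equal(nrow(tbl), 6) # 3 targets x 2 tissue classes
  expect_setequal(unique(tbl$gene), c("IGF2", "H19", "IGF2R"))
  expect_true(all(tbl$fold_change > 0))
  expect_s3_class(plot_fold_changes(tbl), "ggplot")
})
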