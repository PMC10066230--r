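test_that("significance banding follows the study rule with a right-open trend band", {
  expect_equal(classify_significance(0.012), "significant")
  expect_equal(classify_significance(0.116), "trend")
  expect_equal(classify_significance(c(0.049, 0.05, 0.199, 0.20)),
               c("significant", "trend", "trend", "none"))
  expect_error(classify_significance(1.2), "\\[0, 1\\]")
  expect_error(classify_significance(-0.1), "\\[0, 1\\]")
})

test_that("identical groups give a zero statistic and class none", {
  x <- c(1.2, 3.4, 2.2, 4.1, 2.9, 3.3)
  r <- compare_groups(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$significance_class, "none")
  expect_false(r$degenerate)
})

test_that("test-selection cascade picks the branches the data call for", {
  # clean gaussian, equal variance -> pooled t dominates over repeated draws
  picks <- vapply(1:60, function(s) {
    set.seed(s)
    compare_groups(rnorm(20), rnorm(20, 2))$test_used
  }, "")
  expect_gt(mean(picks == "t_equal_var"), 0.8)
  expect_true(all(vapply(1:60, function(s) {
    set.seed(s)
    compare_groups(rnorm(20), rnorm(20, 2))$significance_class
  }, "") == "significant"))
  # strongly skewed data -> nonparametric branch dominates
  picks_exp <- vapply(1:60, function(s) {
    set.seed(s)
    compare_groups(rexp(20), rexp(20))$test_used
  }, "")
  expect_gt(mean(picks_exp == "wilcoxon_rank"), 0.8)
  # unequal variances with gaussian data -> Welch appears
  set.seed(4)
  r <- compare_groups(rnorm(30, sd = 1), rnorm(30, sd = 6))
  expect_true(r$test_used %in% c("t_welch", "wilcoxon_rank"))
  if (r$test_used == "t_welch") expect_lt(r$f_test_p, 0.05)
})

test_that("cascade invariants hold: wilcoxon iff a shapiro gate fails; f-test only on t branches", {
  set.seed(42)
  for (i in 1:40) {
    x <- if (i %% 2) rnorm(12) else rexp(12)
    y <- if (i %% 3) rnorm(12, 0.5) else rexp(12)^2
    r <- compare_groups(x, y)
    gate_fails <- any(r$shapiro_p < 0.05, na.rm = TRUE)
    expect_identical(r$test_used == "wilcoxon_rank", gate_fails)
    expect_identical(!is.na(r$f_test_p), r$test_used %in% c("t_equal_var", "t_welch"))
    expect_gte(r$p_value, 0)
    expect_lte(r$p_value, 1)
  }
})

test_that("comparison is label-swap invariant up to the sign of direction", {
  set.seed(9)
  x <- rexp(10); y <- rnorm(10, 1)
  a <- compare_groups(x, y); b <- compare_groups(y, x)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$test_used, b$test_used)
  expect_equal(a$direction, -b$direction)
})

test_that("degenerate input (both groups constant) flags and returns p = 1", {
  r <- compare_groups(rep(2, 5), rep(2, 5))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  r2 <- compare_groups(rep(2, 5), rep(7, 5))   # constant but different groups
  expect_false(r2$degenerate)
  expect_equal(r2$test_used, "wilcoxon_rank")
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("chi-square independence matches hand arithmetic and keeps declared df", {
  r <- chisq_independence(rbind(c(10, 10), c(10, 10)))
  expect_equal(r$statistic, 0)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, 1)
  expect_warning(r2 <- chisq_independence(rbind(c(8, 0, 0, 0), c(0, 8, 0, 0))),
                 "zero-marginal")
  # expected 4 per cell in the two active columns: 4 cells * (8-4)^2/4 = 16
  expect_equal(r2$statistic, 16)
  expect_equal(r2$df, 3)
  expect_identical(r2$p_value, chisq_tail(r2$statistic, r2$df))
  expect_error(chisq_independence(rbind(c(1, 0), c(2, 0))), "positive marginals")
})

test_that("chi-square tail matches numerical integration of the density", {
  for (df in c(1, 3, 5, 10)) for (q in c(0.5, 4, 11.667, 23.333, 40)) {
    num <- stats::integrate(function(t) stats::dchisq(t, df), q, Inf,
                            rel.tol = 1e-12)$value
    expect_equal(chisq_tail(q, df), num, tolerance = 1e-8)
  }
  expect_equal(chisq_tail(0, 4), 1)
  expect_error(chisq_tail(-1, 3), "negative")
})

test_that("screening a null dataset is calibrated and BH column is monotone", {
  set.seed(11)
  vals <- matrix(rnorm(20 * 200), 20, dimnames = list(NULL, paste0("f", 1:200)))
  ds <- omics_dataset(vals, group = rep(0:1, each = 10))
  sc <- screen_dataset(ds)
  expect_equal(nrow(sc), 200)
  frac <- mean(sc$significance_class == "significant")
  expect_lt(abs(frac - 0.05), 0.05)
  expect_true(all(sc$p_bh >= sc$p_value - 1e-12))
})
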