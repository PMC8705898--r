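test_that("difference CI matches the closed-form two-sample construction", {
  # identical groups: centred at zero
  g <- group_summary(10, 1, 100)
  ci0 <- ci_difference(g, g)
  expect_equal(ci0$point, 0)
  expect_equal(ci0$lower, -ci0$upper, tolerance = 1e-12)

  # closed form: half-width = t(0.95, df) * sqrt(1/100 + 1/100); Welch df = 198
  hw <- qt(0.95, 198) * sqrt(0.02)
  expect_equal(ci0$df, 198, tolerance = 1e-9)
  expect_equal(ci0$upper, hw, tolerance = 1e-12)

  # cross-check against t.test on raw data with matching summaries
  set.seed(1)
  x <- rnorm(12); x <- (x - mean(x)) / sd(x) * 3.2 + 57
  y <- rnorm(15); y <- (y - mean(y)) / sd(y) * 4.1 + 52
  tt <- t.test(x, y, conf.level = 0.90)
  ci <- ci_difference(summarize_group(x), summarize_group(y))
  expect_equal(as.numeric(tt$conf.int), c(ci$lower, ci$upper), tolerance = 1e-9)
  expect_equal(unname(tt$parameter), ci$df, tolerance = 1e-9)
})

test_that("ratio CI is exactly the shifted-and-scaled difference CI", {
  set.seed(7)
  for (i in 1:25) {
    t <- group_summary(runif(1, 5, 100), runif(1, 0.1, 20), sample(3:30, 1))
    r <- group_summary(runif(1, 5, 100), runif(1, 0.1, 20), sample(3:30, 1))
    d <- ci_difference(t, r)
    q <- ci_ratio(t, r)
    expect_equal(q$lower, (r$mean + d$lower) / r$mean, tolerance = 1e-14)
    expect_equal(q$upper, (r$mean + d$upper) / r$mean, tolerance = 1e-14)
    expect_equal(q$point, t$mean / r$mean, tolerance = 1e-14)
  }
})

test_that("discriminatory-power interval matches the printed validation table", {
  test <- group_summary(70.91, 2.92, 12)
  ref <- group_summary(60.13, 3.48, 12)
  ci_w <- ci_ratio(test, ref, df_rule = "welch")
  ci_p <- ci_ratio(test, ref, df_rule = "pooled")
  expect_equal(round(c(ci_w$lower, ci_w$upper), 2), c(1.14, 1.22))
  expect_equal(round(c(ci_p$lower, ci_p$upper), 2), c(1.14, 1.22))
})

test_that("interval width shrinks with n and grows with sigma", {
  base <- ci_ratio(group_summary(55, 5, 12), group_summary(50, 5, 12))
  more_n <- ci_ratio(group_summary(55, 5, 24), group_summary(50, 5, 24))
  more_s <- ci_ratio(group_summary(55, 8, 12), group_summary(50, 8, 12))
  w <- function(ci) ci$upper - ci$lower
  expect_lt(w(more_n), w(base))
  expect_gt(w(more_s), w(base))
})

test_that("log-scale ratio CI: point, scale equivariance and reciprocity", {
  set.seed(3)
  x <- rlnorm(6, log(15), 0.4)
  y <- rlnorm(6, log(14), 0.4)
  ci <- ci_ratio_log(x, y)
  expect_equal(ci$point, exp(mean(log(x)) - mean(log(y))), tolerance = 1e-12)

  # equal samples: point exactly 1
  expect_equal(ci_ratio_log(x, x)$point, 1, tolerance = 1e-12)

  # scaling the reference by k scales the whole interval by 1/k
  ci_k <- ci_ratio_log(x, 2 * y)
  expect_equal(c(ci_k$lower, ci_k$point, ci_k$upper),
               c(ci$lower, ci$point, ci$upper) / 2, tolerance = 1e-12)

  # swapping arms gives the reciprocal interval
  ci_sw <- ci_ratio_log(y, x)
  expect_equal(ci_sw$lower, 1 / ci$upper, tolerance = 1e-12)
  expect_equal(ci_sw$upper, 1 / ci$lower, tolerance = 1e-12)

  expect_error(ci_ratio_log(c(x, -1), y), "positive")
})

test_that("range verdicts form an exhaustive trichotomy with closed bounds", {
  mk <- function(lo, hi) structure(
    list(point = (lo + hi) / 2, lower = lo, upper = hi, df = 10,
         alpha = 0.1, scale = "ratio"), class = "ci_result")
  # boundary values count as within
  expect_equal(range_check(mk(0.90, 1.11), "ivrt_90_111")$status, "within")
  expect_equal(range_check(mk(0.95, 1.05), "ivrt_90_111")$status, "within")
  expect_equal(range_check(mk(1.14, 1.22), "ivrt_90_111")$status, "outside")
  expect_equal(range_check(mk(0.5006, 0.9085), "ivpt_80_125")$status, "straddles")
  expect_equal(range_check(mk(0.80, 1.25), "ivpt_80_125")$status, "within")
  expect_error(range_check(mk(1, 1.1), "no_such_range"), "unknown")

  # every interval gets exactly one status
  set.seed(5)
  for (i in 1:200) {
    b <- sort(runif(2, 0.5, 1.5))
    st <- range_check(mk(b[1], b[2]), "physchem_90_110")$status
    expect_true(st %in% c("within", "outside", "straddles"))
  }
})

test_that("bootstrap interval is deterministic, degenerate on constants, and consistent at large n", {
  x <- rep(5, 10); y <- rep(4, 10)
  b <- bootstrap_ci(x, y, reps = 1000, seed = 1)
  expect_equal(c(b$lower, b$point, b$upper), c(1.25, 1.25, 1.25))

  set.seed(9)
  x <- rnorm(200, 20, 2); y <- rnorm(200, 18, 2)
  b1 <- bootstrap_ci(x, y, reps = 4000, seed = 42)
  b2 <- bootstrap_ci(x, y, reps = 4000, seed = 42)
  expect_identical(c(b1$lower, b1$upper), c(b2$lower, b2$upper))

  # large-n agreement with the t-based ratio interval
  ci <- ci_ratio(summarize_group(x), summarize_group(y))
  expect_equal(b1$lower, ci$lower, tolerance = 0.01)
  expect_equal(b1$upper, ci$upper, tolerance = 0.01)

  expect_error(bootstrap_ci(x, y, reps = 100, seed = 1), "1000")
  expect_error(bootstrap_ci(x, y, reps = 1000), "seed")
})

test_that("group summaries validate their invariants", {
  expect_error(group_summary(10, -1, 5), "non-negative")
  expect_error(group_summary(10, 1, 1), "at least 2")
  expect_error(cv_pct(c(-1, 1)), "mean is zero")
  expect_equal(cv_pct(c(10, 10, 10)), 0)
})
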