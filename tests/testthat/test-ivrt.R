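test_that("Higuchi fit recovers an exact square-root-of-time line", {
  p <- higuchi_profile(10)
  f <- suppressWarnings(higuchi_fit(p))   # perfect fit warns in summary.lm
  expect_equal(f$K, 10, tolerance = 1e-9)
  expect_equal(f$intercept, 0, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_equal(f$q6, 10 * sqrt(6), tolerance = 1e-9)

  # constant profile: zero slope
  fc <- suppressWarnings(higuchi_fit(make_profile(rep(7, 7), ivrt_times())))
  expect_equal(fc$K, 0, tolerance = 1e-9)

  expect_error(higuchi_fit(make_profile(c(1, 2), c(1, 2))), "at least 3")
})

test_that("Higuchi fit is equivariant under scaling of q", {
  set.seed(13)
  q <- 30 * sqrt(ivrt_times()) + rnorm(7)
  f1 <- higuchi_fit(make_profile(q, ivrt_times()))
  f2 <- higuchi_fit(make_profile(2.5 * q, ivrt_times()))
  expect_equal(f2$K, 2.5 * f1$K, tolerance = 1e-9)
  expect_equal(f2$intercept, 2.5 * f1$intercept, tolerance = 1e-9)
  expect_equal(f2$q6, 2.5 * f1$q6, tolerance = 1e-9)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-9)
})

test_that("fitted K lands within 3 SE of the generating truth", {
  set.seed(101)
  q <- 30 * sqrt(ivrt_times()) + rnorm(7, 0, 1)
  f <- higuchi_fit(make_profile(q, ivrt_times()))
  expect_lt(abs(f$K - 30), 3 * f$se_K)
})

test_that("the 90% CI of the fitted slope covers truth at nominal rate", {
  # 500 noise-only replicates: empirical coverage within 90 +/- 3 points
  set.seed(77)
  K_true <- 28
  cover <- vapply(1:500, function(i) {
    q <- K_true * sqrt(ivrt_times()) + rnorm(7, 0, 1)
    f <- higuchi_fit(make_profile(q, ivrt_times()))
    hw <- qt(0.95, f$df) * f$se_K
    abs(f$K - K_true) <= hw
  }, logical(1))
  expect_gt(mean(cover), 0.87)
  expect_lt(mean(cover), 0.93)
})

test_that("linearity check separates proportional from flat dose response", {
  strengths <- rep(c(0.025, 0.05, 0.075), each = 12)
  exact <- data.frame(strength = strengths, K = 1100 * strengths,
                      q6 = 2500 * strengths)
  lc <- linearity_check(exact)
  expect_equal(lc$r2, c(1, 1), tolerance = 1e-12)
  expect_true(all(lc$pass))

  flat <- data.frame(strength = strengths, K = rep(28, 36), q6 = rep(57, 36))
  lf <- linearity_check(flat)
  expect_equal(lf$r2, c(0, 0), tolerance = 1e-12)
  expect_false(any(lf$pass))

  # proportional response with 5% multiplicative noise still passes at 0.90
  set.seed(21)
  noisy <- data.frame(strength = strengths,
                      K = 1100 * strengths * rnorm(36, 1, 0.05),
                      q6 = 2500 * strengths * rnorm(36, 1, 0.05))
  expect_true(all(linearity_check(noisy)$pass))

  expect_error(linearity_check(exact[exact$strength < 0.06, ]), "3 distinct")
})

test_that("intermediate precision reproduces printed and hand-computed CVs", {
  # printed operator summary: mean 63.9, SD 6.00 -> CV 9.39%
  expect_equal(round(100 * 6.00 / 63.9, 2), 9.39)
  set.seed(31)
  vals <- rnorm(12); vals <- (vals - mean(vals)) / sd(vals) * 6.00 + 63.9
  ip <- intermediate_precision(
    data.frame(operator = rep(c("op1", "op2"), each = 12),
               K = c(rnorm(12, 31.7, 2.7), rnorm(12, 31.9, 2.6)),
               q6 = c(rnorm(12, 62.8, 5.8), vals)))
  expect_equal(round(ip$by_group$q6_cv[ip$by_group$operator == "op2"], 2), 9.39)

  # identical values: zero CV everywhere; pooled CV from raw replicates
  two <- data.frame(operator = rep(c("a", "b"), each = 3),
                    K = rep(c(10, 20), each = 3), q6 = rep(c(10, 20), each = 3))
  ip2 <- intermediate_precision(two)
  expect_equal(ip2$by_group$K_cv, c(0, 0))
  expect_equal(unname(ip2$global["K_cv"]),
               100 * sd(rep(c(10, 20), each = 3)) / 15, tolerance = 1e-12)
})

test_that("discriminatory power requires the whole CI outside the release range", {
  dp <- discriminatory_power(group_summary(70.91, 2.92, 12),
                             group_summary(60.13, 3.48, 12))
  expect_true(dp$discriminates)
  expect_equal(dp$verdict$status, "outside")

  same <- discriminatory_power(group_summary(60, 3, 12), group_summary(60, 3, 12))
  expect_false(same$discriminates)
  expect_equal(same$ci$point, 1)

  # interval straddling the upper bound: no discriminatory power
  st <- discriminatory_power(group_summary(66, 8, 6), group_summary(60, 8, 6))
  expect_equal(st$verdict$status, "straddles")
  expect_false(st$discriminates)
})

test_that("robustness ANOVA behaves at both extremes and holds its size", {
  idential_p <- robustness_anova(data.frame(K = c(10, 11, 12), q6 = c(50, 51, 52)),
                                 data.frame(K = c(10, 11, 12), q6 = c(50, 51, 52)))
  expect_true(all(idential_p$p_value > 0.99))
  expect_false(any(idential_p$significant))

  far <- robustness_anova(data.frame(K = rnorm(12, 30, 1), q6 = rnorm(12, 60, 1)),
                          data.frame(K = rnorm(12, 40, 1), q6 = rnorm(12, 80, 1)))
  expect_true(all(far$p_value < 0.001))
  expect_true(all(far$significant))

  # type-I error under the null: rejection rate compatible with 5%
  set.seed(55)
  rej <- vapply(1:4000, function(i) {
    r <- robustness_anova(data.frame(K = rnorm(3, 30, 2), q6 = rnorm(3, 60, 4)),
                          data.frame(K = rnorm(3, 30, 2), q6 = rnorm(3, 60, 4)))
    r$significant[r$parameter == "K"]
  }, logical(1))
  expect_gt(mean(rej), 0.038)
  expect_lt(mean(rej), 0.062)
})

test_that("batch equivalence table reuses the same CI engine and verdicts", {
  set.seed(61)
  b1 <- data.frame(K = rnorm(12, 28.7, 2.2), q6 = rnorm(12, 57.3, 4.1))
  b2 <- data.frame(K = rnorm(12, 28.1, 5.4), q6 = rnorm(12, 56.7, 8.9))
  eq <- ivrt_equivalence(b1, b2)
  expect_equal(eq$parameter, c("K", "q6"))
  # byte-identical with the shared engine on the same summaries
  ci <- ci_ratio(summarize_group(b1$K), summarize_group(b2$K))
  expect_identical(eq$ratio[1], ci$point)
  expect_identical(c(eq$lower[1], eq$upper[1]), c(ci$lower, ci$upper))

  # identical arms: ratio exactly 1, CI contains 1, within range at n = 12
  same <- ivrt_equivalence(b1, b1)
  expect_equal(same$ratio, c(1, 1))
  expect_true(all(same$lower < 1 & same$upper > 1))
  expect_true(all(same$status == "within"))
})
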