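test_that("operating characteristics reproduce the 2x2 arithmetic", {
  op <- operating_point(tp = 34, fp = 76, fn = 5, tn = 227)
  expect_equal(round_half_up(100 * op$sensitivity, 1), 87.2)
  expect_equal(round_half_up(100 * op$specificity, 1), 74.9)
  expect_equal(round_half_up(100 * op$ppv, 1), 30.9)
  expect_equal(round_half_up(100 * op$npv, 1), 97.8)
  expect_equal(round_half_up(100 * op$youden, 1), 62.1)
  expect_equal(op$lr_pos, op$sensitivity / (1 - op$specificity))
  expect_equal(round_half_up(op$lr_pos, 2), 3.48)
  # a perfect 2x2
  p <- operating_point(tp = 1, fp = 0, fn = 0, tn = 1)
  expect_equal(p$sensitivity, 1)
  expect_equal(p$specificity, 1)
  expect_equal(p$youden, 1)
  expect_identical(p$lr_pos, Inf)
})

test_that("exact binomial CIs come from the Beta-quantile construction", {
  cp <- clopper_pearson(39, 39)
  expect_equal(cp[["estimate"]], 1)
  expect_equal(cp[["lower"]], qbeta(0.025, 39, 1))
  expect_equal(round_half_up(100 * cp[["lower"]], 0), 91)
  expect_identical(cp[["upper"]], 1)
  cp0 <- clopper_pearson(0, 25)
  expect_identical(cp0[["lower"]], 0)
  expect_equal(cp0[["upper"]], qbeta(0.975, 1, 25))
  # cross-check against binom.test's exact interval
  bt <- binom.test(13, 61)$conf.int
  cp2 <- clopper_pearson(13, 61)
  expect_equal(unname(cp2[2:3]), as.numeric(bt), tolerance = 1e-12)
})

test_that("undefined predictive values are flagged, not raised", {
  op <- operating_point(tp = 0, fp = 0, fn = 2, tn = 3)
  expect_false(op$ppv_defined)
  expect_true(is.na(op$ppv))
  expect_true(op$npv_defined)
  expect_error(operating_point(tp = -1, fp = 0, fn = 1, tn = 1),
               "nonnegative")
  expect_error(operating_point(tp = 0, fp = 1, fn = 0, tn = 1),
               "positive subject")
})

test_that("the threshold sweep enumerates observed cut-offs and checks out against subsets", {
  set.seed(41)
  n <- 120
  y <- runif(n) < 0.3
  if (!any(y)) y[1] <- TRUE
  s <- sample(0:6, n, replace = TRUE)
  sw <- threshold_sweep(s, y)
  expect_s3_class(sw, "dfu_sweep")
  expect_lte(nrow(sw), 7)
  expect_identical(sw$threshold, sort(unique(s)))
  for (i in seq_len(nrow(sw))) {
    t <- sw$threshold[i]
    expect_identical(sw$tp[i], sum(s >= t & y))
    expect_identical(sw$fp[i], sum(s >= t & !y))
    expect_identical(sw$fn[i], sum(s < t & y))
    expect_identical(sw$tn[i], sum(s < t & !y))
    expect_identical(sw$tp[i] + sw$fp[i] + sw$fn[i] + sw$tn[i],
                     as.integer(n))
    # Youden identity, exact on count arithmetic
    expect_identical(sw$youden[i],
                     sw$tp[i] / (sw$tp[i] + sw$fn[i]) +
                       sw$tn[i] / (sw$fp[i] + sw$tn[i]) - 1)
  }
  # binary score: one all-inclusive threshold plus one informative point
  swb <- threshold_sweep(as.integer(s >= 3), y)
  expect_identical(nrow(swb), 2L)
  expect_equal(swb$sensitivity[1], 1)
  expect_equal(swb$specificity[1], 0)
  expect_error(threshold_sweep(s, rep(FALSE, n)), "degenerate")
})

test_that("Youden selection takes the maximum, lowest threshold on ties", {
  sw <- data.frame(threshold = c(10, 15, 17, 18, 20),
                   youden = c(27.1, 56.5, 64.0, 69.4, 61.9) / 100)
  expect_identical(youden_best(sw)$threshold, 18)
  tie <- data.frame(threshold = c(2, 5), youden = c(0.4, 0.4))
  expect_identical(youden_best(tie)$threshold, 2)
  one <- data.frame(threshold = 3, youden = 0.1)
  expect_identical(youden_best(one)$threshold, 3)
})

test_that("cumulative incidence returns exact proportions with CP intervals", {
  inc <- cumulative_incidence(rep(c(TRUE, FALSE), times = c(39, 303)))
  expect_equal(round_half_up(100 * inc$proportion, 1), 11.4)
  expect_equal(inc$ci_low, qbeta(0.025, 39, 304))
  none <- cumulative_incidence(rep(FALSE, 50))
  expect_identical(none$proportion, 0)
  expect_identical(none$ci_low, 0)
  coh <- example_cohort()
  expect_identical(cumulative_incidence(coh, "major")$events,
                   sum(coh$major_amputation))
  expect_identical(cumulative_incidence(coh, "any")$events,
                   sum(coh$major_amputation | coh$minor_amputation))
})
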