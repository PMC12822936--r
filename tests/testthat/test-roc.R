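test_that("AUC equals the exhaustive pair-counting oracle, ties included", {
  set.seed(7)
  for (n in 4:10) {
    for (rep in 1:40) {
      cs <- random_roc_case(n)
      got <- roc_auc(cs$scores, cs$outcomes)$auc
      expect_equal(got, auc_pairs(cs$scores, cs$outcomes),
                   tolerance = 1e-12)
    }
  }
  # degenerate tie structure
  expect_equal(roc_auc(rep(2, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                    TRUE))$auc, 0.5)
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # worked small case: positive 3 against negatives {1, 2, 4}
  expect_equal(roc_auc(1:4, c(FALSE, FALSE, TRUE, FALSE))$auc, 2 / 3)
})

test_that("negating the outcome maps auc to 1 - auc", {
  set.seed(11)
  for (rep in 1:20) {
    cs <- random_roc_case(12, alphabet = 4)
    expect_equal(roc_auc(cs$scores, cs$outcomes)$auc,
                 1 - roc_auc(cs$scores, !cs$outcomes)$auc,
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the trapezoidal area under the empirical ROC", {
  set.seed(23)
  for (rep in 1:10) {
    cs <- random_roc_case(60, alphabet = 5)
    r <- roc_auc(cs$scores, cs$outcomes)
    fpr <- c(1, 1 - r$specificity, 0)
    tpr <- c(1, r$sensitivity, 0)
    trap <- sum((fpr[-length(fpr)] - fpr[-1]) *
                  (tpr[-length(tpr)] + tpr[-1]) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    # sensitivity non-increasing as the threshold rises
    expect_true(all(diff(r$sensitivity) <= 0))
    expect_true(all(diff(r$specificity) >= 0))
  }
})

test_that("AUC and DeLong variance agree with pROC", {
  set.seed(31)
  y <- runif(300) < 0.2
  s <- round(rnorm(300, mean = ifelse(y, 1.2, 0)), 1)  # heavy ties
  r <- roc_auc(s, y)
  pr <- pROC::roc(response = y, predictor = s, quiet = TRUE,
                  direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$se_auc^2, as.numeric(pROC::var(pr, method = "delong")),
               tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$ci_low, max(0, ci[1]), tolerance = 1e-10)
  expect_equal(r$ci_high, min(1, ci[3]), tolerance = 1e-10)
})

test_that("DeLong variance is nonnegative and the CI shrinks ~ n^(-1/2)", {
  se_at <- function(n, seed) {
    set.seed(seed)
    y <- rep(c(TRUE, FALSE), times = c(n / 4, 3 * n / 4))
    s <- rnorm(n, mean = ifelse(y, 1, 0))
    r <- roc_auc(s, y)
    expect_gte(r$se_auc, 0)
    r$se_auc
  }
  se_small <- mean(vapply(1:20, function(k) se_at(200, k), numeric(1)))
  se_big <- mean(vapply(1:20, function(k) se_at(1800, k), numeric(1)))
  expect_equal(se_small / se_big, 3, tolerance = 0.2)
})

test_that("degenerate outcome vectors are rejected", {
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "degenerate")
  expect_error(roc_auc(1:4, rep(FALSE, 4)), "degenerate")
  expect_error(roc_auc(1:4, c(TRUE, FALSE, NA, FALSE)), "missing")
})

test_that("discrimination labels follow the prespecified AUROC bands", {
  expect_identical(as.character(discrimination_label(0.900)), "excellent")
  expect_identical(as.character(discrimination_label(0.811)), "good")
  expect_identical(as.character(discrimination_label(0.747)), "moderate")
  expect_identical(as.character(discrimination_label(0.655)), "poor")
  expect_identical(as.character(discrimination_label(0.55)), "very_poor")
  expect_identical(as.character(discrimination_label(0.50)), "chance")
  expect_false(attr(discrimination_label(0.50), "below_chance"))
  lab <- discrimination_label(0.40)
  expect_identical(as.character(lab), "chance")
  expect_true(attr(lab, "below_chance"))
  expect_error(discrimination_label(1.2), "\\[0, 1\\]")
})

test_that("stratified AUC partitions cleanly and flags event-free strata", {
  set.seed(5)
  n <- 200
  y <- runif(n) < 0.25
  s <- rnorm(n, ifelse(y, 1, 0))
  g <- rep(c("a", "b"), length.out = n)
  st <- stratified_auc(s, y, g)
  for (k in c("a", "b")) {
    idx <- g == k
    expect_equal(st[[k]]$auc, roc_auc(s[idx], y[idx])$auc)
  }
  # single stratum reduces to the unstratified analysis
  st1 <- stratified_auc(s, y, rep("all", n))
  expect_equal(st1$all$auc, roc_auc(s, y)$auc)
  # an event-free stratum yields a marker, never a number
  g2 <- ifelse(y, "events_here", "mixed")
  g2[which(!y)[1:30]] <- "events_here"
  st2 <- stratified_auc(s, y, g2)
  expect_s3_class(st2$mixed, "dfu_roc_incalculable")
  expect_false(isTRUE(st2$mixed$calculable))
  expect_s3_class(st2$events_here, "dfu_roc")
})
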