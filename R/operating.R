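# Operating characteristics at a threshold: confusion counts, exact
# binomial CIs, likelihood ratios, Youden index.

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact two-sided interval for a binomial proportion via Beta-quantile
#' inversion: lower bound `qbeta(a/2, x, n - x + 1)` (0 when `x = 0`),
#' upper bound `qbeta(1 - a/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param x number of successes.
#' @param n number of trials (`n >= 1`).
#' @param conf_level confidence level, default 0.95.
#' @return Named numeric: `estimate`, `lower`, `upper`.
#' @examples
#' clopper_pearson(39, 39)  # lower bound ~ 0.91
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n, conf_level > 0, conf_level < 1)
  a <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(estimate = x / n, lower = lower, upper = upper)
}

# Log-method CI for a likelihood ratio. Undefined (NA) when the point
# estimate is 0 or infinite.
.lr_ci <- function(lr, se_log, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (!is.finite(lr) || lr <= 0 || !is.finite(se_log)) {
    return(c(lower = NA_real_, upper = NA_real_))
  }
  c(lower = lr * exp(-z * se_log), upper = lr * exp(z * se_log))
}

#' Operating characteristics from a 2 x 2 confusion table
#'
#' Sensitivity, specificity, predictive values (with exact Clopper-Pearson
#' binomial CIs), likelihood ratios (with log-method CIs) and the Youden
#' index (`sensitivity + specificity - 1`) from confusion counts. Zero
#' denominators for PPV/NPV are reported as `NA` with the matching
#' `*_defined` flag set to `FALSE`, never as errors.
#'
#' @param tp,fp,fn,tn nonnegative integer confusion counts; at least one
#'   positive (`tp + fn >= 1`) and one negative (`fp + tn >= 1`) subject.
#' @param threshold optional label recording the decision rule (e.g. the
#'   cut-off the counts came from).
#' @param conf_level confidence level for all intervals.
#' @return A `dfu_operating_point` list holding the counts, each
#'   proportion with its CI, `lr_pos`/`lr_neg` with CIs, and `youden`.
#'   All proportions are on the 0-1 scale; the print method formats
#'   percentages.
#' @examples
#' operating_point(tp = 34, fp = 76, fn = 5, tn = 227)
#' @export
operating_point <- function(tp, fp, fn, tn, threshold = NA,
                            conf_level = 0.95) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be nonnegative integers")
  }
  if (tp + fn < 1) stop("need at least one positive subject (tp + fn >= 1)")
  if (fp + tn < 1) stop("need at least one negative subject (fp + tn >= 1)")
  sens <- clopper_pearson(tp, tp + fn, conf_level)
  spec <- clopper_pearson(tn, fp + tn, conf_level)
  ppv_defined <- (tp + fp) > 0
  npv_defined <- (fn + tn) > 0
  ppv <- if (ppv_defined) clopper_pearson(tp, tp + fp, conf_level) else
    c(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  npv <- if (npv_defined) clopper_pearson(tn, fn + tn, conf_level) else
    c(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  se_v <- sens[["estimate"]]
  sp_v <- spec[["estimate"]]
  lr_pos <- if (sp_v < 1) se_v / (1 - sp_v) else Inf
  lr_neg <- if (sp_v > 0) (1 - se_v) / sp_v else Inf
  # Simel et al. log-method standard errors
  se_log_pos <- if (tp > 0 && fp > 0) {
    sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
  } else NA_real_
  se_log_neg <- if (fn > 0 && tn > 0) {
    sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
  } else NA_real_
  out <- list(
    threshold = threshold,
    tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn), tn = as.integer(tn),
    sensitivity = se_v, sensitivity_ci = unname(sens[2:3]),
    specificity = sp_v, specificity_ci = unname(spec[2:3]),
    ppv = ppv[["estimate"]], ppv_ci = unname(ppv[2:3]),
    ppv_defined = ppv_defined,
    npv = npv[["estimate"]], npv_ci = unname(npv[2:3]),
    npv_defined = npv_defined,
    lr_pos = lr_pos, lr_pos_ci = unname(.lr_ci(lr_pos, se_log_pos, conf_level)),
    lr_neg = lr_neg, lr_neg_ci = unname(.lr_ci(lr_neg, se_log_neg, conf_level)),
    youden = se_v + sp_v - 1,
    conf_level = conf_level
  )
  class(out) <- "dfu_operating_point"
  out
}

#' @export
print.dfu_operating_point <- function(x, ...) {
  fmt <- function(est, ci) {
    sprintf("%s%% (%s-%s)", .fmt_pct1(est), .fmt_pct1(ci[1]), .fmt_pct1(ci[2]))
  }
  if (!is.na(x$threshold)) {
    cat(sprintf("Operating point at threshold >= %s\n", x$threshold))
  } else {
    cat("Operating point\n")
  }
  cat(sprintf("  counts: tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat("  sensitivity:", fmt(x$sensitivity, x$sensitivity_ci), "\n")
  cat("  specificity:", fmt(x$specificity, x$specificity_ci), "\n")
  cat("  PPV:        ",
      if (x$ppv_defined) fmt(x$ppv, x$ppv_ci) else "undefined", "\n")
  cat("  NPV:        ",
      if (x$npv_defined) fmt(x$npv, x$npv_ci) else "undefined", "\n")
  cat(sprintf("  LR+: %.3g  LR-: %.3g\n", x$lr_pos, x$lr_neg))
  cat(sprintf("  Youden index: %s\n", .fmt_pct1(x$youden)))
  invisible(x)
}

# Flatten an operating point into a one-row data frame (sweep building).
.op_row <- function(op) {
  data.frame(
    threshold = op$threshold,
    tp = op$tp, fp = op$fp, fn = op$fn, tn = op$tn,
    sensitivity = op$sensitivity,
    sens_low = op$sensitivity_ci[1], sens_high = op$sensitivity_ci[2],
    specificity = op$specificity,
    spec_low = op$specificity_ci[1], spec_high = op$specificity_ci[2],
    ppv = op$ppv, ppv_low = op$ppv_ci[1], ppv_high = op$ppv_ci[2],
    npv = op$npv, npv_low = op$npv_ci[1], npv_high = op$npv_ci[2],
    lr_pos = op$lr_pos, lrp_low = op$lr_pos_ci[1], lrp_high = op$lr_pos_ci[2],
    lr_neg = op$lr_neg, lrn_low = op$lr_neg_ci[1], lrn_high = op$lr_neg_ci[2],
    youden = op$youden,
    stringsAsFactors = FALSE
  )
}

#' Operating characteristics at every observed cut-off
#'
#' Sweeps the rule `score >= t` over every distinct observed score `t`,
#' in ascending order, producing one [operating_point()] per threshold.
#'
#' @param scores numeric/ordinal score per patient (higher = higher risk).
#' @param outcomes logical event indicator aligned with `scores`; must
#'   contain at least one event and one non-event.
#' @param conf_level confidence level for all intervals.
#' @return A `dfu_sweep` data frame, one row per threshold, with the
#'   columns of [operating_point()] flattened (`threshold`, counts,
#'   estimates, CI bounds, `youden`).
#' @seealso [youden_best()]
#' @examples
#' coh <- example_cohort()
#' threshold_sweep(saint_elian(coh)$total, coh$major_amputation)
#' @export
threshold_sweep <- function(scores, outcomes, conf_level = 0.95) {
  outcomes <- as.logical(outcomes)
  if (length(scores) != length(outcomes)) stop("length mismatch")
  if (anyNA(scores) || anyNA(outcomes)) stop("missing values are not allowed")
  if (!any(outcomes) || all(outcomes)) {
    stop("degenerate outcome vector: need both events and non-events")
  }
  thr <- sort(unique(scores))
  rows <- lapply(thr, function(t) {
    pos <- scores >= t
    op <- operating_point(
      tp = sum(pos & outcomes), fp = sum(pos & !outcomes),
      fn = sum(!pos & outcomes), tn = sum(!pos & !outcomes),
      threshold = t, conf_level = conf_level
    )
    .op_row(op)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dfu_sweep", "data.frame")
  out
}

#' Pick the Youden-optimal operating point of a sweep
#'
#' Returns the sweep row maximizing the Youden index
#' (`sensitivity + specificity - 1`). Ties are broken toward the lowest
#' threshold, which maximizes sensitivity among the maximizers.
#'
#' @param sweep a `dfu_sweep` from [threshold_sweep()] (rows in ascending
#'   threshold order), or any data frame with `threshold` and `youden`
#'   columns.
#' @return One-row data frame (the selected sweep row).
#' @examples
#' coh <- example_cohort()
#' sw <- threshold_sweep(saint_elian(coh)$total, coh$major_amputation)
#' youden_best(sw)
#' @export
youden_best <- function(sweep) {
  stopifnot(is.data.frame(sweep), nrow(sweep) >= 1,
            all(c("threshold", "youden") %in% names(sweep)))
  sweep <- sweep[order(sweep$threshold), , drop = FALSE]
  best <- which.max(sweep$youden)  # first maximum = lowest threshold
  out <- sweep[best, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cumulative incidence with exact binomial confidence interval
#'
#' Six-month cumulative incidence of major amputation, or of the derived
#' composite "any amputation" (major or minor), with a Clopper-Pearson
#' 95% CI.
#'
#' @param outcomes a [dfu_cohort()]/data frame with `major_amputation` and
#'   `minor_amputation` columns, or a plain logical event vector (in which
#'   case `outcome` is ignored).
#' @param outcome `"major"` or `"any"`.
#' @param conf_level confidence level.
#' @return List: `events`, `n`, `proportion`, `ci_low`, `ci_high`.
#' @examples
#' cumulative_incidence(example_cohort(), "major")
#' @export
cumulative_incidence <- function(outcomes, outcome = c("major", "any"),
                                 conf_level = 0.95) {
  ev <- if (is.data.frame(outcomes)) {
    .dfu_outcome_vector(outcomes, match.arg(outcome))
  } else {
    as.logical(outcomes)
  }
  if (length(ev) < 1L || anyNA(ev)) stop("need a nonempty, complete cohort")
  cp <- clopper_pearson(sum(ev), length(ev), conf_level)
  list(
    events = sum(ev), n = length(ev),
    proportion = cp[["estimate"]],
    ci_low = cp[["lower"]], ci_high = cp[["upper"]]
  )
}
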