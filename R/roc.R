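# Tie-aware empirical ROC curves, AUROC with DeLong variance, and the
# paired DeLong test for correlated curves.

# Placement values (DeLong structural components) via mid-ranks.
# For positives: V10_i = P_hat(X_neg < x_i) + 0.5 P_hat(X_neg = x_i);
# computed as (combined mid-rank - within-group mid-rank) / n_opposite.
.placements <- function(scores, outcomes) {
  pos <- scores[outcomes]
  neg <- scores[!outcomes]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, m = m, n = n)
}

.check_roc_input <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  if (length(scores) != length(outcomes)) stop("length mismatch")
  if (anyNA(scores) || anyNA(outcomes)) stop("missing values are not allowed")
  if (!any(outcomes) || all(outcomes)) {
    stop("degenerate outcome vector: need both events and non-events")
  }
  outcomes
}

#' Empirical ROC curve and AUROC with DeLong variance
#'
#' The AUC is the tie-corrected pair statistic
#' \deqn{AUC = \frac{\#(pos > neg) + \tfrac12\,\#(pos = neg)}{n_{pos}\, n_{neg}},}
#' i.e. the probability that a random event-patient outscores a random
#' non-event patient (ties counted half), which equals the trapezoidal
#' area under the empirical ROC. The standard error comes from the DeLong
#' structural components (placement values): `se^2 = var(V10)/n_pos +
#' var(V01)/n_neg`, and the CI is the normal interval `auc +/- z se`,
#' truncated to [0, 1].
#'
#' ROC points are produced at every distinct observed score `t` for the
#' rule `score >= t`; sensitivity is non-increasing as the threshold
#' rises.
#'
#' @param scores numeric/ordinal risk score per patient (higher = higher
#'   risk).
#' @param outcomes logical event indicator aligned with `scores`; needs at
#'   least one event and one non-event.
#' @param conf_level confidence level for the AUC interval.
#' @return A `dfu_roc` list: `score_levels`, `sensitivity`,
#'   `specificity` (per threshold), `auc`, `se_auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, `conf_level`.
#' @examples
#' coh <- example_cohort()
#' roc_auc(saint_elian(coh)$total, coh$major_amputation)
#' @export
roc_auc <- function(scores, outcomes, conf_level = 0.95) {
  outcomes <- .check_roc_input(scores, outcomes)
  pl <- .placements(scores, outcomes)
  auc <- mean(pl$v10)
  s10 <- if (pl$m > 1) stats::var(pl$v10) else 0
  s01 <- if (pl$n > 1) stats::var(pl$v01) else 0
  se <- sqrt(s10 / pl$m + s01 / pl$n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  thr <- sort(unique(scores))
  pos <- scores[outcomes]; neg <- scores[!outcomes]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  out <- list(
    score_levels = thr, sensitivity = sens, specificity = spec,
    auc = auc, se_auc = se,
    ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
    n_pos = pl$m, n_neg = pl$n, conf_level = conf_level
  )
  class(out) <- "dfu_roc"
  out
}

#' @export
print.dfu_roc <- function(x, ...) {
  cat(sprintf(
    "AUROC %.3f (%d%% CI %.3f-%.3f), %d events / %d non-events [%s]\n",
    x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
    x$n_pos, x$n_neg, as.character(discrimination_label(x$auc))
  ))
  invisible(x)
}

#' DeLong test for two correlated (paired) ROC curves
#'
#' Compares the AUCs of two scores measured on the same patients. The
#' variance of the AUC difference uses the DeLong placement-value
#' covariance structure: with placement vectors \eqn{V^A_{10}, V^B_{10}}
#' over the \eqn{m} events and \eqn{V^A_{01}, V^B_{01}} over the \eqn{n}
#' non-events,
#' \deqn{var(\Delta) = \frac{s_{10}^A + s_{10}^B - 2 s_{10}^{AB}}{m}
#'   + \frac{s_{01}^A + s_{01}^B - 2 s_{01}^{AB}}{n},}
#' and the two-sided p-value comes from the standard normal reference.
#' When the variance is zero and the AUCs are equal (e.g. identical score
#' vectors) the p-value is 1.
#'
#' @param scores_a,scores_b two score vectors aligned to the same
#'   patients.
#' @param outcomes logical event indicator; needs at least one event and
#'   one non-event.
#' @param conf_level confidence level for the CI on the AUC difference.
#' @return A `dfu_delong` list: `auc_a`, `auc_b`, `delta_auc`
#'   (`auc_a - auc_b`), `se`, `ci_low`, `ci_high`, `p_value`,
#'   `covariance` (the paired covariance term `s10_ab/m + s01_ab/n`).
#' @examples
#' coh <- example_cohort()
#' delong_paired_test(saint_elian(coh)$total, sinbad_score(coh),
#'                    coh$major_amputation)
#' @export
delong_paired_test <- function(scores_a, scores_b, outcomes,
                               conf_level = 0.95) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must be aligned to the same patients")
  }
  outcomes <- .check_roc_input(scores_a, outcomes)
  pa <- .placements(scores_a, outcomes)
  pb <- .placements(scores_b, outcomes)
  m <- pa$m; n <- pa$n
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  delta <- auc_a - auc_b
  s10 <- function(u, v) if (m > 1) stats::cov(u, v) else 0
  s01 <- function(u, v) if (n > 1) stats::cov(u, v) else 0
  var_delta <- (s10(pa$v10, pa$v10) + s10(pb$v10, pb$v10) -
                  2 * s10(pa$v10, pb$v10)) / m +
               (s01(pa$v01, pa$v01) + s01(pb$v01, pb$v01) -
                  2 * s01(pa$v01, pb$v01)) / n
  var_delta <- max(var_delta, 0)
  covar <- s10(pa$v10, pb$v10) / m + s01(pa$v01, pb$v01) / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (var_delta == 0) {
    p <- if (delta == 0) 1 else 0
    se <- 0
  } else {
    se <- sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(delta) / se)
  }
  out <- list(
    auc_a = auc_a, auc_b = auc_b, delta_auc = delta, se = se,
    ci_low = delta - z * se, ci_high = delta + z * se,
    p_value = p, covariance = covar, conf_level = conf_level
  )
  class(out) <- "dfu_delong"
  out
}

#' @export
print.dfu_delong <- function(x, ...) {
  cat(sprintf(
    "Paired DeLong test: AUC %.3f vs %.3f, dAUC %.3f (%.3f to %.3f), p %s\n",
    x$auc_a, x$auc_b, x$delta_auc, x$ci_low, x$ci_high,
    format_p(x$p_value)
  ))
  invisible(x)
}

#' Per-stratum AUROC with explicit incalculable markers
#'
#' Computes [roc_auc()] separately within each stratum (e.g. care
#' setting). A stratum with zero events or zero non-events -- such as an
#' outpatient stratum in which no amputation occurred -- yields an
#' explicit incalculable marker (a `dfu_roc_incalculable` list), never a
#' number.
#'
#' @param scores risk score per patient.
#' @param outcomes logical event indicator.
#' @param strata stratum label per patient.
#' @param conf_level confidence level.
#' @return Named list (one element per stratum level), each a `dfu_roc`
#'   or a `dfu_roc_incalculable` with fields `calculable = FALSE`,
#'   `n_pos`, `n_neg`, `n`.
#' @examples
#' coh <- example_cohort()
#' stratified_auc(saint_elian(coh)$total, coh$major_amputation,
#'                ifelse(coh$inpatient, "inpatient", "outpatient"))
#' @export
stratified_auc <- function(scores, outcomes, strata, conf_level = 0.95) {
  outcomes <- as.logical(outcomes)
  if (length(strata) != length(scores) ||
      length(scores) != length(outcomes)) {
    stop("`scores`, `outcomes` and `strata` must be aligned")
  }
  strata <- as.factor(strata)
  out <- lapply(levels(strata), function(s) {
    idx <- strata == s
    y <- outcomes[idx]
    if (!any(y) || all(y)) {
      structure(
        list(calculable = FALSE, n_pos = sum(y), n_neg = sum(!y),
             n = sum(idx)),
        class = "dfu_roc_incalculable"
      )
    } else {
      roc_auc(scores[idx], y, conf_level)
    }
  })
  names(out) <- levels(strata)
  class(out) <- "dfu_stratified_auc"
  out
}

#' @export
print.dfu_roc_incalculable <- function(x, ...) {
  cat(sprintf(
    "AUROC not calculable: %d events / %d non-events in stratum (n = %d)\n",
    x$n_pos, x$n_neg, x$n
  ))
  invisible(x)
}

#' @export
print.dfu_stratified_auc <- function(x, ...) {
  for (s in names(x)) {
    cat(sprintf("%-12s ", s))
    print(x[[s]])
  }
  invisible(x)
}

#' Qualitative discrimination band of an AUROC
#'
#' Prespecified interpretation bands: 0.50 chance-level; 0.51-0.59 very
#' poor; 0.60-0.69 poor; 0.70-0.79 moderate; 0.80-0.89 good; >= 0.90
#' excellent. Values below 0.50 are labelled `chance` with a
#' `below_chance` attribute set to `TRUE`.
#'
#' @param auc a single AUC in [0, 1].
#' @return Factor with levels `chance`, `very_poor`, `poor`, `moderate`,
#'   `good`, `excellent` (and attribute `below_chance`).
#' @examples
#' discrimination_label(0.900)
#' discrimination_label(0.747)
#' @export
discrimination_label <- function(auc) {
  stopifnot(length(auc) == 1, is.finite(auc))
  if (auc < 0 || auc > 1) stop("`auc` must lie in [0, 1]")
  lab <- if (auc <= 0.5) "chance"
  else if (auc < 0.6) "very_poor"
  else if (auc < 0.7) "poor"
  else if (auc < 0.8) "moderate"
  else if (auc < 0.9) "good"
  else "excellent"
  structure(
    factor(lab, levels = c("chance", "very_poor", "poor", "moderate",
                           "good", "excellent")),
    below_chance = auc < 0.5
  )
}
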