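# Monte-Carlo power for a paired AUC comparison.

#' Simulation-based power of a paired DeLong AUC comparison
#'
#' Estimates the power of the two-sided paired DeLong test to detect a
#' difference between two correlated scores at given AUCs and sample
#' sizes. Each replicate draws correlated binormal score pairs: within
#' each outcome group the two scores are bivariate normal with unit
#' variances and correlation `correlation`; the event-group mean of score
#' \eqn{k} is \eqn{\mu_k = \sqrt{2}\,\Phi^{-1}(AUC_k)}, which yields the
#' requested AUC under the equal-variance binormal model. The paired
#' DeLong test is applied to every replicate and power is the fraction of
#' two-sided p-values below `alpha`, with a Clopper-Pearson Monte-Carlo
#' CI.
#'
#' @param auc_a,auc_b target AUCs, each in [0.5, 1).
#' @param n_pos,n_neg events and non-events per replicate.
#' @param correlation within-patient correlation of the two scores,
#'   in (-1, 1).
#' @param alpha two-sided significance level, in (0, 1).
#' @param n_reps number of Monte-Carlo replicates (>= 100).
#' @param seed integer seed; the estimate is deterministic given the
#'   seed.
#' @return List: `power`, `ci_low`, `ci_high` (Monte-Carlo CI),
#'   `rejections`, `n_reps`.
#' @examples
#' power_paired_auc(0.90, 0.75, n_pos = 39, n_neg = 303,
#'                  correlation = 0.5, n_reps = 200, seed = 7)
#' @export
power_paired_auc <- function(auc_a, auc_b, n_pos, n_neg,
                             correlation = 0.5, alpha = 0.05,
                             n_reps = 1000, seed = 1L) {
  stopifnot(
    auc_a >= 0.5, auc_a < 1, auc_b >= 0.5, auc_b < 1,
    n_pos >= 2, n_neg >= 2, n_reps >= 100,
    alpha > 0, alpha < 1
  )
  if (abs(correlation) >= 1) {
    stop("`correlation` must lie strictly within (-1, 1)")
  }
  mu_a <- sqrt(2) * stats::qnorm(auc_a)
  mu_b <- sqrt(2) * stats::qnorm(auc_b)
  rho_c <- sqrt(1 - correlation^2)
  set.seed(as.integer(seed))
  rej <- 0L
  y <- rep(c(TRUE, FALSE), times = c(n_pos, n_neg))
  for (r in seq_len(n_reps)) {
    e1 <- stats::rnorm(n_pos + n_neg)
    e2 <- correlation * e1 + rho_c * stats::rnorm(n_pos + n_neg)
    shift <- c(rep(1, n_pos), rep(0, n_neg))
    sa <- mu_a * shift + e1
    sb <- mu_b * shift + e2
    p <- delong_paired_test(sa, sb, y)$p_value
    if (p < alpha) rej <- rej + 1L
  }
  cp <- clopper_pearson(rej, n_reps)
  list(
    power = rej / n_reps, ci_low = cp[["lower"]], ci_high = cp[["upper"]],
    rejections = rej, n_reps = n_reps
  )
}
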