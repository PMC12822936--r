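# Banded incidence tables and relative risks with robust variance.

#' Build a K x 2 event/no-event contingency table over risk bands
#'
#' Counts events and non-events per risk band, keeping empty bands (zero
#' rows) and recording which band is the lowest-theoretical-risk
#' reference.
#'
#' @param bands factor (ideally ordered) of risk bands, one per patient.
#' @param outcomes logical event indicator aligned with `bands`.
#' @param reference band label to use as reference; defaults to the first
#'   level. Must be one of the levels of `bands`.
#' @return A `dfu_contingency` list: `band_labels`, `events`, `nonevents`
#'   (aligned integer vectors) and `reference` (label).
#' @examples
#' coh <- example_cohort()
#' build_contingency(collapse_risk_category("mw", mw_grade(coh)),
#'                   coh$major_amputation)
#' @export
build_contingency <- function(bands, outcomes, reference = NULL) {
  if (!is.factor(bands)) bands <- factor(bands)
  outcomes <- as.logical(outcomes)
  if (length(bands) != length(outcomes) || length(bands) < 1L) {
    stop("`bands` and `outcomes` must be aligned, nonempty vectors")
  }
  if (anyNA(bands) || anyNA(outcomes)) stop("missing values are not allowed")
  if (is.null(reference)) reference <- levels(bands)[1L]
  if (!reference %in% levels(bands)) {
    stop("reference band ", sQuote(reference), " is not a band label")
  }
  tab <- table(bands, factor(outcomes, levels = c(TRUE, FALSE)))
  out <- list(
    band_labels = levels(bands),
    events = as.integer(tab[, 1L]),
    nonevents = as.integer(tab[, 2L]),
    reference = reference
  )
  class(out) <- "dfu_contingency"
  out
}

#' @export
print.dfu_contingency <- function(x, ...) {
  n <- x$events + x$nonevents
  pct <- ifelse(n > 0, 100 * x$events / n, NA_real_)
  df <- data.frame(
    band = paste0(x$band_labels,
                  ifelse(x$band_labels == x$reference, " (ref)", "")),
    events = x$events, nonevents = x$nonevents,
    incidence = ifelse(is.na(pct), "-", sprintf("%.1f%%", pct)),
    stringsAsFactors = FALSE
  )
  print(df, row.names = FALSE)
  invisible(x)
}

.z975 <- 1.959964

#' Relative risk of a band versus the reference, with robust variance
#'
#' Risk ratio of one band against the reference band of a
#' [build_contingency()] table, matching a Poisson regression with robust
#' (sandwich) variance: for a saturated model on a categorical exposure
#' the estimator is the closed-form ratio of band incidences
#' \eqn{(e_b/n_b) / (e_r/n_r)} and the robust standard error of the log RR
#' is \eqn{\sqrt{1/e_b - 1/n_b + 1/e_r - 1/n_r}}. The 95% CI is
#' \eqn{\exp(\log RR \pm 1.959964\, se)} and the p-value comes from the
#' two-sided normal reference on the log scale.
#'
#' When either the reference band or the comparison band has zero events
#' the estimate is flagged not-calculable (`calculable = FALSE`) rather
#' than raising an error.
#'
#' @param table a `dfu_contingency` from [build_contingency()].
#' @param band band label to compare against the reference; must differ
#'   from the reference.
#' @return A `dfu_rr` list: `band`, `reference`, `rr`, `ci_low`,
#'   `ci_high`, `p_value`, `calculable`.
#' @examples
#' tab <- build_contingency(
#'   factor(rep(c("1-3", "4-5"), times = c(194, 148)), ordered = TRUE),
#'   rep(c(TRUE, FALSE, TRUE, FALSE), times = c(3, 191, 36, 112))
#' )
#' risk_ratio(tab, "4-5")  # RR 15.7, as from robust Poisson regression
#' @export
risk_ratio <- function(table, band) {
  stopifnot(inherits(table, "dfu_contingency"))
  if (identical(band, table$reference)) {
    stop("`band` must differ from the reference band")
  }
  i <- match(band, table$band_labels)
  if (is.na(i)) stop("unknown band ", sQuote(band))
  r <- match(table$reference, table$band_labels)
  e_b <- table$events[i]; n_b <- e_b + table$nonevents[i]
  e_r <- table$events[r]; n_r <- e_r + table$nonevents[r]
  out <- list(
    band = band, reference = table$reference,
    rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p_value = NA_real_, calculable = FALSE
  )
  if (e_r > 0L && e_b > 0L && n_b > 0L && n_r > 0L) {
    rr <- (e_b / n_b) / (e_r / n_r)
    se <- sqrt(1 / e_b - 1 / n_b + 1 / e_r - 1 / n_r)
    out$rr <- rr
    out$ci_low <- exp(log(rr) - .z975 * se)
    out$ci_high <- exp(log(rr) + .z975 * se)
    out$p_value <- 2 * stats::pnorm(-abs(log(rr) / se))
    out$calculable <- TRUE
  }
  class(out) <- "dfu_rr"
  out
}

#' @export
print.dfu_rr <- function(x, ...) {
  if (!x$calculable) {
    cat(sprintf("RR %s vs %s: NC (not calculable: no events in a band)\n",
                x$band, x$reference))
  } else {
    cat(sprintf("RR %s vs %s: %.3g (95%% CI %.3g-%.3g), p %s\n",
                x$band, x$reference, x$rr, x$ci_low, x$ci_high,
                format_p(x$p_value)))
  }
  invisible(x)
}

# All non-reference bands of a table, as a data frame.
.risk_ratio_table <- function(tab) {
  bands <- setdiff(tab$band_labels, tab$reference)
  rows <- lapply(bands, function(b) {
    rr <- risk_ratio(tab, b)
    data.frame(
      band = b, reference = tab$reference, rr = rr$rr,
      ci_low = rr$ci_low, ci_high = rr$ci_high, p_value = rr$p_value,
      calculable = rr$calculable, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Format a p-value for report output
#'
#' Values below 0.001 print as `"<0.001"`; otherwise three decimals.
#'
#' @param p numeric p-value(s).
#' @return Character vector.
#' @examples
#' format_p(c(0.0532, 2e-6))
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' Round half away from zero
#'
#' Report-style rounding: halves round away from zero at the requested
#' number of decimals (so 21.25 at one decimal prints 21.3), unlike base
#' `round()`'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Numeric vector.
#' @examples
#' round_half_up(21.25, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# Percentage formatting per report style: one decimal, trailing ".0"
# dropped (e.g. 91, 74.9).
.fmt_pct1 <- function(x) {
  s <- sprintf("%.1f", round_half_up(100 * x, 1))
  sub("\\.0$", "", s)
}
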