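# The full external-validation analysis, packaged as a single classed
# object in the classic R modelling idiom.

.dfu_systems <- c("mw", "ut", "sinbad", "se")

# Risk bands for the four systems from a score table + wound records.
.dfu_bands <- function(cohort) {
  ut <- ut_classify(cohort)
  list(
    mw = collapse_risk_category("mw", mw_grade(cohort)),
    ut = collapse_risk_category("ut", ut),
    sinbad = collapse_risk_category("sinbad", sinbad_score(cohort)),
    se = collapse_risk_category("se", saint_elian(cohort))
  )
}

#' Externally validate the four classification systems on a cohort
#'
#' Runs the complete validation analysis of the Meggitt-Wagner,
#' University of Texas, SINBAD and Saint Elian systems against a binary
#' amputation outcome:
#' \itemize{
#'   \item cumulative incidence of major and of any amputation, with
#'     exact binomial CIs;
#'   \item banded incidence and relative risks (robust-variance Poisson
#'     estimator) per system, lowest-risk band as reference, with
#'     not-calculable flags where a band has no events;
#'   \item AUROC with DeLong CIs for all seven score variants
#'     ([dfu_scores()]), overall and stratified by care setting, with
#'     explicit incalculable markers for event-free strata;
#'   \item all pairwise DeLong comparisons among the seven variants;
#'   \item full threshold sweeps with exact binomial CIs, and the
#'     Youden-optimal cut-off per variant.
#' }
#' The analysis is deterministic given the cohort: rerunning it (or
#' serializing via [as_report_json()]) reproduces identical numbers.
#'
#' @param cohort a [dfu_cohort()].
#' @param outcome `"major"` (major amputation, the primary outcome) or
#'   `"any"` (the derived composite of major or minor amputation).
#' @param conf_level confidence level used throughout.
#' @return An object of class `dfu_validation`; see
#'   [print.dfu_validation()], [summary.dfu_validation()],
#'   [plot.dfu_validation()], [predict.dfu_validation()],
#'   [as_report_json()].
#' @examples
#' fit <- dfu_validation(example_cohort())
#' fit
#' summary(fit)
#' @export
dfu_validation <- function(cohort, outcome = c("major", "any"),
                           conf_level = 0.95) {
  stopifnot(is.data.frame(cohort))
  outcome <- match.arg(outcome)
  y <- .dfu_outcome_vector(cohort, outcome)
  if (anyNA(y)) stop("outcome columns must be complete")
  degenerate <- !any(y) || all(y)
  if (degenerate) {
    warning("degenerate cohort (no events or no non-events): ",
            "discrimination analyses are marked incalculable")
  }
  scores <- dfu_scores(cohort)
  strata <- factor(ifelse(cohort$inpatient, "inpatient", "outpatient"),
                   levels = c("inpatient", "outpatient"))

  incidence <- list(
    major = cumulative_incidence(cohort, "major", conf_level),
    any = cumulative_incidence(cohort, "any", conf_level)
  )

  bands <- .dfu_bands(cohort)
  band_analysis <- lapply(bands, function(b) {
    tab <- build_contingency(b, y)
    list(table = tab, rr = .risk_ratio_table(tab))
  })

  roc <- lapply(scores, function(s) {
    if (degenerate) {
      structure(list(calculable = FALSE, n_pos = sum(y), n_neg = sum(!y),
                     n = length(y)),
                class = "dfu_roc_incalculable")
    } else {
      roc_auc(s, y, conf_level)
    }
  })
  stratified <- if (degenerate) NULL else {
    lapply(scores, function(s) stratified_auc(s, y, strata, conf_level))
  }

  pairwise <- NULL
  sweeps <- NULL
  youden <- NULL
  if (!degenerate) {
    combos <- utils::combn(.dfu_score_variants, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
      a <- combos[1, k]; b <- combos[2, k]
      d <- delong_paired_test(scores[[a]], scores[[b]], y, conf_level)
      data.frame(
        score_a = a, score_b = b, auc_a = d$auc_a, auc_b = d$auc_b,
        delta_auc = d$delta_auc, ci_low = d$ci_low, ci_high = d$ci_high,
        p_value = d$p_value, stringsAsFactors = FALSE
      )
    }))
    sweeps <- lapply(scores, function(s) threshold_sweep(s, y, conf_level))
    youden <- do.call(rbind, lapply(.dfu_score_variants, function(v) {
      cbind(score = v, youden_best(sweeps[[v]]), stringsAsFactors = FALSE)
    }))
  }

  out <- list(
    n = nrow(cohort), outcome = outcome, conf_level = conf_level,
    provenance = attr(cohort, "provenance"),
    degenerate = degenerate,
    incidence = incidence,
    bands = band_analysis,
    roc = roc,
    stratified = stratified,
    pairwise = pairwise,
    sweeps = sweeps,
    youden = youden,
    scores = scores,
    outcomes = y,
    strata = strata,
    call = match.call()
  )
  class(out) <- "dfu_validation"
  out
}

# AUROC summary table across the seven variants (and strata).
.roc_table <- function(x) {
  rows <- lapply(.dfu_score_variants, function(v) {
    r <- x$roc[[v]]
    if (inherits(r, "dfu_roc_incalculable")) {
      return(data.frame(score = v, auc = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, label = "NC",
                        stringsAsFactors = FALSE))
    }
    data.frame(
      score = v, auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
      label = as.character(discrimination_label(r$auc)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
print.dfu_validation <- function(x, ...) {
  cat(sprintf(
    "External validation of 4 DFU classification systems (n = %d, outcome: %s amputation)\n",
    x$n, x$outcome
  ))
  inc <- x$incidence$major
  cat(sprintf(
    "Major amputation: %d/%d = %s%% (95%% CI %s-%s)\n",
    inc$events, inc$n, .fmt_pct1(inc$proportion),
    .fmt_pct1(inc$ci_low), .fmt_pct1(inc$ci_high)
  ))
  inc <- x$incidence$any
  cat(sprintf(
    "Any amputation:   %d/%d = %s%%\n", inc$events, inc$n,
    .fmt_pct1(inc$proportion)
  ))
  if (x$degenerate) {
    cat("Degenerate outcome vector: discrimination not calculable.\n")
    return(invisible(x))
  }
  cat("\nAUROC (DeLong 95% CI):\n")
  tab <- .roc_table(x)
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-15s %.3f (%.3f-%.3f)  %s\n", tab$score[i],
                tab$auc[i], tab$ci_low[i], tab$ci_high[i], tab$label[i]))
  }
  if (!is.null(x$youden)) {
    cat("\nYouden-optimal cut-offs (score >= threshold):\n")
    for (i in seq_len(nrow(x$youden))) {
      r <- x$youden[i, ]
      cat(sprintf(
        "  %-15s >= %-3s sens %s%%, spec %s%%, Youden %s\n",
        r$score, format(r$threshold), .fmt_pct1(r$sensitivity),
        .fmt_pct1(r$specificity), .fmt_pct1(r$youden)
      ))
    }
  }
  invisible(x)
}

#' Summarize a validation analysis
#'
#' Prints the full report: incidence, banded relative risks per system,
#' the AUROC table (overall and per care-setting stratum, with
#' not-calculable markers), all pairwise DeLong comparisons and the
#' Youden-optimal operating points.
#'
#' @param object a [dfu_validation()] object.
#' @param ... unused.
#' @return `object`, invisibly.
#' @export
summary.dfu_validation <- function(object, ...) {
  x <- object
  print(x)
  if (x$degenerate) return(invisible(x))
  sysnames <- c(mw = "Meggitt-Wagner", ut = "University of Texas",
                sinbad = "SINBAD", se = "Saint Elian")
  cat("\nBanded incidence and relative risks:\n")
  for (s in .dfu_systems) {
    cat(sprintf("-- %s --\n", sysnames[[s]]))
    print(x$bands[[s]]$table)
    rr <- x$bands[[s]]$rr
    for (i in seq_len(nrow(rr))) {
      if (!rr$calculable[i]) {
        cat(sprintf("  RR %s vs %s: NC\n", rr$band[i], rr$reference[i]))
      } else {
        cat(sprintf("  RR %s vs %s: %.3g (95%% CI %.3g-%.3g), p %s\n",
                    rr$band[i], rr$reference[i], rr$rr[i], rr$ci_low[i],
                    rr$ci_high[i], format_p(rr$p_value[i])))
      }
    }
  }
  if (!is.null(x$stratified)) {
    cat("\nAUROC by care setting:\n")
    for (v in .dfu_score_variants) {
      st <- x$stratified[[v]]
      cat(sprintf("  %-15s", v))
      parts <- vapply(names(st), function(s) {
        r <- st[[s]]
        if (inherits(r, "dfu_roc_incalculable")) {
          sprintf("%s: NC (0 events)", s)
        } else {
          sprintf("%s: %.3f (%.3f-%.3f)", s, r$auc, r$ci_low, r$ci_high)
        }
      }, character(1))
      cat(paste(parts, collapse = "   "), "\n")
    }
  }
  cat("\nPairwise DeLong comparisons (delta AUC = A - B):\n")
  pw <- x$pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf(
      "  %-15s vs %-15s %+0.3f (%+0.3f to %+0.3f), p %s\n",
      pw$score_a[i], pw$score_b[i], pw$delta_auc[i], pw$ci_low[i],
      pw$ci_high[i], format_p(pw$p_value[i])
    ))
  }
  invisible(x)
}

#' Plot the ROC curves of a validation analysis
#'
#' Draws the empirical ROC curves of the seven score variants with AUCs
#' in the legend; the diagonal marks chance discrimination.
#'
#' @param x a [dfu_validation()] object.
#' @param variants which score variants to draw; defaults to all seven.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dfu_validation <- function(x, variants = .dfu_score_variants, ...) {
  if (x$degenerate) stop("nothing to plot: degenerate outcome vector")
  variants <- match.arg(variants, .dfu_score_variants, several.ok = TRUE)
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey50",
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  cols <- grDevices::hcl.colors(length(variants), "Dark 3")
  legend_txt <- character(length(variants))
  for (i in seq_along(variants)) {
    r <- x$roc[[variants[i]]]
    fpr <- c(1, 1 - r$specificity, 0)
    tpr <- c(1, r$sensitivity, 0)
    graphics::lines(fpr, tpr, type = "s", col = cols[i], lwd = 2)
    legend_txt[i] <- sprintf("%s (AUC %.3f)", variants[i], r$auc)
  }
  graphics::legend("bottomright", legend = legend_txt, col = cols,
                   lwd = 2, cex = 0.8, bty = "n")
  invisible(x)
}

#' Score and band new wound records with a fitted validation's systems
#'
#' Applies the four classification systems to new wound records,
#' returning either the seven score variants or the collapsed risk bands
#' together with the Youden-optimal high-risk flags selected on the
#' validation cohort.
#'
#' @param object a [dfu_validation()] object.
#' @param newdata a [dfu_cohort()] or data frame of wound records.
#' @param type `"scores"` for the seven score variants, `"bands"` for
#'   the collapsed risk bands plus `high_risk_*` indicators
#'   (`score >= Youden-optimal threshold`).
#' @param ... unused.
#' @return Data frame, one row per record.
#' @export
predict.dfu_validation <- function(object, newdata,
                                   type = c("scores", "bands"), ...) {
  type <- match.arg(type)
  sc <- dfu_scores(newdata)
  if (type == "scores") return(sc)
  bands <- .dfu_bands(newdata)
  out <- data.frame(
    mw_band = bands$mw, ut_band = bands$ut, sinbad_band = bands$sinbad,
    se_band = bands$se
  )
  if (!is.null(object$youden)) {
    for (v in .dfu_score_variants) {
      thr <- object$youden$threshold[object$youden$score == v]
      out[[paste0("high_risk_", v)]] <- sc[[v]] >= thr
    }
  }
  out
}

# Plain-list view of the analysis, for JSON serialization.
.validation_as_list <- function(x) {
  strat <- NULL
  if (!is.null(x$stratified)) {
    strat <- lapply(x$stratified, function(st) {
      lapply(st, function(r) {
        if (inherits(r, "dfu_roc_incalculable")) {
          list(calculable = FALSE, n_pos = r$n_pos, n_neg = r$n_neg,
               n = r$n)
        } else {
          list(calculable = TRUE, auc = r$auc, se = r$se_auc,
               ci_low = r$ci_low, ci_high = r$ci_high,
               n_pos = r$n_pos, n_neg = r$n_neg)
        }
      })
    })
  }
  list(
    schema = "dfuscore/report/v1",
    n = x$n, outcome = x$outcome, conf_level = x$conf_level,
    provenance = x$provenance,
    degenerate = x$degenerate,
    incidence = x$incidence,
    bands = lapply(x$bands, function(b) {
      list(
        band_labels = b$table$band_labels, events = b$table$events,
        nonevents = b$table$nonevents, reference = b$table$reference,
        rr = b$rr
      )
    }),
    roc = .roc_table(x),
    stratified = strat,
    pairwise = x$pairwise,
    youden = x$youden,
    sweeps = if (!is.null(x$sweeps)) {
      lapply(x$sweeps, function(s) as.data.frame(s))
    }
  )
}

#' Serialize a validation analysis to JSON
#'
#' Machine-readable twin of the printed report: every number in the
#' human-readable tables appears here unrounded (formatting is the only
#' lossy step). Serialization is deterministic: the same analysis always
#' yields byte-identical JSON.
#'
#' @param x a [dfu_validation()] object.
#' @param pretty pretty-print the JSON?
#' @return A JSON string (class `json`).
#' @seealso [write_report()]
#' @export
as_report_json <- function(x, pretty = TRUE) {
  stopifnot(inherits(x, "dfu_validation"))
  jsonlite::toJSON(.validation_as_list(x), auto_unbox = TRUE,
                   digits = NA, na = "null", pretty = pretty)
}

#' Write the JSON report of a validation analysis to a file
#'
#' @param x a [dfu_validation()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  writeLines(as_report_json(x), path, useBytes = TRUE)
  invisible(path)
}
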