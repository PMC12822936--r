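# Typed cohort representation: one row per patient, closed enum vocabularies.

.dfu_enum_levels <- list(
  depth            = c("intact", "superficial", "tendon_capsule", "bone_joint"),
  gangrene         = c("none", "localized", "extensive"),
  infection_idsa   = c("none", "mild", "moderate", "severe"),
  ischemia_grade   = c("none", "mild", "moderate", "severe"),
  neuropathy_grade = c("none", "diminished", "lops", "charcot"),
  edema_grade      = c("none", "perilesional", "unilateral", "bilateral"),
  site_region      = c("forefoot", "midfoot", "hindfoot"),
  se_location      = c("phalangeal", "metatarsal", "tarsal"),
  se_topography    = c("dorsal_or_plantar", "lateral_or_medial", "two_or_more"),
  se_zones         = c("one", "two", "whole_foot"),
  healing_phase    = c("epithelialization", "granulation", "inflammatory")
)

.dfu_wound_cols <- c(
  "patient_id", "depth", "osteomyelitis_or_abscess", "gangrene",
  "infection_idsa", "ischemia_grade", "neuropathy_grade", "edema_grade",
  "site_region", "se_location", "se_topography", "se_zones",
  "area_cm2", "healing_phase"
)
.dfu_outcome_cols <- c(
  "major_amputation", "minor_amputation", "inpatient", "follow_up_months"
)
.dfu_logical_cols <- c(
  "osteomyelitis_or_abscess", "major_amputation", "minor_amputation",
  "inpatient"
)
.dfu_numeric_cols <- c("area_cm2", "follow_up_months")
.dfu_cols <- c(.dfu_wound_cols, .dfu_outcome_cols)

#' Construct a typed diabetic-foot cohort
#'
#' Builds a `dfu_cohort` from a data frame holding one wound assessment and
#' one outcome record per patient. Enum columns use closed lower-snake-case
#' vocabularies; unknown tokens are hard errors (never coerced), as are
#' missing mandatory columns and duplicated patient identifiers. Soft
#' eligibility rules (minimum follow-up, area consistency) are *not*
#' enforced here; see [validate_cohort()], which reports them as data.
#'
#' Required columns and levels:
#' \describe{
#'   \item{patient_id}{unique opaque identifier}
#'   \item{depth}{`intact`, `superficial`, `tendon_capsule`, `bone_joint` —
#'     deepest tissue reached}
#'   \item{osteomyelitis_or_abscess}{logical; deep infection qualifying
#'     Wagner grade 3}
#'   \item{gangrene}{`none`, `localized` (toes/forefoot), `extensive`
#'     (whole foot)}
#'   \item{infection_idsa}{IDSA severity `none` < `mild` < `moderate` <
#'     `severe`}
#'   \item{ischemia_grade}{`none` < `mild` < `moderate` < `severe`, from
#'     Doppler waveform assessment}
#'   \item{neuropathy_grade}{`none` < `diminished` < `lops` (loss of
#'     protective sensation) < `charcot`}
#'   \item{edema_grade}{`none` < `perilesional` < `unilateral` <
#'     `bilateral`}
#'   \item{site_region}{`forefoot`, `midfoot`, `hindfoot`}
#'   \item{se_location}{Saint Elian anatomical location: `phalangeal`,
#'     `metatarsal`, `tarsal`}
#'   \item{se_topography}{`dorsal_or_plantar`, `lateral_or_medial`,
#'     `two_or_more`}
#'   \item{se_zones}{affected regions: `one`, `two`, `whole_foot`}
#'   \item{area_cm2}{nonnegative ulcer area in square centimetres}
#'   \item{healing_phase}{`epithelialization`, `granulation`,
#'     `inflammatory`}
#'   \item{major_amputation}{logical; any amputation above the ankle,
#'     ipsilateral, within follow-up}
#'   \item{minor_amputation}{logical; toe or transmetatarsal level}
#'   \item{inpatient}{logical; care setting at the index encounter}
#'   \item{follow_up_months}{nonnegative; eligibility requires >= 6}
#' }
#'
#' @param data data frame with the columns above (extra columns are carried
#'   through unchanged, e.g. an opaque covariate bag).
#' @param provenance free-text label recording where the cohort came from
#'   (e.g. `"real"` or `"synthetic seed=11"`).
#' @return A `dfu_cohort` (a data frame subclass) with a `provenance`
#'   attribute.
#' @seealso [validate_cohort()], [example_cohort()], [simulate_cohort()]
#' @examples
#' coh <- example_cohort()
#' nrow(coh)
#' attr(coh, "provenance")
#' @export
dfu_cohort <- function(data, provenance = "real") {
  if (!is.data.frame(data)) stop("`data` must be a data frame")
  miss <- setdiff(.dfu_cols, names(data))
  if (length(miss) > 0L) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(data) < 1L) stop("a cohort must contain at least one record")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data <- data[, c(.dfu_cols, setdiff(names(data), .dfu_cols)), drop = FALSE]
  data$patient_id <- as.character(data$patient_id)
  for (col in names(.dfu_enum_levels)) {
    v <- as.character(data[[col]])
    bad <- !is.na(v) & !(v %in% .dfu_enum_levels[[col]])
    if (any(bad)) {
      stop(sprintf(
        "unknown token(s) in column '%s' at row(s) %s: %s",
        col, paste(which(bad), collapse = ", "),
        paste(sQuote(unique(v[bad])), collapse = ", ")
      ))
    }
    data[[col]] <- v
  }
  for (col in .dfu_logical_cols) {
    if (!is.logical(data[[col]])) {
      stop("column '", col, "' must be logical")
    }
  }
  for (col in .dfu_numeric_cols) {
    if (!is.numeric(data[[col]])) {
      stop("column '", col, "' must be numeric")
    }
  }
  ids <- data$patient_id[!is.na(data$patient_id)]
  if (anyDuplicated(ids) > 0L) {
    stop("patient_id must be unique within a cohort")
  }
  rownames(data) <- NULL
  attr(data, "provenance") <- as.character(provenance)[1L]
  class(data) <- c("dfu_cohort", "data.frame")
  data
}

#' @export
print.dfu_cohort <- function(x, ...) {
  grp <- table(outcome_groups(x))
  cat(sprintf(
    "<dfu_cohort> %d patients (provenance: %s)\n", nrow(x),
    attr(x, "provenance") %||% "unknown"
  ))
  cat(sprintf(
    "  outcomes: %d major amputation, %d minor only, %d none\n",
    grp[["major"]], grp[["minor_no_major"]], grp[["none"]]
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check cohort records against the data-model rules
#'
#' Audits every record against the soft invariants of the data model and
#' the study eligibility rule. Violations are returned as data, one row per
#' failed rule, never raised as errors; a fully conforming cohort yields a
#' zero-row data frame. The check is side-effect free and idempotent.
#'
#' Rules checked per record:
#' * every enum field holds a declared level and is non-missing;
#' * `area_cm2` is non-missing and `>= 0`, and `> 0` unless
#'   `depth == "intact"`;
#' * `follow_up_months` is non-missing and `>= 6` (study eligibility);
#' * logical fields are non-missing.
#'
#' @param cohort a [dfu_cohort()] or a data frame with the same columns.
#' @return Data frame with columns `row`, `patient_id`, `field`, `rule`.
#' @examples
#' coh <- example_cohort()
#' nrow(validate_cohort(coh))  # 0: the shipped example is fully conforming
#' coh$follow_up_months[2] <- 2
#' validate_cohort(coh)
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  out <- list()
  add <- function(rows, field, rule) {
    if (length(rows) == 0L || !any(rows)) return()
    idx <- which(rows)
    out[[length(out) + 1L]] <<- data.frame(
      row = idx,
      patient_id = as.character(cohort$patient_id[idx]),
      field = field, rule = rule, stringsAsFactors = FALSE
    )
  }
  for (col in intersect(names(.dfu_enum_levels), names(cohort))) {
    v <- as.character(cohort[[col]])
    add(is.na(v) | !(v %in% .dfu_enum_levels[[col]]), col,
        "must be one of the declared levels")
  }
  for (col in intersect(.dfu_logical_cols, names(cohort))) {
    add(is.na(cohort[[col]]), col, "must be TRUE or FALSE")
  }
  if ("area_cm2" %in% names(cohort)) {
    a <- cohort$area_cm2
    add(is.na(a) | a < 0, "area_cm2", "must be nonnegative")
    if ("depth" %in% names(cohort)) {
      add(!is.na(a) & a == 0 & !is.na(cohort$depth) &
            cohort$depth != "intact",
          "area_cm2", "must be positive unless depth is 'intact'")
    }
  }
  if ("follow_up_months" %in% names(cohort)) {
    f <- cohort$follow_up_months
    add(is.na(f) | f < 6, "follow_up_months",
        "must be at least 6 months (eligibility)")
  }
  if (length(out) == 0L) {
    return(data.frame(
      row = integer(), patient_id = character(),
      field = character(), rule = character(), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$row, res$field), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Partition a cohort into the three outcome groups
#'
#' Patients are partitioned into disjoint groups: `major` (major
#' amputation, regardless of any minor procedure), `minor_no_major` (minor
#' amputation only) and `none`. Minor amputations count as "no major
#' amputation" in every analysis; a patient is never double-counted.
#'
#' @param cohort a [dfu_cohort()] or data frame with `major_amputation` and
#'   `minor_amputation` logical columns.
#' @return Factor with levels `major`, `minor_no_major`, `none`.
#' @examples
#' table(outcome_groups(example_cohort()))
#' @export
outcome_groups <- function(cohort) {
  maj <- cohort$major_amputation
  min_ <- cohort$minor_amputation
  g <- ifelse(maj, "major", ifelse(min_, "minor_no_major", "none"))
  factor(g, levels = c("major", "minor_no_major", "none"))
}

# Outcome vector for an analysis: major only, or the any-amputation
# composite (derived, never stored).
.dfu_outcome_vector <- function(cohort, outcome = c("major", "any")) {
  outcome <- match.arg(outcome)
  if (outcome == "major") {
    cohort$major_amputation
  } else {
    cohort$major_amputation | cohort$minor_amputation
  }
}
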