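# The four classification systems. All classifiers are vectorized, total
# functions of a wound-record data frame: every valid record maps to
# exactly one output.

.ord <- function(x, field) {
  # 1-based position of a token within its declared level order
  match(as.character(x), .dfu_enum_levels[[field]])
}

.check_wound <- function(wound) {
  if (!is.data.frame(wound)) stop("`wound` must be a data frame of wound records")
  miss <- setdiff(setdiff(.dfu_wound_cols, "patient_id"), names(wound))
  if (length(miss) > 0L) {
    stop("missing wound column(s): ", paste(miss, collapse = ", "))
  }
  wound
}

#' Meggitt-Wagner grade (0-5)
#'
#' Six-grade scale driven by ulcer depth, deep infection and gangrene
#' extent. The grade is the *highest* applicable rung of a most-severe-wins
#' ladder: 5 extensive gangrene (entire foot); 4 localized gangrene
#' (toes/forefoot); 3 deep ulcer with osteomyelitis or abscess; 2 ulcer
#' reaching tendon or joint capsule (or bone); 1 superficial ulcer;
#' 0 intact skin.
#'
#' @param wound a [dfu_cohort()] or data frame of wound records.
#' @return Integer vector of grades in `0:5`.
#' @examples
#' mw_grade(example_cohort())
#' @export
mw_grade <- function(wound) {
  w <- .check_wound(wound)
  g <- ifelse(w$gangrene == "extensive", 5L,
       ifelse(w$gangrene == "localized", 4L,
       ifelse(w$osteomyelitis_or_abscess, 3L,
       ifelse(w$depth %in% c("tendon_capsule", "bone_joint"), 2L,
       ifelse(w$depth == "superficial", 1L, 0L)))))
  as.integer(g)
}

#' University of Texas class (grade 0-3, stage A-D)
#'
#' Depth grade: 0 pre-/post-ulcerative lesion with intact skin,
#' 1 superficial, 2 penetrating to tendon or capsule, 3 penetrating to
#' bone or joint. Stage from the binary infection/ischemia pair:
#' A neither, B infection only, C ischemia only, D both. Infection is any
#' IDSA grade above `none`; ischemia is any Doppler grade above `none`.
#' The 4 x 4 grid yields 16 possible classes.
#'
#' @inheritParams mw_grade
#' @return Data frame with columns `grade` (integer `0:3`) and `stage`
#'   (factor `A` < `B` < `C` < `D`).
#' @examples
#' ut_classify(example_cohort())
#' @export
ut_classify <- function(wound) {
  w <- .check_wound(wound)
  grade <- .ord(w$depth, "depth") - 1L
  inf <- w$infection_idsa != "none"
  isc <- w$ischemia_grade != "none"
  stage <- ifelse(inf & isc, "D", ifelse(inf, "B", ifelse(isc, "C", "A")))
  data.frame(
    grade = as.integer(grade),
    stage = factor(stage, levels = c("A", "B", "C", "D")),
    stringsAsFactors = FALSE
  )
}

#' SINBAD score (0-6)
#'
#' One point per adverse item: Site (midfoot/hindfoot), Ischemia (any
#' grade above none), Neuropathy (any grade above none), Bacterial
#' infection (any IDSA grade above none), Area (>= 1 cm\eqn{^2}; closed
#' lower bound) and Depth (reaching tendon/capsule or bone, i.e. beyond
#' superficial).
#'
#' @inheritParams mw_grade
#' @param breakdown if `TRUE`, return a data frame with the six 0/1 item
#'   indicators plus the `total`; otherwise just the integer total.
#' @return Integer vector in `0:6`, or a data frame when
#'   `breakdown = TRUE`.
#' @examples
#' sinbad_score(example_cohort())
#' sinbad_score(example_cohort()[1:3, ], breakdown = TRUE)
#' @export
sinbad_score <- function(wound, breakdown = FALSE) {
  w <- .check_wound(wound)
  items <- data.frame(
    site       = as.integer(w$site_region %in% c("midfoot", "hindfoot")),
    ischemia   = as.integer(w$ischemia_grade != "none"),
    neuropathy = as.integer(w$neuropathy_grade != "none"),
    infection  = as.integer(w$infection_idsa != "none"),
    area       = as.integer(w$area_cm2 >= 1),
    depth      = as.integer(w$depth %in% c("tendon_capsule", "bone_joint"))
  )
  total <- as.integer(rowSums(items))
  if (breakdown) {
    items$total <- total
    items
  } else {
    total
  }
}

#' Saint Elian score (6-30) with per-item breakdown
#'
#' Ten parameters in three domains. Anatomical and contributing items
#' score 1/2/3 in the order listed; aggravating items score 0/1/2/3.
#' \itemize{
#'   \item Anatomical: location (phalangeal 1, metatarsal 2, tarsal 3),
#'     topography (dorsal/plantar 1, lateral/medial 2, two or more 3),
#'     affected zones (one 1, two 2, whole foot 3).
#'   \item Aggravating: ischemia, infection, edema and neuropathy each
#'     0 (none) to 3 (worst level).
#'   \item Contributing: depth (superficial 1, below dermis 2,
#'     full-thickness 3; intact skin treated as 1), area (< 10 cm^2 = 1,
#'     10-40 cm^2 = 2, > 40 cm^2 = 3) and healing phase
#'     (epithelialization 1, granulation 2, inflammatory 3).
#' }
#' The total runs 6-30 and maps to a severity band: `mild` (<= 10),
#' `moderate` (11-20), `severe` (21-30). A total of exactly 10 is graded
#' mild so the bands are contiguous.
#'
#' @inheritParams mw_grade
#' @return Data frame with the ten per-item scores, `total` and `severity`
#'   (factor `mild` < `moderate` < `severe`).
#' @examples
#' saint_elian(example_cohort())[, c("total", "severity")]
#' @export
saint_elian <- function(wound) {
  w <- .check_wound(wound)
  depth_pts <- pmax(.ord(w$depth, "depth") - 1L, 1L)  # intact -> 1
  area_pts <- ifelse(w$area_cm2 < 10, 1L, ifelse(w$area_cm2 <= 40, 2L, 3L))
  items <- data.frame(
    location   = .ord(w$se_location, "se_location"),
    topography = .ord(w$se_topography, "se_topography"),
    zones      = .ord(w$se_zones, "se_zones"),
    ischemia   = .ord(w$ischemia_grade, "ischemia_grade") - 1L,
    infection  = .ord(w$infection_idsa, "infection_idsa") - 1L,
    edema      = .ord(w$edema_grade, "edema_grade") - 1L,
    neuropathy = .ord(w$neuropathy_grade, "neuropathy_grade") - 1L,
    depth      = as.integer(depth_pts),
    area       = as.integer(area_pts),
    healing    = .ord(w$healing_phase, "healing_phase")
  )
  total <- as.integer(rowSums(items))
  items$total <- total
  items$severity <- factor(
    ifelse(total <= 10, "mild", ifelse(total <= 20, "moderate", "severe")),
    levels = c("mild", "moderate", "severe")
  )
  items
}

#' Collapse a classifier output into the analysis risk bands
#'
#' Maps raw classifier output onto the ordinal risk bands used for the
#' banded incidence / relative-risk analysis, with the lowest
#' theoretical-risk band first (the reference):
#' \itemize{
#'   \item `mw`: grades 0-3 -> `1-3`, grades 4-5 -> `4-5` (grades with
#'     sparse events merged into the reference band);
#'   \item `ut`: grade-3 stage-D wounds -> `3D`, everything else ->
#'     `other`;
#'   \item `sinbad`: scores 0-4 -> `1-4`, then `5`, `6`;
#'   \item `se`: totals `<16`, `16-20`, `>20`.
#' }
#'
#' @param system one of `"mw"`, `"ut"`, `"sinbad"`, `"se"`.
#' @param x classifier output matching `system`: integer grades for `mw`
#'   and `sinbad`, the data frame from [ut_classify()] for `ut`, and
#'   either the data frame from [saint_elian()] or an integer total for
#'   `se`.
#' @return Ordered factor of risk bands (lowest band first).
#' @examples
#' coh <- example_cohort()
#' collapse_risk_category("mw", mw_grade(coh))
#' collapse_risk_category("ut", ut_classify(coh))
#' collapse_risk_category("se", saint_elian(coh))
#' @export
collapse_risk_category <- function(system, x) {
  system <- match.arg(system, c("mw", "ut", "sinbad", "se"))
  switch(system,
    mw = {
      g <- as.integer(x)
      stopifnot(all(g %in% 0:5))
      factor(ifelse(g <= 3L, "1-3", "4-5"),
             levels = c("1-3", "4-5"), ordered = TRUE)
    },
    ut = {
      if (!is.data.frame(x) || !all(c("grade", "stage") %in% names(x))) {
        stop("for system 'ut', `x` must be the output of ut_classify()")
      }
      factor(ifelse(x$grade == 3L & x$stage == "D", "3D", "other"),
             levels = c("other", "3D"), ordered = TRUE)
    },
    sinbad = {
      s <- as.integer(x)
      stopifnot(all(s %in% 0:6))
      factor(ifelse(s <= 4L, "1-4", as.character(s)),
             levels = c("1-4", "5", "6"), ordered = TRUE)
    },
    se = {
      tot <- if (is.data.frame(x)) x$total else as.integer(x)
      stopifnot(all(tot >= 6 & tot <= 30))
      factor(ifelse(tot < 16, "<16", ifelse(tot <= 20, "16-20", ">20")),
             levels = c("<16", "16-20", ">20"), ordered = TRUE)
    }
  )
}

#' Compute all seven score variants analysed in the validation
#'
#' The discrimination analysis evaluates seven scores derived from the
#' four systems: the Saint Elian total (6-30), the Meggitt-Wagner grade
#' (0-5), the SINBAD total (0-6), the University of Texas depth grade
#' (0-3), and three binary UT components -- the 3D indicator (grade 3
#' stage D), ischemia and infection. Higher values always mean higher
#' theoretical amputation risk.
#'
#' @inheritParams mw_grade
#' @return Data frame with integer columns `saint_elian`,
#'   `meggitt_wagner`, `sinbad`, `ut_3d`, `ut_depth`, `ut_ischemia`,
#'   `ut_infection`.
#' @examples
#' dfu_scores(example_cohort())
#' @export
dfu_scores <- function(wound) {
  w <- .check_wound(wound)
  ut <- ut_classify(w)
  data.frame(
    saint_elian    = saint_elian(w)$total,
    meggitt_wagner = mw_grade(w),
    sinbad         = sinbad_score(w),
    ut_3d          = as.integer(ut$grade == 3L & ut$stage == "D"),
    ut_depth       = ut$grade,
    ut_ischemia    = as.integer(w$ischemia_grade != "none"),
    ut_infection   = as.integer(w$infection_idsa != "none")
  )
}

.dfu_score_variants <- c(
  "saint_elian", "meggitt_wagner", "sinbad", "ut_3d", "ut_depth",
  "ut_ischemia", "ut_infection"
)
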