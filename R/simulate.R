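# Latent-severity synthetic cohort generator.
#
# A single standard-normal latent severity L drives both the outcome
# (logistic link, intercept calibrated to the target incidence) and every
# wound item (ordered-threshold model on L plus item-specific Gaussian
# noise, thresholds fixed so the marginal category frequencies are
# preserved whatever the noise). A shared latent induces the positive
# inter-score correlation that makes paired DeLong comparisons
# meaningful; per-item noise controls how discriminative each system's
# score is.

# Marginal category frequencies emulating a referral-hospital diabetic
# foot cohort (advanced wounds, ~60% ischemic, ~46% deep lesions).
.dfu_sim_marginals <- list(
  depth = c(intact = 0, superficial = 0.366, tendon_capsule = 0.169,
            bone_joint = 0.465),
  gangrene = c(none = 0.57, localized = 0.41, extensive = 0.02),
  infection_idsa = c(none = 0.267, mild = 0.301, moderate = 0.360,
                     severe = 0.072),
  ischemia_grade = c(none = 0.404, mild = 0.30, moderate = 0.20,
                     severe = 0.096),
  neuropathy_grade = c(none = 0.20, diminished = 0.30, lops = 0.40,
                       charcot = 0.10),
  edema_grade = c(none = 0.35, perilesional = 0.30, unilateral = 0.25,
                  bilateral = 0.10),
  site_region = c(forefoot = 0.743, midfoot = 0.13, hindfoot = 0.127),
  se_location = c(phalangeal = 0.50, metatarsal = 0.35, tarsal = 0.15),
  se_topography = c(dorsal_or_plantar = 0.55, lateral_or_medial = 0.30,
                    two_or_more = 0.15),
  se_zones = c(one = 0.65, two = 0.25, whole_foot = 0.10),
  healing_phase = c(epithelialization = 0.15, granulation = 0.45,
                    inflammatory = 0.40)
)
.dfu_sim_p_osteo <- 0.35
# Ulcer area: log-normal with P(area < 10) ~ 0.45 and P(area > 40) ~ 0.26
.dfu_sim_area_meanlog <- 2.529
.dfu_sim_area_sdlog <- 1.803

.dfu_noise_items <- c(
  "depth", "osteomyelitis", "gangrene", "infection", "ischemia",
  "neuropathy", "edema", "site", "area", "location", "topography",
  "zones", "healing"
)

# Which noise items each calibration knob shares, and the score the knob
# is calibrated against. Order matters: later knobs depend on earlier,
# already-fixed items but not vice versa.
.dfu_sim_knobs <- list(
  ut_ischemia    = "ischemia",
  ut_infection   = "infection",
  meggitt_wagner = c("depth", "osteomyelitis", "gangrene"),
  sinbad         = c("site", "neuropathy", "area"),
  saint_elian    = c("location", "topography", "zones", "edema", "healing")
)

#' Default per-item latent-noise standard deviations
#'
#' Noise scales produced by [calibrate_sim_noise()] under the default
#' simulation configuration (bisection against a 20000-patient pilot at
#' seed 1), frozen here so that [simulate_cohort()] hits the default
#' target AUCs out of the box.
#'
#' @return Named numeric vector, one nonnegative noise sd per wound item.
#' @export
dfu_default_noise <- function() {
  c(
    depth = 0.664, osteomyelitis = 0.664, gangrene = 0.664,
    infection = 0, ischemia = 1.641,
    neuropathy = 7.5, edema = 1.016, site = 7.5, area = 7.5,
    location = 1.016, topography = 1.016, zones = 1.016, healing = 1.016
  )
}

#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates every parameter of the synthetic cohort
#' generator. The defaults emulate the structure of a referral-hospital
#' diabetic foot cohort: 342 patients, 11.4% six-month major-amputation
#' incidence, 31.9% inpatients containing all events, and per-system
#' discrimination targets spanning AUROC 0.65-0.90.
#'
#' @param n_patients cohort size (>= 20).
#' @param target_incidence major-amputation incidence, in (0, 1).
#' @param inpatient_fraction inpatient share of the cohort, in (0, 1).
#' @param events_inpatient_only if `TRUE` (default) every event patient
#'   is assigned to the inpatient stratum and the inpatient quota is
#'   filled with the most severe non-event patients, reproducing a
#'   zero-event outpatient stratum and spectrum bias on restriction.
#' @param target_auc named proportions in (0.5, 1): desired AUROC per
#'   calibratable score (`saint_elian`, `meggitt_wagner`, `sinbad`,
#'   `ut_ischemia`, `ut_infection`).
#' @param latent_noise named positive noise sd per wound item (see
#'   [dfu_default_noise()]).
#' @param outcome_slope slope of the latent severity in the outcome
#'   logit; fixes the discrimination ceiling (the AUC of the latent
#'   itself).
#' @param minor_fraction probability of a minor amputation among
#'   patients without a major one.
#' @param seed integer seed; cohorts are fully reproducible given the
#'   seed.
#' @return A `dfu_sim_config` list.
#' @seealso [simulate_cohort()], [calibrate_sim_noise()]
#' @export
dfu_sim_config <- function(n_patients = 342,
                           target_incidence = 0.114,
                           inpatient_fraction = 0.319,
                           events_inpatient_only = TRUE,
                           target_auc = c(saint_elian = 0.90,
                                          meggitt_wagner = 0.81,
                                          sinbad = 0.75,
                                          ut_ischemia = 0.65,
                                          ut_infection = 0.65),
                           latent_noise = dfu_default_noise(),
                           outcome_slope = 3,
                           minor_fraction = 0.251,
                           seed = 1L) {
  stopifnot(
    n_patients >= 20,
    target_incidence > 0, target_incidence < 1,
    inpatient_fraction > 0, inpatient_fraction < 1,
    is.logical(events_inpatient_only),
    outcome_slope > 0,
    minor_fraction >= 0, minor_fraction < 1
  )
  if (any(target_auc <= 0.5) || any(target_auc >= 1)) {
    stop("target AUCs must lie in (0.5, 1)")
  }
  bad <- setdiff(names(target_auc), names(.dfu_sim_knobs))
  if (length(bad) > 0L) {
    stop("no calibration knob for target(s): ", paste(bad, collapse = ", "))
  }
  miss <- setdiff(.dfu_noise_items, names(latent_noise))
  if (length(miss) > 0L) {
    stop("latent_noise missing item(s): ", paste(miss, collapse = ", "))
  }
  if (any(latent_noise < 0)) stop("latent noise sds must be nonnegative")
  out <- list(
    n_patients = as.integer(n_patients),
    target_incidence = target_incidence,
    inpatient_fraction = inpatient_fraction,
    events_inpatient_only = isTRUE(events_inpatient_only),
    target_auc = target_auc,
    latent_noise = latent_noise[.dfu_noise_items],
    outcome_slope = outcome_slope,
    minor_fraction = minor_fraction,
    seed = as.integer(seed)
  )
  class(out) <- "dfu_sim_config"
  out
}

# Ordered-threshold assignment preserving the marginal frequencies: the
# cutpoints on signal = L + sigma * eps (total sd sqrt(1 + sigma^2)) are
# the normal quantiles of the cumulative category probabilities.
.assign_ordinal <- function(signal, sigma, probs) {
  keep <- probs > 0
  lv <- names(probs)[keep]
  p <- probs[keep]
  sd_tot <- sqrt(1 + sigma^2)
  cuts <- stats::qnorm(cumsum(p)[-length(p)], sd = sd_tot)
  lv[findInterval(signal, cuts) + 1L]
}

#' Generate a synthetic diabetic-foot cohort
#'
#' Draws a cohort under the latent-severity model of
#' [dfu_sim_config()]: a standard-normal severity per patient; a major
#' amputation via a logistic link whose intercept is root-found so the
#' expected incidence equals `target_incidence`; every wound item by
#' thresholding the severity plus item-specific Gaussian noise (marginal
#' category frequencies are noise-invariant by construction); a minor
#' amputation among the remaining patients; and a care-setting assignment
#' that, when `events_inpatient_only`, places all events plus the most
#' severe non-event patients in the inpatient stratum.
#'
#' @param config a [dfu_sim_config()].
#' @return A [dfu_cohort()] of `config$n_patients` records, provenance
#'   `"synthetic seed=<seed>"`. Identical seeds give identical cohorts.
#' @examples
#' coh <- simulate_cohort(dfu_sim_config(n_patients = 200, seed = 42))
#' cumulative_incidence(coh, "major")$proportion
#' @export
simulate_cohort <- function(config = dfu_sim_config()) {
  stopifnot(inherits(config, "dfu_sim_config"))
  n <- config$n_patients
  ns <- config$latent_noise
  set.seed(config$seed)
  L <- stats::rnorm(n)
  sig <- function(item) L + ns[[item]] * stats::rnorm(n)
  x_depth <- sig("depth"); x_osteo <- sig("osteomyelitis")
  x_gang <- sig("gangrene"); x_inf <- sig("infection")
  x_isch <- sig("ischemia"); x_neuro <- sig("neuropathy")
  x_edema <- sig("edema"); x_site <- sig("site")
  x_area <- sig("area"); x_loc <- sig("location")
  x_topo <- sig("topography"); x_zones <- sig("zones")
  x_heal <- sig("healing")

  m <- .dfu_sim_marginals
  depth <- .assign_ordinal(x_depth, ns[["depth"]], m$depth)
  osteo <- x_osteo > stats::qnorm(1 - .dfu_sim_p_osteo,
                                  sd = sqrt(1 + ns[["osteomyelitis"]]^2))
  gangrene <- .assign_ordinal(x_gang, ns[["gangrene"]], m$gangrene)
  infection <- .assign_ordinal(x_inf, ns[["infection"]], m$infection_idsa)
  ischemia <- .assign_ordinal(x_isch, ns[["ischemia"]], m$ischemia_grade)
  neuropathy <- .assign_ordinal(x_neuro, ns[["neuropathy"]],
                                m$neuropathy_grade)
  edema <- .assign_ordinal(x_edema, ns[["edema"]], m$edema_grade)
  site <- .assign_ordinal(x_site, ns[["site"]], m$site_region)
  location <- .assign_ordinal(x_loc, ns[["location"]], m$se_location)
  topography <- .assign_ordinal(x_topo, ns[["topography"]],
                                m$se_topography)
  zones <- .assign_ordinal(x_zones, ns[["zones"]], m$se_zones)
  healing <- .assign_ordinal(x_heal, ns[["healing"]], m$healing_phase)
  # Gaussian copula on the area signal -> log-normal sizes, rounded to
  # 0.1 cm2 with a positive floor.
  u_area <- stats::pnorm(x_area / sqrt(1 + ns[["area"]]^2))
  area <- pmax(0.1, round(stats::qlnorm(
    u_area, .dfu_sim_area_meanlog, .dfu_sim_area_sdlog
  ), 1))

  b <- config$outcome_slope
  a <- stats::uniroot(
    function(a) mean(stats::plogis(a + b * L)) - config$target_incidence,
    interval = c(-60, 60), tol = 1e-10
  )$root
  major <- stats::runif(n) < stats::plogis(a + b * L)
  minor <- rep(FALSE, n)
  if (any(!major) && config$minor_fraction > 0) {
    idx <- which(!major)
    a2 <- stats::uniroot(
      function(a2) mean(stats::plogis(a2 + b * L[idx])) -
        config$minor_fraction,
      interval = c(-60, 60), tol = 1e-10
    )$root
    minor[idx] <- stats::runif(length(idx)) < stats::plogis(a2 + b * L[idx])
  }

  quota <- max(1L, round(config$inpatient_fraction * n))
  inpatient <- rep(FALSE, n)
  if (config$events_inpatient_only) {
    inpatient[major] <- TRUE
    extra <- quota - sum(major)
    if (extra > 0) {
      cand <- which(!major)
      inpatient[cand[order(L[cand], decreasing = TRUE)[seq_len(
        min(extra, length(cand)))]]] <- TRUE
    }
  } else {
    inpatient[order(L, decreasing = TRUE)[seq_len(quota)]] <- TRUE
  }

  follow_up <- 6 + round(stats::rexp(n, rate = 1 / 6), 1)

  df <- data.frame(
    patient_id = sprintf("S%05d", seq_len(n)),
    depth = depth,
    osteomyelitis_or_abscess = osteo,
    gangrene = gangrene,
    infection_idsa = infection,
    ischemia_grade = ischemia,
    neuropathy_grade = neuropathy,
    edema_grade = edema,
    site_region = site,
    se_location = location,
    se_topography = topography,
    se_zones = zones,
    area_cm2 = area,
    healing_phase = healing,
    major_amputation = major,
    minor_amputation = minor,
    inpatient = inpatient,
    follow_up_months = follow_up,
    stringsAsFactors = FALSE
  )
  dfu_cohort(df, provenance = sprintf("synthetic seed=%d", config$seed))
}

#' Calibrate the generator's noise scales to the target AUCs
#'
#' Tunes the per-item latent-noise standard deviations so that each
#' score named in `config$target_auc` attains its target AUROC, by
#' bisection of a shared noise scale per knob against a large fixed-seed
#' pilot cohort. Knobs are calibrated in dependency order (ischemia,
#' infection, then the Meggitt-Wagner depth/gangrene group, the
#' SINBAD-specific items, and finally the Saint Elian-specific items), so
#' each bisection sees all earlier items already fixed. A target that is
#' unattainable -- above the knob's discrimination ceiling at zero noise,
#' or below its floor at maximal noise -- raises an error.
#'
#' @param config a [dfu_sim_config()]; its `latent_noise` provides the
#'   starting values and its `seed` fixes the pilot draws.
#' @param n_pilot pilot cohort size per bisection step.
#' @param tol acceptable |pilot AUC - target|.
#' @param sigma_max upper bracket for a noise sd.
#' @param max_iter bisection iterations per knob.
#' @return The configuration with calibrated `latent_noise`, carrying an
#'   attribute `pilot_auc` (achieved pilot AUC per calibrated score).
#' @examples
#' \donttest{
#' cfg <- calibrate_sim_noise(dfu_sim_config(seed = 7), n_pilot = 4000)
#' attr(cfg, "pilot_auc")
#' }
#' @export
calibrate_sim_noise <- function(config = dfu_sim_config(),
                                n_pilot = 8000, tol = 0.005,
                                sigma_max = 40, max_iter = 30) {
  stopifnot(inherits(config, "dfu_sim_config"), n_pilot >= 1000)
  pilot <- config
  pilot$n_patients <- as.integer(n_pilot)
  achieved <- c()
  for (score in names(.dfu_sim_knobs)) {
    if (!score %in% names(config$target_auc)) next
    target <- config$target_auc[[score]]
    items <- .dfu_sim_knobs[[score]]
    eval_auc <- function(sg) {
      pilot$latent_noise[items] <- sg
      coh <- simulate_cohort(pilot)
      roc_auc(dfu_scores(coh)[[score]], coh$major_amputation)$auc
    }
    lo <- 0; hi <- sigma_max
    a_lo <- eval_auc(lo)
    if (a_lo < target - tol) {
      stop(sprintf(
        "target AUC %.3f for %s unattainable: ceiling %.3f at zero noise",
        target, score, a_lo
      ))
    }
    a_hi <- eval_auc(hi)
    if (a_hi > target + tol) {
      stop(sprintf(
        "target AUC %.3f for %s below the noise floor %.3f",
        target, score, a_hi
      ))
    }
    best <- if (abs(a_lo - target) < abs(a_hi - target)) {
      c(lo, a_lo)
    } else {
      c(hi, a_hi)
    }
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      a_mid <- eval_auc(mid)
      if (abs(a_mid - target) < abs(best[2] - target)) best <- c(mid, a_mid)
      if (abs(a_mid - target) <= tol / 2) break
      if (a_mid > target) lo <- mid else hi <- mid
    }
    pilot$latent_noise[items] <- best[1]
    config$latent_noise[items] <- best[1]
    achieved[score] <- best[2]
  }
  attr(config, "pilot_auc") <- achieved
  config
}

#' Deterministic 12-patient worked-example cohort
#'
#' A hand-written cohort spanning the full range of all four classifiers
#' -- every Meggitt-Wagner grade 0-5, all four University of Texas
#' stages, every SINBAD total 0-6, and Saint Elian mild, moderate and
#' severe bands -- with three major amputations (all inpatients), two
#' minor amputations, and an event-free outpatient stratum. Used as the
#' worked example throughout the documentation; regenerating it always
#' yields the identical cohort.
#'
#' @return A [dfu_cohort()] of 12 records, provenance
#'   `"example fixture"`.
#' @examples
#' coh <- example_cohort()
#' cbind(id = coh$patient_id, dfu_scores(coh))
#' @export
example_cohort <- function() {
  df <- data.frame(
    patient_id = sprintf("P%02d", 1:12),
    depth = c("intact", "superficial", "superficial", "tendon_capsule",
              "bone_joint", "bone_joint", "tendon_capsule", "bone_joint",
              "superficial", "tendon_capsule", "bone_joint", "superficial"),
    osteomyelitis_or_abscess = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                                 FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    gangrene = c("none", "none", "none", "none", "none", "none",
                 "localized", "extensive", "none", "none", "none", "none"),
    infection_idsa = c("none", "mild", "none", "mild", "moderate",
                       "severe", "moderate", "severe", "none", "none",
                       "moderate", "mild"),
    ischemia_grade = c("none", "none", "mild", "mild", "none", "moderate",
                       "moderate", "severe", "moderate", "none", "mild",
                       "none"),
    neuropathy_grade = c("none", "none", "none", "none", "lops", "lops",
                         "none", "charcot", "diminished", "lops", "lops",
                         "none"),
    edema_grade = c("none", "none", "none", "none", "none", "unilateral",
                    "perilesional", "bilateral", "none", "none",
                    "unilateral", "none"),
    site_region = c("forefoot", "forefoot", "forefoot", "forefoot",
                    "midfoot", "hindfoot", "forefoot", "hindfoot",
                    "midfoot", "forefoot", "forefoot", "forefoot"),
    se_location = c("phalangeal", "phalangeal", "phalangeal", "phalangeal",
                    "metatarsal", "tarsal", "metatarsal", "tarsal",
                    "phalangeal", "phalangeal", "metatarsal", "phalangeal"),
    se_topography = c("dorsal_or_plantar", "dorsal_or_plantar",
                      "lateral_or_medial", "dorsal_or_plantar",
                      "dorsal_or_plantar", "two_or_more",
                      "lateral_or_medial", "two_or_more",
                      "dorsal_or_plantar", "dorsal_or_plantar",
                      "lateral_or_medial", "dorsal_or_plantar"),
    se_zones = c("one", "one", "one", "one", "one", "two", "one",
                 "whole_foot", "one", "one", "two", "one"),
    area_cm2 = c(0, 0.5, 2, 1.5, 6, 15, 8, 60, 0.8, 0.9, 12, 0.4),
    healing_phase = c("epithelialization", "epithelialization",
                      "epithelialization", "granulation", "granulation",
                      "inflammatory", "granulation", "inflammatory",
                      "granulation", "granulation", "inflammatory",
                      "epithelialization"),
    major_amputation = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                         TRUE, FALSE, FALSE, TRUE, FALSE),
    minor_amputation = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE,
                         FALSE, FALSE, FALSE, FALSE, FALSE),
    inpatient = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                  FALSE, FALSE, TRUE, FALSE),
    follow_up_months = c(12, 10, 8, 9, 9, 6, 7, 6, 14, 11, 7, 18),
    stringsAsFactors = FALSE
  )
  dfu_cohort(df, provenance = "example fixture")
}
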