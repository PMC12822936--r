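# Record builders and independent brute-force oracles shared across tests.

# One cohort-shaped row with benign defaults, overridable per field.
wound_row <- function(...) {
  base <- list(
    patient_id = "W001",
    depth = "superficial",
    osteomyelitis_or_abscess = FALSE,
    gangrene = "none",
    infection_idsa = "none",
    ischemia_grade = "none",
    neuropathy_grade = "none",
    edema_grade = "none",
    site_region = "forefoot",
    se_location = "phalangeal",
    se_topography = "dorsal_or_plantar",
    se_zones = "one",
    area_cm2 = 0.5,
    healing_phase = "epithelialization",
    major_amputation = FALSE,
    minor_amputation = FALSE,
    inpatient = FALSE,
    follow_up_months = 12
  )
  mods <- list(...)
  stopifnot(all(names(mods) %in% names(base)))
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}

# rbind rows and renumber ids so they are unique.
bind_wounds <- function(...) {
  df <- do.call(rbind, list(...))
  df$patient_id <- sprintf("W%03d", seq_len(nrow(df)))
  df
}

# Exhaustive pair-counting AUC oracle (ties count half).
auc_pairs <- function(scores, outcomes) {
  pos <- scores[outcomes]
  neg <- scores[!outcomes]
  tot <- 0
  for (x in pos) {
    for (y in neg) tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(pos) * length(neg))
}

# Brute-force paired DeLong oracle: placement values by explicit
# enumeration, covariances by explicit sums.
delong_brute <- function(a, b, y) {
  psi <- function(x, v) if (x > v) 1 else if (x == v) 0.5 else 0
  pos <- which(y)
  neg <- which(!y)
  m <- length(pos)
  n <- length(neg)
  v10 <- function(s) {
    vapply(pos, function(i) {
      mean(vapply(neg, function(j) psi(s[i], s[j]), numeric(1)))
    }, numeric(1))
  }
  v01 <- function(s) {
    vapply(neg, function(j) {
      mean(vapply(pos, function(i) psi(s[i], s[j]), numeric(1)))
    }, numeric(1))
  }
  va10 <- v10(a); vb10 <- v10(b)
  va01 <- v01(a); vb01 <- v01(b)
  cv <- function(u, v) {
    if (length(u) > 1) {
      sum((u - mean(u)) * (v - mean(v))) / (length(u) - 1)
    } else 0
  }
  vd <- (cv(va10, va10) + cv(vb10, vb10) - 2 * cv(va10, vb10)) / m +
    (cv(va01, va01) + cv(vb01, vb01) - 2 * cv(va01, vb01)) / n
  vd <- max(vd, 0)
  delta <- mean(va10) - mean(vb10)
  p <- if (vd == 0) {
    if (delta == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(delta) / sqrt(vd))
  }
  list(auc_a = mean(va10), auc_b = mean(vb10), delta = delta,
       var = vd, p = p)
}

# Random non-degenerate score/outcome pair with ties.
random_roc_case <- function(n, alphabet = 3) {
  repeat {
    y <- stats::runif(n) < 0.4
    if (any(y) && !all(y)) break
  }
  list(scores = sample.int(alphabet, n, replace = TRUE), outcomes = y)
}
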