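# Calibrated synthetic cohort generator. Patients carry the demographic mix
# of a large mid-Atlantic academic-health-system adult population; events are
# generated from latent "evidence classes" (which data types carry qualifying
# type-2-diabetes patterns) so that every data-type stratum downstream is
# populated and exactly controllable.

EVIDENCE_CLASSES <- c("none", "DX", "RX", "LAB",
                      "DX+RX", "DX+LAB", "RX+LAB", "DX+RX+LAB")

#' Build a cohort generation profile
#'
#' All tunable parameters of the synthetic generator. Defaults reproduce the
#' study population the package is calibrated against: ~208k adults observed
#' 2017--2019, mean age 62.4 (SD 15.4), 51.3% female, 81.4% Maryland
#' residents, mean Charlson comorbidity index 2.17.
#'
#' @param n_patients Cohort size.
#' @param age_mean,age_sd Target mean/SD of age (years) at study start; ages
#'   are drawn from a truncated normal on `age_range` whose latent mean is
#'   calibrated so the *truncated* mean equals `age_mean`.
#' @param age_range Inclusive age bounds at study start.
#' @param p_female,p_sex_other Probability of female / unknown-sex records
#'   (male takes the remainder).
#' @param race_probs,ethnicity_probs Named probability vectors over the
#'   race/ethnicity levels; must sum to 1.
#' @param p_maryland Probability of Maryland residence.
#' @param inpatient_visit_mean,ed_visit_mean Poisson means for visit counts
#'   over the study period.
#' @param cci_mean Target mean Charlson comorbidity index; per-category
#'   prevalences are rescaled by a single multiplier to hit it.
#' @param evidence_class_probs Named probabilities over the 7 qualifying
#'   data-type combinations plus `"none"`.
#' @param event_rate_params Background (non-qualifying) event rates per
#'   patient-year and extra-qualifying-event means.
#' @param lab_value_params Per-LOINC background value distributions.
#' @param charlson_prevalence Relative per-category comorbidity prevalences
#'   (rescaled during calibration).
#' @param study_window Inclusive study window.
#' @return A `cohort_profile` list.
#' @export
cohort_profile <- function(
    n_patients = 207813,
    age_mean = 62.4, age_sd = 15.4, age_range = c(18, 90),
    p_female = 0.513, p_sex_other = 0.001,
    race_probs = c(white = 0.528, black = 0.318, asian = 0.056, other = 0.098),
    ethnicity_probs = c(non_hispanic = 0.899, hispanic = 0.053, other = 0.048),
    p_maryland = 0.814,
    inpatient_visit_mean = 0.657, ed_visit_mean = 1.01,
    cci_mean = 2.17,
    evidence_class_probs = c(
      none = 0.22, DX = 0.17, RX = 0.07, LAB = 0.08,
      `DX+RX` = 0.14, `DX+LAB` = 0.10, `RX+LAB` = 0.06, `DX+RX+LAB` = 0.16
    ),
    event_rate_params = list(
      bg_dx_per_year = 5, bg_rx_per_year = 3, bg_lab_per_year = 4,
      qual_dx_extra_mean = 1.0, qual_rx_extra_mean = 1.0,
      qual_lab_extra_mean = 0.7
    ),
    lab_value_params = default_lab_value_params(),
    charlson_prevalence = default_charlson_prevalence(),
    study_window = default_study_window()) {
  p <- structure(as.list(environment()), class = "cohort_profile")
  for (nm in c("race_probs", "ethnicity_probs", "evidence_class_probs")) {
    if (abs(sum(p[[nm]]) - 1) > 1e-9) {
      stop("config error: ", nm, " must sum to 1 (got ", sum(p[[nm]]), ")",
           call. = FALSE)
    }
  }
  if (!setequal(names(p$evidence_class_probs), EVIDENCE_CLASSES)) {
    stop("config error: evidence_class_probs must name the 7 data-type ",
         "combinations plus 'none'", call. = FALSE)
  }
  probs <- c(p$p_female, p$p_sex_other, p$p_maryland,
             p$race_probs, p$ethnicity_probs, p$evidence_class_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  p
}

#' The default (study-calibrated) generation profile
#'
#' Parameter anchors: mean age 62.4 (SD 15.4); 51.3% female; race
#' white/black/asian/other = 52.8/31.8/5.6/9.8%; ethnicity non-Hispanic/
#' Hispanic/other = 89.9/5.3/4.8%; 81.4% Maryland; mean inpatient visits
#' 0.657 and ED visits 1.01; mean Charlson index 2.17. About 78% of patients
#' carry qualifying evidence of some kind (evidence class other than "none").
#'
#' @return A [cohort_profile()].
#' @export
default_profile <- function() cohort_profile()

#' @rdname cohort_profile
#' @export
default_lab_value_params <- function() {
  list(
    # background (non-qualifying) draws; HbA1c deliberately spans the
    # high-normal 5.6-5.8% band
    `55454-3` = list(kind = "hba1c_normal", unit = "%"),
    `4548-4`  = list(kind = "hba1c_normal", unit = "%"),
    `2345-7`  = list(kind = "uniform", min = 70, max = 180, unit = "mg/dL"),
    `1558-6`  = list(kind = "uniform", min = 70, max = 120, unit = "mg/dL"),
    `2160-0`  = list(kind = "normal", mean = 0.95, sd = 0.2, unit = "mg/dL"),
    `718-7`   = list(kind = "normal", mean = 13.5, sd = 1.5, unit = "g/dL")
  )
}

#' @rdname cohort_profile
#' @export
default_charlson_prevalence <- function() {
  c(
    myocardial_infarction = 0.06, congestive_heart_failure = 0.10,
    peripheral_vascular_disease = 0.08, cerebrovascular_disease = 0.10,
    dementia = 0.05, chronic_pulmonary_disease = 0.15,
    rheumatologic_disease = 0.03, peptic_ulcer_disease = 0.02,
    mild_liver_disease = 0.04, diabetes_uncomplicated = 0.20,
    diabetes_complicated = 0.08, hemiplegia_paraplegia = 0.02,
    renal_disease = 0.10, any_malignancy = 0.10,
    moderate_severe_liver_disease = 0.01, metastatic_solid_tumor = 0.03,
    hiv_aids = 0.005
  )
}

# mean of N(mu, sd) truncated to [lo, hi]
.trunc_norm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# latent mean such that the truncated mean equals `target`
.calibrate_trunc_mu <- function(target, sd, lo, hi) {
  stats::uniroot(function(mu) .trunc_norm_mean(mu, sd, lo, hi) - target,
                 interval = c(target - 2 * sd, target + 2 * sd),
                 tol = 1e-8)$root
}

#' Generate a patient demographics table
#'
#' Ages come from a truncated normal on the profile's age range whose latent
#' mean is calibrated (one-dimensional root find) so the truncated mean
#' matches the profile target; categorical fields are independent draws from
#' the profile probabilities; visit counts are Poisson. Deterministic given
#' `(profile, n, seed)`.
#'
#' @param profile A [cohort_profile()].
#' @param seed Integer RNG seed.
#' @param n Number of patients (defaults to `profile$n_patients`).
#' @return Tibble of patients (see [ehr_cohort()] for columns).
#' @export
generate_patients <- function(profile = default_profile(), seed = 1L,
                              n = profile$n_patients) {
  stopifnot(n >= 1)
  lo <- profile$age_range[1]
  hi <- profile$age_range[2]
  mu <- .calibrate_trunc_mu(profile$age_mean, profile$age_sd, lo, hi)
  start_year <- as.integer(format(profile$study_window[1], "%Y"))
  withr::with_seed(seed, {
    plo <- stats::pnorm(lo, mu, profile$age_sd)
    phi <- stats::pnorm(hi, mu, profile$age_sd)
    age <- round(stats::qnorm(stats::runif(n, plo, phi), mu, profile$age_sd))
    age <- pmin(pmax(age, lo), hi)
    sex_probs <- c(female = profile$p_female,
                   male = 1 - profile$p_female - profile$p_sex_other,
                   other = profile$p_sex_other)
    tibble::tibble(
      patient_id = sprintf("P%07d", seq_len(n)),
      birth_year = start_year - as.integer(age),
      sex = sample(names(sex_probs), n, replace = TRUE, prob = sex_probs),
      race = sample(names(profile$race_probs), n, replace = TRUE,
                    prob = profile$race_probs),
      ethnicity = sample(names(profile$ethnicity_probs), n, replace = TRUE,
                         prob = profile$ethnicity_probs),
      state = sample(c("MD", "other"), n, replace = TRUE,
                     prob = c(profile$p_maryland, 1 - profile$p_maryland)),
      inpatient_visits = stats::rpois(n, profile$inpatient_visit_mean),
      ed_visits = stats::rpois(n, profile$ed_visit_mean)
    )
  })
}

.uniform_dates <- function(n, window) {
  ndays <- as.integer(window[2] - window[1]) + 1L
  window[1] + (sample.int(ndays, n, replace = TRUE) - 1L)
}

.dx_event <- function(patient_id, code, date, setting) {
  tibble::tibble(patient_id = patient_id, data_type = "DX",
                 code_system = "ICD10", code = code, event_date = date,
                 setting = setting, value = NA_real_, unit = NA_character_)
}

#' Generate clinical events for a patient table
#'
#' Each patient is assigned a latent evidence class (which data types carry
#' qualifying type-2-diabetes patterns). Class members receive patterns strong
#' enough to satisfy the strictest shipped criterion for that data type:
#' DX members get >= 2 outpatient E11.x diagnoses on distinct days inside the
#' trailing two-year reference period; RX members get >= 1 antihyperglycemic
#' dispensing; LAB members get >= 2 elevated HbA1c results (>= 6.5%) on
#' distinct days. All patients additionally receive background events
#' (non-diabetes codes, normal laboratory values) at the profile rates.
#'
#' The returned table carries an `evidence_class` attribute (tibble of
#' `patient_id`, `evidence_class`).
#'
#' @param patients Patient table.
#' @param profile A [cohort_profile()].
#' @param seed Integer RNG seed.
#' @return Tibble of clinical events.
#' @export
generate_events <- function(patients, profile = default_profile(), seed = 1L) {
  stopifnot(nrow(patients) > 0)
  window <- profile$study_window
  ccw_start <- window[2] - 729L  # trailing 2-year reference period
  erp <- profile$event_rate_params
  years <- (as.integer(window[2] - window[1]) + 1L) / 365.25
  withr::with_seed(seed, {
    n <- nrow(patients)
    cls <- sample(names(profile$evidence_class_probs), n, replace = TRUE,
                  prob = profile$evidence_class_probs)
    pid <- patients$patient_id
    has <- function(dt) grepl(dt, cls, fixed = TRUE)

    qual_dx_codes <- c("E11.9", "E11.65", "E11.8", "E11.21", "E11.40")
    qual <- list()

    # qualifying diagnoses: two guaranteed distinct outpatient days in the
    # trailing 730-day period, plus Poisson extras
    i <- which(has("DX"))
    if (length(i) > 0) {
      m <- length(i)
      d1 <- sample.int(730L, m, replace = TRUE) - 1L
      d2 <- (d1 + sample.int(729L, m, replace = TRUE)) %% 730L
      base <- .dx_event(
        rep(pid[i], 2),
        sample(qual_dx_codes, 2 * m, replace = TRUE),
        ccw_start + c(d1, d2),
        "outpatient"
      )
      k <- stats::rpois(m, erp$qual_dx_extra_mean)
      j <- rep(seq_len(m), k)
      extra <- .dx_event(
        pid[i][j],
        sample(qual_dx_codes, length(j), replace = TRUE),
        ccw_start + sample.int(730L, length(j), replace = TRUE) - 1L,
        sample(c("outpatient", "inpatient", "ed"), length(j),
               replace = TRUE, prob = c(0.7, 0.2, 0.1))
      )
      qual$dx <- dplyr::bind_rows(base, extra)
    }

    # qualifying medications: >= 1 antihyperglycemic dispensing in window
    rx_codes <- default_code_sets()$t2d_rx$codes
    i <- which(has("RX"))
    if (length(i) > 0) {
      k <- 1L + stats::rpois(length(i), erp$qual_rx_extra_mean)
      j <- rep(seq_along(i), k)
      qual$rx <- tibble::tibble(
        patient_id = pid[i][j], data_type = "RX", code_system = "RXNORM",
        code = sample(rx_codes, length(j), replace = TRUE),
        event_date = .uniform_dates(length(j), window),
        setting = NA_character_, value = NA_real_, unit = NA_character_
      )
    }

    # qualifying laboratories: two guaranteed distinct-day elevated HbA1c
    # results, plus extras
    i <- which(has("LAB"))
    if (length(i) > 0) {
      m <- length(i)
      nd <- as.integer(window[2] - window[1])  # day offsets 0..nd
      d1 <- sample.int(nd + 1L, m, replace = TRUE) - 1L
      d2 <- (d1 + sample.int(nd, m, replace = TRUE)) %% (nd + 1L)
      k <- stats::rpois(m, erp$qual_lab_extra_mean)
      j <- rep(seq_len(m), k)
      mk_lab <- function(id, date, nn) tibble::tibble(
        patient_id = id, data_type = "LAB", code_system = "LOINC",
        code = sample(c("55454-3", "4548-4"), nn, replace = TRUE,
                      prob = c(0.8, 0.2)),
        event_date = date, setting = NA_character_,
        value = round(stats::runif(nn, 6.6, 11.5), 1), unit = "%"
      )
      qual$lab <- dplyr::bind_rows(
        mk_lab(rep(pid[i], 2), window[1] + c(d1, d2), 2L * m),
        mk_lab(pid[i][j], .uniform_dates(length(j), window), length(j))
      )
    }

    bg <- .background_events(pid, profile, years)
    events <- dplyr::bind_rows(qual$dx, qual$rx, qual$lab, bg)
    events <- dplyr::arrange(events, .data$patient_id, .data$data_type,
                             .data$event_date, .data$code)
    attr(events, "evidence_class") <-
      tibble::tibble(patient_id = pid, evidence_class = cls)
    events
  })
}

# non-qualifying background noise for every patient: common non-diabetes
# diagnoses, non-diabetes medications, normal-range laboratory results
.background_events <- function(pid, profile, years) {
  erp <- profile$event_rate_params
  window <- profile$study_window
  n <- length(pid)
  bg_dx_codes <- c("I10", "J06.9", "M54.5", "K21.9", "E78.5", "F41.9",
                   "N39.0", "R05", "H52.4", "Z00.00")
  bg_rx_codes <- c("29046", "83367", "17767", "7646", "435", "36567",
                   "10582", "8640")
  lab_loincs <- names(profile$lab_value_params)

  k <- stats::rpois(n, erp$bg_dx_per_year * years)
  j <- rep(seq_len(n), k)
  dx <- .dx_event(
    pid[j], sample(bg_dx_codes, length(j), replace = TRUE),
    .uniform_dates(length(j), window),
    sample(c("outpatient", "inpatient", "ed"), length(j), replace = TRUE,
           prob = c(0.8, 0.1, 0.1))
  )

  k <- stats::rpois(n, erp$bg_rx_per_year * years)
  j <- rep(seq_len(n), k)
  rx <- tibble::tibble(
    patient_id = pid[j], data_type = "RX", code_system = "RXNORM",
    code = sample(bg_rx_codes, length(j), replace = TRUE),
    event_date = .uniform_dates(length(j), window),
    setting = NA_character_, value = NA_real_, unit = NA_character_
  )

  k <- stats::rpois(n, erp$bg_lab_per_year * years)
  j <- rep(seq_len(n), k)
  loinc <- sample(lab_loincs, length(j), replace = TRUE)
  val <- numeric(length(j))
  unit <- character(length(j))
  for (lc in lab_loincs) {
    sel <- loinc == lc
    if (!any(sel)) next
    par <- profile$lab_value_params[[lc]]
    m <- sum(sel)
    val[sel] <- switch(
      par$kind,
      hba1c_normal = pmin(pmax(stats::rnorm(m, 5.45, 0.35), 4.2), 6.2),
      uniform = stats::runif(m, par$min, par$max),
      normal = pmax(stats::rnorm(m, par$mean, par$sd), 0.01)
    )
    unit[sel] <- par$unit
  }
  lab <- tibble::tibble(
    patient_id = pid[j], data_type = "LAB", code_system = "LOINC",
    code = loinc, event_date = .uniform_dates(length(j), window),
    setting = NA_character_, value = round(val, 2), unit = unit
  )
  dplyr::bind_rows(dx, rx, lab)
}

# expected mean Charlson score under independent category draws with the
# standard severity hierarchy (complicated diabetes over uncomplicated,
# metastatic over localized malignancy, severe over mild liver disease)
.expected_cci <- function(prev, weights) {
  p <- pmin(prev, 1)
  pair <- function(hi, lo) {
    weights[hi] * p[hi] + weights[lo] * p[lo] * (1 - p[hi])
  }
  pairs <- c("diabetes_complicated", "diabetes_uncomplicated",
             "metastatic_solid_tumor", "any_malignancy",
             "moderate_severe_liver_disease", "mild_liver_disease")
  simple <- setdiff(names(p), pairs)
  sum(weights[simple] * p[simple]) +
    pair("diabetes_complicated", "diabetes_uncomplicated") +
    pair("metastatic_solid_tumor", "any_malignancy") +
    pair("moderate_severe_liver_disease", "mild_liver_disease")
}

.calibrate_charlson_multiplier <- function(profile, map = charlson_map()) {
  w <- stats::setNames(
    vapply(split(map$weight, map$category), `[`, numeric(1), 1),
    names(split(map$weight, map$category))
  )
  prev <- profile$charlson_prevalence
  w <- w[names(prev)]
  f <- function(m) .expected_cci(m * prev, w) - profile$cci_mean
  stats::uniroot(f, interval = c(1e-6, 1 / max(prev)), tol = 1e-9)$root
}

# representative emission codes per category; the two diabetes categories
# deliberately emit type-1 (E10.x) codes so comorbidity noise never satisfies
# the type-2 code set {E11}
.charlson_emit_codes <- list(
  myocardial_infarction = c("I21.9", "I22.0"),
  congestive_heart_failure = c("I50.9", "I42.9"),
  peripheral_vascular_disease = c("I70.2", "I73.9"),
  cerebrovascular_disease = c("I63.9", "I67.9"),
  dementia = c("F03.9", "G30.9"),
  chronic_pulmonary_disease = c("J44.9", "J45.9"),
  rheumatologic_disease = c("M06.9", "M32.9"),
  peptic_ulcer_disease = c("K27.9", "K25.9"),
  mild_liver_disease = c("K74.0", "K73.9"),
  diabetes_uncomplicated = "E10.9",
  diabetes_complicated = c("E10.2", "E10.5"),
  hemiplegia_paraplegia = c("G81.9", "G82.2"),
  renal_disease = c("N18.3", "N18.9"),
  any_malignancy = c("C50.9", "C61", "C34.9"),
  moderate_severe_liver_disease = c("K72.9", "I85.0"),
  metastatic_solid_tumor = c("C78.0", "C79.9"),
  hiv_aids = "B20"
)

#' Generate comorbidity diagnosis events
#'
#' Draws independent per-category comorbidity indicators whose prevalences are
#' the profile's relative prevalences rescaled by a single multiplier, solved
#' analytically so the expected cohort mean Charlson index equals
#' `profile$cci_mean`. Each positive indicator emits one ICD-10 diagnosis
#' event with a representative code from that category (type-1 diabetes codes
#' for the diabetes categories, so comorbidity noise never carries qualifying
#' type-2 evidence). Deterministic given `(patients, profile, seed)`.
#'
#' @inheritParams generate_events
#' @param prevalence_multiplier Optional override of the calibrated global
#'   prevalence multiplier (used e.g. to study score monotonicity).
#' @return Tibble of DX events.
#' @export
generate_comorbidities <- function(patients, profile = default_profile(),
                                   seed = 1L, prevalence_multiplier = NULL) {
  stopifnot(nrow(patients) > 0)
  m <- prevalence_multiplier %||% .calibrate_charlson_multiplier(profile)
  prev <- pmin(m * profile$charlson_prevalence, 1)
  window <- profile$study_window
  withr::with_seed(seed, {
    n <- nrow(patients)
    out <- vector("list", length(prev))
    for (k in seq_along(prev)) {
      cat_name <- names(prev)[k]
      i <- which(stats::runif(n) < prev[k])
      if (length(i) == 0) next
      codes <- .charlson_emit_codes[[cat_name]]
      out[[k]] <- .dx_event(
        patients$patient_id[i],
        if (length(codes) == 1) rep(codes, length(i))
        else sample(codes, length(i), replace = TRUE),
        .uniform_dates(length(i), window),
        sample(c("outpatient", "inpatient"), length(i), replace = TRUE,
               prob = c(0.85, 0.15))
      )
    }
    events <- dplyr::bind_rows(out)
    if (nrow(events) == 0) events <- empty_events()[, EVENT_COLS]
    dplyr::arrange(events, .data$patient_id, .data$event_date, .data$code)
  })
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [generate_patients()] + [generate_events()] +
#' [generate_comorbidities()], combined into a validated [ehr_cohort()] with
#' stable event identities. The evidence-class assignment is preserved as the
#' `evidence_class` attribute of the cohort.
#'
#' @inheritParams generate_patients
#' @return An [ehr_cohort()].
#' @export
generate_cohort <- function(profile = default_profile(), seed = 1L,
                            n = profile$n_patients) {
  patients <- generate_patients(profile, seed = seed, n = n)
  ev <- generate_events(patients, profile, seed = seed + 1L)
  com <- generate_comorbidities(patients, profile, seed = seed + 2L)
  events <- dplyr::bind_rows(ev, com)
  events$event_id <- seq_len(nrow(events))
  out <- ehr_cohort(patients, events, study_window = profile$study_window)
  attr(out, "evidence_class") <- attr(ev, "evidence_class")
  out
}
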