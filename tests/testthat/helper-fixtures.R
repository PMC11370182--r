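# Hand-built fixtures and independent brute-force oracles shared across the
# suite. Oracles deliberately use naive linear scans / exhaustive enumeration
# so they stay independent of the vectorised implementation paths.

make_patients <- function(ids, birth_year = 1960) {
  tibble::tibble(
    patient_id = ids, birth_year = birth_year, sex = "female",
    race = "white", ethnicity = "non_hispanic", state = "MD",
    inpatient_visits = 0L, ed_visits = 0L
  )
}

dx_event <- function(id, code, date, setting = "outpatient") {
  tibble::tibble(
    patient_id = id, data_type = "DX", code_system = "ICD10", code = code,
    event_date = as.Date(date), setting = setting,
    value = NA_real_, unit = NA_character_
  )
}

rx_event <- function(id, code, date) {
  tibble::tibble(
    patient_id = id, data_type = "RX", code_system = "RXNORM", code = code,
    event_date = as.Date(date), setting = NA_character_,
    value = NA_real_, unit = NA_character_
  )
}

lab_event <- function(id, code, date, value, unit = "%") {
  tibble::tibble(
    patient_id = id, data_type = "LAB", code_system = "LOINC", code = code,
    event_date = as.Date(date), setting = NA_character_,
    value = value, unit = unit
  )
}

# memoised mid-size synthetic cohorts so several files can share one
.fixture_env <- new.env(parent = emptyenv())
test_cohort <- function(n = 2000, seed = 7) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(seed = seed, n = n)
  }
  .fixture_env[[key]]
}

# ---- oracles -------------------------------------------------------------

strip_dots <- function(x) gsub(".", "", toupper(x), fixed = TRUE)

oracle_match_code <- function(code, set) {
  x <- strip_dots(code)
  hits <- FALSE
  for (cs in set$codes) {
    hits <- hits || if (set$match_mode == "exact") identical(x, cs)
    else substr(x, 1, nchar(cs)) == cs
  }
  hits
}

# exhaustive single-patient criterion check: every constraint evaluated by
# direct enumeration (combn over candidate day subsets for the span rule)
oracle_criterion <- function(events, crit, window) {
  ev <- events[events$event_date >= window[1] &
                 events$event_date <= window[2], , drop = FALSE]
  ev <- ev[ev$data_type == crit$data_type, , drop = FALSE]
  keep <- vapply(ev$code, oracle_match_code, TRUE, set = crit$set)
  ev <- ev[keep, , drop = FALSE]
  if (!is.null(crit$setting)) {
    ev <- ev[!is.na(ev$setting) & ev$setting == crit$setting, , drop = FALSE]
  }
  if (!is.null(crit$predicate)) {
    p <- crit$predicate
    ok <- !is.na(ev$unit) & ev$unit == p$unit &
      vapply(ev$value, function(v) isTRUE(do.call(p$op, list(v, p$threshold))),
             TRUE)
    ev <- ev[ok, , drop = FALSE]
  }
  days <- as.integer(ev$event_date)
  if (crit$distinct_days) days <- unique(days)
  if (length(days) < crit$min_count) return(FALSE)
  if (is.null(crit$window_days)) return(TRUE)
  combos <- utils::combn(days, crit$min_count)
  any(apply(combos, 2, function(d) max(d) - min(d) <= crit$window_days))
}

oracle_evaluate_phenotype <- function(cohort, defn) {
  window <- if (is.null(defn$reference_period_days)) cohort$study_window
  else c(cohort$study_window[2] - defn$reference_period_days + 1,
         cohort$study_window[2])
  out <- list()
  for (pid in cohort$patients$patient_id) {
    ev <- cohort$events[cohort$events$patient_id == pid, , drop = FALSE]
    types <- character()
    for (pw in defn$pathways) {
      if (all(vapply(pw$criteria, oracle_criterion, TRUE,
                     events = ev, window = window))) {
        types <- union(types, pw$data_types)
      }
    }
    if (length(types) > 0) {
      out[[pid]] <- paste(c("DX", "RX", "LAB")[c("DX", "RX", "LAB") %in% types],
                          collapse = "+")
    }
  }
  out
}

oracle_charlson <- function(dx_codes, map) {
  codes <- strip_dots(dx_codes)
  present <- character()
  for (cat in unique(map$category)) {
    prefixes <- map$prefix[map$category == cat]
    hit <- FALSE
    for (code in codes) {
      for (p in prefixes) hit <- hit || substr(code, 1, nchar(p)) == p
    }
    if (hit) present <- c(present, cat)
  }
  drop_if <- function(present, hi, lo) {
    if (hi %in% present) setdiff(present, lo) else present
  }
  present <- drop_if(present, "diabetes_complicated", "diabetes_uncomplicated")
  present <- drop_if(present, "metastatic_solid_tumor", "any_malignancy")
  present <- drop_if(present, "moderate_severe_liver_disease",
                     "mild_liver_disease")
  w <- map$weight[!duplicated(map$category)]
  names(w) <- map$category[!duplicated(map$category)]
  sum(w[present])
}

# random small cohort with events engineered to exercise every criterion
# feature (settings, repeated days, borderline lab values, odd units)
random_small_cohort <- function(seed, n_patients = 20, max_events = 10) {
  withr::with_seed(seed, {
    ids <- sprintf("Q%03d", seq_len(n_patients))
    rows <- list()
    dates <- seq(as.Date("2017-01-01"), as.Date("2020-06-30"), by = "day")
    for (id in ids) {
      k <- sample(0:max_events, 1)
      if (k == 0) next
      for (j in seq_len(k)) {
        dt <- sample(c("DX", "RX", "LAB"), 1)
        rows[[length(rows) + 1L]] <- switch(
          dt,
          DX = dx_event(id, sample(c("E11.9", "E11.65", "E08.9", "I10", "J06.9"), 1),
                        sample(dates, 1),
                        sample(c("inpatient", "outpatient", "ed"), 1)),
          RX = rx_event(id, sample(c("6809", "860975", "29046", "1545653"), 1),
                        sample(dates, 1)),
          LAB = lab_event(id, sample(c("55454-3", "4548-4", "2345-7"), 1),
                          sample(dates, 1),
                          round(stats::runif(1, 4.5, 9.5), 1),
                          sample(c("%", "mmol/mol"), 1, prob = c(0.8, 0.2)))
        )
      }
    }
    ehr_cohort(make_patients(ids), dplyr::bind_rows(rows))
  })
}
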