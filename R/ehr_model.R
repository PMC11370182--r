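# Canonical in-memory EHR cohort model: demographics + coded event streams,
# code-set matching semantics, study-window filtering, CSV readers/writers.

DATA_TYPES <- c("DX", "RX", "LAB")
CODE_SYSTEMS <- c(DX = "ICD10", RX = "RXNORM", LAB = "LOINC")
SEX_LEVELS <- c("female", "male", "other")
RACE_LEVELS <- c("white", "black", "asian", "other")
ETHNICITY_LEVELS <- c("hispanic", "non_hispanic", "other")
STATE_LEVELS <- c("MD", "other")
SETTING_LEVELS <- c("inpatient", "outpatient", "ed")

PATIENT_COLS <- c(
  "patient_id", "birth_year", "sex", "race", "ethnicity", "state",
  "inpatient_visits", "ed_visits"
)
EVENT_COLS <- c(
  "patient_id", "data_type", "code_system", "code", "event_date",
  "setting", "value", "unit"
)

#' Default study window
#'
#' The three-year observation window all shipped profiles and definitions use:
#' 2017-01-01 through 2019-12-31, closed on both ends.
#'
#' @return A length-2 `Date` vector `c(start, end)`.
#' @export
default_study_window <- function() {
  as.Date(c("2017-01-01", "2019-12-31"))
}

#' Construct an EHR cohort
#'
#' Bundles a patient demographics table, a clinical event table (diagnosis,
#' medication and laboratory streams in long format) and an inclusive study
#' window into a validated `ehr_cohort` object. Events gain a stable integer
#' `event_id` (row order) if they do not already carry one; perturbation
#' operators key their per-event random draws on this identity.
#'
#' @param patients Data frame with columns `patient_id`, `birth_year`, `sex`,
#'   `race`, `ethnicity`, `state`, `inpatient_visits`, `ed_visits`.
#' @param events Data frame with columns `patient_id`, `data_type`,
#'   `code_system`, `code`, `event_date`, `setting`, `value`, `unit`.
#' @param study_window Length-2 `Date` vector, inclusive on both ends.
#' @return An `ehr_cohort`: a list with elements `patients` (tibble),
#'   `events` (tibble) and `study_window`.
#' @export
ehr_cohort <- function(patients, events = empty_events(),
                       study_window = default_study_window()) {
  patients <- tibble::as_tibble(patients)
  events <- tibble::as_tibble(events)
  if (!"event_id" %in% names(events)) {
    events$event_id <- seq_len(nrow(events))
  }
  x <- structure(
    list(patients = patients, events = events,
         study_window = as.Date(study_window)),
    class = "ehr_cohort"
  )
  validate_cohort(x)
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf(
    "<ehr_cohort> %d patients, %d events (%s DX / %s RX / %s LAB), window %s..%s\n",
    nrow(x$patients), nrow(x$events),
    sum(x$events$data_type == "DX"), sum(x$events$data_type == "RX"),
    sum(x$events$data_type == "LAB"),
    format(x$study_window[1]), format(x$study_window[2])
  ))
  invisible(x)
}

#' An empty, correctly-typed event table
#' @return Zero-row tibble with the clinical event columns plus `event_id`.
#' @export
empty_events <- function() {
  tibble::tibble(
    patient_id = character(), data_type = character(),
    code_system = character(), code = character(),
    event_date = as.Date(character()), setting = character(),
    value = double(), unit = character(), event_id = integer()
  )
}

validate_cohort <- function(x) {
  p <- x$patients
  e <- x$events
  miss <- setdiff(PATIENT_COLS, names(p))
  if (length(miss) > 0) {
    stop("demographics table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(EVENT_COLS, names(e))
  if (length(miss) > 0) {
    stop("event table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(p$patient_id)) {
    stop("patient_id must be unique within a cohort", call. = FALSE)
  }
  if (length(x$study_window) != 2 || x$study_window[1] > x$study_window[2]) {
    stop("study_window must be an inclusive c(start, end) with start <= end",
         call. = FALSE)
  }
  start_year <- as.integer(format(x$study_window[1], "%Y"))
  age <- start_year - p$birth_year
  if (nrow(p) > 0 && (any(age < 18) || any(age > 90))) {
    stop("patient age at study start must lie in [18, 90]", call. = FALSE)
  }
  if (nrow(e) > 0) {
    unknown <- setdiff(unique(e$patient_id), p$patient_id)
    if (length(unknown) > 0) {
      stop("integrity error: event(s) reference unknown patient_id: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    bad <- e$code_system != CODE_SYSTEMS[e$data_type]
    if (any(bad, na.rm = TRUE)) {
      stop("data_type/code_system mismatch (DX<->ICD10, RX<->RXNORM, LAB<->LOINC)",
           call. = FALSE)
    }
    lab <- e$data_type == "LAB"
    if (any(lab & (is.na(e$value) | is.na(e$unit)))) {
      stop("LAB events must carry a value and a unit", call. = FALSE)
    }
    if (any(!lab & (!is.na(e$value) | !is.na(e$unit)))) {
      stop("DX/RX events must not carry a value or unit", call. = FALSE)
    }
  }
  x
}

#' Read a cohort from CSV
#'
#' Reads the two-file cohort interchange format (a demographics CSV and an
#' events CSV, empty string for not-applicable fields) and validates it:
#' schema, date parsing (with row numbers on failure), referential integrity
#' and the per-data-type code-system pairing.
#'
#' @param demographics_path,events_path Paths to the two CSV files.
#' @param study_window Inclusive study window (`Date` length 2).
#' @return An [ehr_cohort()].
#' @export
read_cohort <- function(demographics_path, events_path,
                        study_window = default_study_window()) {
  p <- readr::read_csv(demographics_path, na = "", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  miss <- setdiff(PATIENT_COLS, names(p))
  if (length(miss) > 0) {
    stop("schema error: demographics file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  p <- dplyr::mutate(
    p,
    birth_year = as.integer(.data$birth_year),
    inpatient_visits = as.integer(.data$inpatient_visits),
    ed_visits = as.integer(.data$ed_visits)
  )
  e <- readr::read_csv(events_path, na = "", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  miss <- setdiff(EVENT_COLS, names(e))
  if (length(miss) > 0) {
    stop("schema error: events file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(e) > 0) {
    dates <- as.Date(e$event_date, format = "%Y-%m-%d")
    bad <- which(is.na(dates) & !is.na(e$event_date))
    if (length(bad) > 0) {
      stop("parse error: unparseable event_date at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    e$event_date <- dates
    e$value <- as.numeric(e$value)
  } else {
    e <- empty_events()[, EVENT_COLS]
  }
  ehr_cohort(p, e, study_window = study_window)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: writes `demographics.csv` and `events.csv`
#' under `out_dir` such that reading them back reproduces the cohort
#' field-for-field. Not-applicable fields are written as empty strings.
#'
#' @param cohort An [ehr_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the two file paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  dem <- file.path(out_dir, "demographics.csv")
  eve <- file.path(out_dir, "events.csv")
  readr::write_csv(cohort$patients[, PATIENT_COLS], dem, na = "")
  readr::write_csv(cohort$events[, EVENT_COLS], eve, na = "")
  invisible(c(demographics = dem, events = eve))
}

#' Define a code set
#'
#' A named list of codes in one terminology with a matching mode. Matching is
#' performed on dot-stripped, upper-cased codes; in `prefix` mode a code
#' matches when any listed code is a prefix of it (so `E11` matches `E11.9`),
#' which is how ICD-10 family codes are conventionally applied.
#'
#' @param name Code-set name.
#' @param code_system One of `"ICD10"`, `"RXNORM"`, `"LOINC"`.
#' @param codes Character vector of codes.
#' @param match_mode `"exact"` or `"prefix"`.
#' @return A `code_set` object.
#' @export
code_set <- function(name, code_system, codes, match_mode = c("exact", "prefix")) {
  match_mode <- match.arg(match_mode)
  code_system <- match.arg(code_system, unname(CODE_SYSTEMS))
  codes <- unique(as.character(codes))
  if (code_system == "ICD10" &&
      !all(grepl("^[A-Za-z][0-9][0-9A-Za-z](\\.?[0-9A-Za-z]{0,4})?$", codes))) {
    stop("invalid ICD-10 code(s) in set '", name, "'", call. = FALSE)
  }
  if (code_system != "ICD10" && !all(grepl("^[0-9][0-9-]*$", codes))) {
    stop("invalid ", code_system, " code(s) in set '", name, "'", call. = FALSE)
  }
  structure(
    list(name = name, code_system = code_system,
         codes = normalize_code(codes), match_mode = match_mode),
    class = "code_set"
  )
}

normalize_code <- function(code) gsub(".", "", toupper(code), fixed = TRUE)

#' Match codes against a code set
#'
#' Vectorised over `code`. Codes are dot-stripped and upper-cased before
#' comparison; `exact` mode is set membership, `prefix` mode is true when any
#' listed code is a leading substring of the normalised code.
#'
#' @param code Character vector of codes (same terminology as the set).
#' @param set A [code_set()].
#' @param code_system Optional terminology of `code`; when supplied it must
#'   agree with the set's (cross-system comparison is a usage error).
#' @return Logical vector.
#' @export
match_code <- function(code, set, code_system = NULL) {
  stopifnot(inherits(set, "code_set"))
  if (!is.null(code_system) && any(code_system != set$code_system)) {
    stop("cross-system code comparison: codes are ",
         paste(unique(code_system), collapse = "/"),
         " but code set '", set$name, "' is ", set$code_system, call. = FALSE)
  }
  x <- normalize_code(code)
  if (set$match_mode == "exact") {
    x %in% set$codes
  } else {
    out <- logical(length(x))
    for (p in set$codes) out <- out | startsWith(x, p)
    out
  }
}

#' Filter events to a date window
#'
#' Keeps events whose `event_date` lies inside the closed interval
#' `[window[1], window[2]]`, preserving input order.
#'
#' @param events Clinical event table.
#' @param window Length-2 `Date` vector (inclusive); must not be inverted.
#' @return Filtered tibble.
#' @export
filter_window <- function(events, window) {
  window <- as.Date(window)
  if (length(window) != 2 || is.na(window[1]) || is.na(window[2]) ||
      window[1] > window[2]) {
    stop("window must be a non-empty inclusive interval c(start, end)",
         call. = FALSE)
  }
  dplyr::filter(events, .data$event_date >= window[1],
                .data$event_date <= window[2])
}

#' Age of each patient at study start
#' @param patients Patient table.
#' @param study_window Study window; ages are taken at its start year.
#' @return Integer vector of ages.
#' @export
patient_age <- function(patients, study_window = default_study_window()) {
  as.integer(format(as.Date(study_window[1]), "%Y")) - patients$birth_year
}
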