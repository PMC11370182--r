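# Declarative computable-phenotype language: criteria over code sets with
# count / temporal / value constraints, conjoined into pathways, disjoined
# into definitions. Five type-2-diabetes definitions ship as YAML configs.

PHENOTYPE_NAMES <- c("CCW", "DDC", "SUPREME_DM", "EMERGE", "JHU")
STRATA <- c("DX", "RX", "LAB", "DX+RX", "DX+LAB", "RX+LAB", "DX+RX+LAB")

#' Load the shipped default code sets
#' @param path Optional alternative YAML file in the same schema.
#' @return Named list of [code_set()] objects.
#' @export
default_code_sets <- function(path = NULL) {
  path <- path %||% system.file("extdata", "code_sets.yaml", package = "dqpheno")
  raw <- yaml::read_yaml(path)
  purrr::imap(raw, function(x, nm) {
    code_set(nm, x$code_system, as.character(x$codes), x$match_mode)
  })
}

#' Construct a phenotype criterion
#'
#' One atomic requirement over a single data type: at least `min_count`
#' events matching `set` (optionally on distinct days, in a given care
#' setting, within some span of `window_days`, and — for laboratories —
#' satisfying a value predicate with an exact unit match).
#'
#' @param data_type `"DX"`, `"RX"` or `"LAB"`.
#' @param set A [code_set()].
#' @param min_count Minimum number of qualifying events (>= 1).
#' @param distinct_days Count events on distinct calendar days only.
#' @param setting Optional care-setting filter (DX events).
#' @param window_days Optional span: `min_count` qualifying events must fall
#'   inside some window of this many days (requires `min_count >= 2`).
#' @param predicate Optional list `list(op, threshold, unit)` with `op` one of
#'   `">=", ">", "<=", "<"`; LAB only. Events whose unit differs from
#'   `predicate$unit` never satisfy the predicate (no unit conversion).
#' @return A `phenotype_criterion`.
#' @export
criterion <- function(data_type, set, min_count = 1L, distinct_days = FALSE,
                      setting = NULL, window_days = NULL, predicate = NULL) {
  data_type <- match.arg(data_type, DATA_TYPES)
  stopifnot(inherits(set, "code_set"), min_count >= 1)
  if (set$code_system != CODE_SYSTEMS[data_type]) {
    stop("code set '", set$name, "' (", set$code_system,
         ") cannot be used for data type ", data_type, call. = FALSE)
  }
  if (!is.null(predicate)) {
    if (data_type != "LAB") {
      stop("value predicates apply to LAB criteria only", call. = FALSE)
    }
    stopifnot(predicate$op %in% c(">=", ">", "<=", "<"),
              is.numeric(predicate$threshold), is.character(predicate$unit))
  }
  if (!is.null(window_days) && min_count < 2) {
    stop("window_days requires min_count >= 2", call. = FALSE)
  }
  if (!is.null(setting)) setting <- match.arg(setting, SETTING_LEVELS)
  structure(
    list(data_type = data_type, set = set, min_count = as.integer(min_count),
         distinct_days = isTRUE(distinct_days), setting = setting,
         window_days = if (!is.null(window_days)) as.integer(window_days),
         predicate = predicate),
    class = "phenotype_criterion"
  )
}

#' Construct a care pathway (conjunction of criteria)
#' @param name Pathway name.
#' @param criteria Non-empty list of [criterion()] objects, all of which must
#'   hold for the pathway to identify a patient.
#' @return A `phenotype_pathway`.
#' @export
pathway <- function(name, criteria) {
  stopifnot(length(criteria) > 0,
            all(vapply(criteria, inherits, TRUE, "phenotype_criterion")))
  structure(list(name = name, criteria = criteria,
                 data_types = sort(unique(vapply(criteria, `[[`, "", "data_type")))),
       class = "phenotype_pathway")
}

.check_structure <- function(name, pathways, reference_period_days) {
  unions <- lapply(pathways, function(p) p$data_types)
  key <- vapply(unions, paste, "", collapse = "+")
  if (name == "CCW") {
    if (!all(key == "DX")) {
      stop("structural violation: CCW may contain diagnosis criteria only",
           call. = FALSE)
    }
    if (!identical(reference_period_days, 730L)) {
      stop("structural violation: CCW requires a 730-day reference period",
           call. = FALSE)
    }
  }
  if (name == "JHU") {
    single <- all(vapply(pathways, function(p) length(p$criteria), 1L) == 1L)
    if (!single || !setequal(key, c("DX", "RX", "LAB")) || length(key) != 3) {
      stop("structural violation: JHU must be exactly three single-criterion ",
           "pathways, one per data type", call. = FALSE)
    }
  }
  if (name == "EMERGE" && any(key %in% c("DX", "RX", "LAB+RX"))) {
    stop("structural violation: eMERGE admits no diagnosis-only, ",
         "medication-only or medication+laboratory-only pathway",
         call. = FALSE)
  }
  if (name == "SUPREME_DM" && any(key == "RX")) {
    stop("structural violation: SUPREME-DM admits no medication-only pathway",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a phenotype definition (disjunction of pathways)
#'
#' Per-name structural invariants are enforced: CCW is diagnosis-only with a
#' 730-day reference period; JHU is exactly three single-criterion pathways
#' (one per data type); eMERGE has no diagnosis-only, medication-only or
#' medication+laboratory-only pathway; SUPREME-DM has no medication-only
#' pathway.
#'
#' @param name One of `"CCW", "DDC", "SUPREME_DM", "EMERGE", "JHU"`.
#' @param pathways List of [pathway()] objects (any one identifies).
#' @param reference_period_days Optional trailing reference period; events are
#'   counted in the trailing window of this many days anchored at the study
#'   window end (default: whole study window).
#' @return A `phenotype_definition`.
#' @export
phenotype_definition <- function(name, pathways, reference_period_days = NULL) {
  name <- match.arg(name, PHENOTYPE_NAMES)
  stopifnot(length(pathways) > 0,
            all(vapply(pathways, inherits, TRUE, "phenotype_pathway")))
  if (!is.null(reference_period_days)) {
    reference_period_days <- as.integer(reference_period_days)
  }
  .check_structure(name, pathways, reference_period_days)
  structure(
    list(name = name, pathways = pathways,
         reference_period_days = reference_period_days),
    class = "phenotype_definition"
  )
}

#' @export
print.phenotype_definition <- function(x, ...) {
  cat(sprintf("<phenotype_definition> %s: %d pathway(s)%s\n", x$name,
              length(x$pathways),
              if (is.null(x$reference_period_days)) ""
              else sprintf(", %d-day reference period", x$reference_period_days)))
  for (p in x$pathways) {
    cat(sprintf("  - %s [%s]\n", p$name, paste(p$data_types, collapse = "+")))
  }
  invisible(x)
}

#' Compile a phenotype definition from a config document
#'
#' Accepts a YAML file path or an already-parsed list in the config schema
#' (`name`, optional `reference_period_days`, `pathways[{name,
#' criteria[{data_type, code_set, min_count, distinct_days, setting,
#' window_days, predicate{op, threshold, unit}}]}]`). Code-set references are
#' resolved against `code_sets`; unresolvable references and structural
#' violations are compile-time errors.
#'
#' @param config File path or list.
#' @param code_sets Named list of [code_set()] objects
#'   (default: [default_code_sets()]).
#' @return A [phenotype_definition()].
#' @export
compile_definition <- function(config, code_sets = default_code_sets()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$name), !is.null(config$pathways))
  pws <- purrr::map(config$pathways, function(pw) {
    crits <- purrr::map(pw$criteria, function(cr) {
      set <- code_sets[[cr$code_set]]
      if (is.null(set)) {
        stop("resolution error: unknown code set '", cr$code_set, "'",
             call. = FALSE)
      }
      criterion(
        data_type = cr$data_type, set = set,
        min_count = cr$min_count %||% 1L,
        distinct_days = isTRUE(cr$distinct_days),
        setting = cr$setting, window_days = cr$window_days,
        predicate = cr$predicate
      )
    })
    pathway(pw$name %||% "unnamed", crits)
  })
  phenotype_definition(config$name, pws,
                       reference_period_days = config$reference_period_days)
}

#' Load the shipped type-2-diabetes definitions
#'
#' @param names Which definitions to load (default all five).
#' @param code_sets Code-set environment to resolve against.
#' @return Named list of [phenotype_definition()] objects.
#' @export
shipped_definitions <- function(names = PHENOTYPE_NAMES,
                                code_sets = default_code_sets()) {
  files <- c(CCW = "ccw.yaml", DDC = "ddc.yaml", SUPREME_DM = "supreme_dm.yaml",
             EMERGE = "emerge.yaml", JHU = "jhu.yaml")
  names <- match.arg(names, PHENOTYPE_NAMES, several.ok = TRUE)
  purrr::map(
    stats::setNames(names, names),
    function(nm) {
      compile_definition(
        system.file("extdata", "phenotypes", files[[nm]], package = "dqpheno"),
        code_sets = code_sets
      )
    }
  )
}

# TRUE when the (already qualifying) event days can satisfy the count /
# distinct-day / span constraints
.count_ok <- function(days, min_count, distinct_days, window_days) {
  d <- as.integer(days)
  if (distinct_days) d <- unique(d)
  if (length(d) < min_count) return(FALSE)
  if (is.null(window_days)) return(TRUE)
  d <- sort(d)
  i <- seq_len(length(d) - min_count + 1L)
  any(d[i + min_count - 1L] - d[i] <= window_days)
}

# events matching a criterion's code set, setting and value predicate
.matching_events <- function(events, crit) {
  ev <- events[events$data_type == crit$data_type, , drop = FALSE]
  ev <- ev[match_code(ev$code, crit$set), , drop = FALSE]
  if (!is.null(crit$setting)) {
    ev <- ev[!is.na(ev$setting) & ev$setting == crit$setting, , drop = FALSE]
  }
  if (!is.null(crit$predicate)) {
    p <- crit$predicate
    ok <- !is.na(ev$unit) & ev$unit == p$unit & !is.na(ev$value) &
      do.call(p$op, list(ev$value, p$threshold))
    ev <- ev[ok, , drop = FALSE]
  }
  ev
}

# patient ids satisfying a criterion, vectorised over a multi-patient table
.satisfying_patients <- function(events, crit, window) {
  ev <- .matching_events(filter_window(events, window), crit)
  if (nrow(ev) == 0) return(character())
  if (is.null(crit$window_days)) {
    # fast path: a plain (distinct-day) count threshold
    if (crit$distinct_days) {
      ev <- dplyr::distinct(ev, .data$patient_id, .data$event_date)
    }
    tab <- table(ev$patient_id)
    return(names(tab)[tab >= crit$min_count])
  }
  ok <- vapply(
    split(ev$event_date, ev$patient_id),
    .count_ok, TRUE,
    min_count = crit$min_count, distinct_days = crit$distinct_days,
    window_days = crit$window_days
  )
  names(ok)[ok]
}

#' Evaluate one criterion for one patient
#'
#' @param events Event table of a single patient.
#' @param crit A [criterion()].
#' @param window Inclusive date interval to count within.
#' @return `TRUE`/`FALSE` (an empty table is `FALSE`).
#' @export
evaluate_criterion <- function(events, crit, window = default_study_window()) {
  stopifnot(inherits(crit, "phenotype_criterion"))
  if (nrow(events) == 0) return(FALSE)
  if (length(unique(events$patient_id)) > 1) {
    stop("evaluate_criterion expects events of a single patient; use ",
         "evaluate_phenotype for cohorts", call. = FALSE)
  }
  length(.satisfying_patients(events, crit, window)) > 0
}

.reference_window <- function(defn, study_window) {
  if (is.null(defn$reference_period_days)) return(study_window)
  c(study_window[2] - defn$reference_period_days + 1L, study_window[2])
}

#' Apply a phenotype definition to a cohort
#'
#' A patient is identified when at least one pathway has all of its criteria
#' satisfied on the patient's events, restricted to the definition's
#' reference window (the trailing `reference_period_days` of the study
#' window, or the whole window). The evidence profile of an identified
#' patient is the union of data types over *satisfied* pathways — the data
#' types that actually did the identifying, not all data types present in
#' the record.
#'
#' @param cohort An [ehr_cohort()].
#' @param defn A [phenotype_definition()].
#' @return A `phenotype_result`: list with `phenotype`, `identified`
#'   (character vector of patient ids), `evidence_profile` (tibble
#'   `patient_id`, `profile`), `n_identified`, `n_cohort`.
#' @export
evaluate_phenotype <- function(cohort, defn) {
  stopifnot(inherits(cohort, "ehr_cohort"), inherits(defn, "phenotype_definition"))
  window <- .reference_window(defn, cohort$study_window)
  per_pathway <- purrr::map(defn$pathways, function(pw) {
    sets <- lapply(pw$criteria, function(cr)
      .satisfying_patients(cohort$events, cr, window))
    sat <- Reduce(intersect, sets)
    tibble::tibble(
      patient_id = sat,
      dx = "DX" %in% pw$data_types,
      rx = "RX" %in% pw$data_types,
      lab = "LAB" %in% pw$data_types
    )
  })
  prof <- dplyr::bind_rows(per_pathway)
  prof <- dplyr::summarise(
    dplyr::group_by(prof, .data$patient_id),
    dx = any(.data$dx), rx = any(.data$rx), lab = any(.data$lab),
    .groups = "drop"
  )
  labels <- paste0(ifelse(prof$dx, "DX+", ""), ifelse(prof$rx, "RX+", ""),
                   ifelse(prof$lab, "LAB+", ""))
  prof$profile <- sub("\\+$", "", labels)
  structure(
    list(
      phenotype = defn$name,
      identified = prof$patient_id,
      evidence_profile = prof[, c("patient_id", "profile")],
      n_identified = nrow(prof),
      n_cohort = nrow(cohort$patients)
    ),
    class = "phenotype_result"
  )
}

#' @export
print.phenotype_result <- function(x, ...) {
  cat(sprintf("<phenotype_result> %s: %d / %d patients identified\n",
              x$phenotype, x$n_identified, x$n_cohort))
  invisible(x)
}

#' Data-type strata of an identification result
#'
#' Partitions identified patients into the 7 possible evidence-profile
#' combinations of diagnosis, medication and laboratory data. Strata counts
#' sum to the number of identified patients; structurally impossible strata
#' report zero.
#'
#' @param result A `phenotype_result`.
#' @return Tibble with columns `phenotype`, `stratum`, `n` (all 7 strata).
#' @export
data_type_stratum <- function(result) {
  stopifnot(inherits(result, "phenotype_result"))
  counts <- table(factor(result$evidence_profile$profile, levels = STRATA))
  tibble::tibble(
    phenotype = result$phenotype,
    stratum = STRATA,
    n = as.integer(counts)
  )
}

#' Tidy an identification result into per-patient rows
#' @param x A `phenotype_result`.
#' @param ... Unused.
#' @return Tibble `phenotype`, `patient_id`, `profile`.
#' @importFrom generics tidy
#' @method tidy phenotype_result
#' @export
tidy.phenotype_result <- function(x, ...) {
  dplyr::mutate(x$evidence_profile, phenotype = x$phenotype,
                .before = "patient_id")
}

#' One-row summary of an identification result
#' @param x A `phenotype_result`.
#' @param ... Unused.
#' @return One-row tibble with counts and the identified fraction.
#' @importFrom generics glance
#' @method glance phenotype_result
#' @export
glance.phenotype_result <- function(x, ...) {
  tibble::tibble(
    phenotype = x$phenotype,
    n_identified = x$n_identified,
    n_cohort = x$n_cohort,
    fraction_identified = x$n_identified / x$n_cohort
  )
}
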