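# Charlson comorbidity index over ICD-10 diagnosis events, using the Quan
# (2005) category prefixes with the original Charlson weights (1/2/3/6).
# The map ships as a plain-text data file and is fully replaceable.

#' Load a Charlson category map
#'
#' The shipped map is the Quan ICD-10 coding of the 17 Charlson categories
#' with original weights. Prefixes are matched on dot-stripped codes. The
#' standard severity hierarchy is applied at scoring time: complicated
#' diabetes supersedes uncomplicated, metastatic solid tumour supersedes
#' localized malignancy, and moderate/severe liver disease supersedes mild.
#'
#' @param path Optional alternative CSV with columns
#'   `category`, `weight`, `prefix`.
#' @return Tibble with one row per (category, prefix).
#' @export
charlson_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "charlson_quan_icd10.csv",
                                package = "dqpheno")
  map <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           category = readr::col_character(),
                           weight = readr::col_integer(),
                           prefix = readr::col_character()
                         ))
  if (!all(map$weight %in% c(1L, 2L, 3L, 6L))) {
    stop("Charlson weights must be in {1, 2, 3, 6}", call. = FALSE)
  }
  map$prefix <- normalize_code(map$prefix)
  map
}

.CHARLSON_HIERARCHY <- list(
  c(keep = "diabetes_complicated", drop = "diabetes_uncomplicated"),
  c(keep = "metastatic_solid_tumor", drop = "any_malignancy"),
  c(keep = "moderate_severe_liver_disease", drop = "mild_liver_disease")
)

# (patient_id, category, weight) flags for every matched category
.charlson_flags <- function(events, map) {
  dx <- events[events$data_type == "DX", c("patient_id", "code"), drop = FALSE]
  codes <- unique(normalize_code(dx$code))
  hit <- list()
  for (k in seq_len(nrow(map))) {
    m <- codes[startsWith(codes, map$prefix[k])]
    if (length(m) > 0) {
      hit[[length(hit) + 1L]] <- tibble::tibble(
        norm_code = m, category = map$category[k], weight = map$weight[k]
      )
    }
  }
  lut <- dplyr::distinct(dplyr::bind_rows(hit))
  if (nrow(lut) == 0) {
    return(tibble::tibble(patient_id = character(), category = character(),
                          weight = integer()))
  }
  dx$norm_code <- normalize_code(dx$code)
  flags <- dplyr::inner_join(dx, lut, by = "norm_code",
                             relationship = "many-to-many")
  dplyr::distinct(flags, .data$patient_id, .data$category, .data$weight)
}

#' Charlson index for every patient in an event table
#'
#' Each of the 17 comorbidity categories contributes its weight once when at
#' least one diagnosis code matches it; the severity hierarchy then removes
#' the milder member of each superseded pair. Patients with no matching
#' events are absent from the result (their score is 0).
#'
#' @param events Clinical event table (non-DX rows are ignored).
#' @param map A [charlson_map()].
#' @return Tibble `patient_id`, `charlson_index`.
#' @export
charlson_scores <- function(events, map = charlson_map()) {
  flags <- .charlson_flags(events, map)
  for (h in .CHARLSON_HIERARCHY) {
    sup <- flags$patient_id[flags$category == h[["keep"]]]
    flags <- flags[!(flags$category == h[["drop"]] &
                       flags$patient_id %in% sup), , drop = FALSE]
  }
  dplyr::summarise(dplyr::group_by(flags, .data$patient_id),
                   charlson_index = sum(.data$weight), .groups = "drop")
}

#' Charlson index of a single patient
#'
#' @param dx_events Event table of one patient (DX rows are scored).
#' @param map A [charlson_map()].
#' @return Integer score (0 when nothing matches).
#' @export
charlson_index <- function(dx_events, map = charlson_map()) {
  if (nrow(dx_events) == 0) return(0L)
  if (length(unique(dx_events$patient_id)) > 1) {
    stop("charlson_index expects events of a single patient; use ",
         "charlson_scores for cohorts", call. = FALSE)
  }
  s <- charlson_scores(dx_events, map)
  if (nrow(s) == 0) 0L else as.integer(s$charlson_index)
}

#' Mean Charlson index of a cohort (zero-filled)
#' @param cohort An [ehr_cohort()].
#' @param map A [charlson_map()].
#' @return Tibble `patient_id`, `charlson_index` covering every patient.
#' @export
cohort_charlson <- function(cohort, map = charlson_map()) {
  s <- charlson_scores(cohort$events, map)
  out <- dplyr::left_join(cohort$patients["patient_id"], s, by = "patient_id")
  out$charlson_index[is.na(out$charlson_index)] <- 0L
  out
}
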