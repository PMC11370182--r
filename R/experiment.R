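# Experiment orchestration: perturbation grids across phenotypes, retention
# curves, 31-region overlap partitions, data-type strata, Table-1-style
# cohort characteristics, and report export.

GRID_AXES <- c("incompleteness", "inaccuracy", "timeliness",
               "compound_incompleteness", "compound_inaccuracy",
               "compound_timeliness")

.axis_defaults <- function(axis) {
  switch(
    axis,
    incompleteness = list(levels = drop_grid(),
                          targets = as.list(DATA_TYPES)),
    inaccuracy = list(levels = drop_grid(),
                      targets = as.list(DATA_TYPES),
                      lab_levels = lab_scale_grid()),
    timeliness = list(levels = c(0L, shift_grid()),
                      targets = as.list(DATA_TYPES)),
    compound_incompleteness = list(levels = drop_grid(),
                                   targets = list(DATA_TYPES)),
    compound_inaccuracy = list(levels = drop_grid(),
                               targets = list(DATA_TYPES)),
    compound_timeliness = list(levels = c(0L, shift_grid()),
                               targets = list(DATA_TYPES))
  )
}

.axis_spec <- function(axis, target, level, seed, pool) {
  tgt <- unlist(target)
  switch(
    axis,
    incompleteness = perturbation("drop", tgt, level, seed),
    inaccuracy = {
      if (identical(tgt, "LAB")) {
        perturbation("scale_lab_value", "LAB", level)
      } else {
        perturbation("replace_code", tgt, level, seed, pool = pool)
      }
    },
    timeliness = perturbation("shift_dates", tgt, level),
    compound_incompleteness = perturbation("drop", tgt, level, seed),
    compound_inaccuracy = perturbation(
      "compound",
      children = list(
        perturbation("replace_code", c("DX", "RX"), level, seed, pool = pool),
        # laboratories are not replaced; their values are pushed down instead
        perturbation("scale_lab_value", "LAB", -level)
      )
    ),
    compound_timeliness = perturbation("shift_dates", tgt, level)
  )
}

.axis_is_stochastic <- function(axis, target) {
  if (axis %in% c("timeliness", "compound_timeliness")) return(FALSE)
  if (axis == "inaccuracy" && identical(unlist(target), "LAB")) return(FALSE)
  TRUE
}

#' Run a perturbation grid over phenotype definitions
#'
#' For every (data-type target, level, replicate seed) the named axis's
#' perturbation is applied to the cohort, every definition is re-evaluated,
#' and the identified count is recorded together with its retention: the
#' count divided by the same replicate's baseline at the identity level
#' (level 0), which equals the unperturbed evaluation. The fraction of the
#' whole cohort identified is also emitted (`fraction_of_cohort`), since
#' either denominator is of interest. Compound axes target all three data
#' types simultaneously; deterministic axes (date shifts, laboratory value
#' scaling) run a single replicate with `replicate_seed = NA`.
#'
#' @param cohort An [ehr_cohort()].
#' @param definitions Named list of [phenotype_definition()] objects.
#' @param axis One of `"incompleteness"`, `"inaccuracy"`, `"timeliness"`,
#'   `"compound_incompleteness"`, `"compound_inaccuracy"`,
#'   `"compound_timeliness"`.
#' @param levels Perturbation levels; must include the identity level 0.
#'   Defaults to the study grids ([drop_grid()], [lab_scale_grid()],
#'   [shift_grid()] with 0 prepended).
#' @param data_type_targets List of data-type targets (defaults per axis).
#' @param seeds Replicate seeds for stochastic axes (default `1:5`).
#' @param pool Optional replacement pool override for inaccuracy axes.
#' @param lab_levels Levels for the LAB target of the inaccuracy axis
#'   (default [lab_scale_grid()]).
#' @return A `dq_grid` tibble: `axis`, `phenotype`, `data_type_target`,
#'   `level`, `replicate_seed`, `n_identified`, `baseline_n`, `retention`,
#'   `fraction_of_cohort`.
#' @export
run_grid <- function(cohort, definitions, axis = GRID_AXES,
                     levels = NULL, data_type_targets = NULL, seeds = 1:5,
                     pool = NULL, lab_levels = NULL) {
  axis <- match.arg(axis)
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (is.null(names(definitions))) {
    names(definitions) <- vapply(definitions, `[[`, "", "name")
  }
  defaults <- .axis_defaults(axis)
  data_type_targets <- data_type_targets %||% defaults$targets
  base_levels <- levels %||% defaults$levels
  lab_levels <- lab_levels %||% defaults$lab_levels %||% base_levels

  rows <- list()
  for (target in data_type_targets) {
    target_label <- paste(unlist(target), collapse = "+")
    lv <- if (axis == "inaccuracy" && identical(unlist(target), "LAB")) {
      lab_levels
    } else {
      base_levels
    }
    if (!any(lv == 0)) {
      stop("config error: levels for target ", target_label,
           " must include the identity level 0", call. = FALSE)
    }
    run_seeds <- if (.axis_is_stochastic(axis, target)) seeds else NA_integer_
    for (seed in run_seeds) {
      for (level in lv) {
        spec <- .axis_spec(axis, target, level,
                           if (is.na(seed)) 1L else seed, pool)
        pert <- apply_perturbation(cohort, spec)
        for (defn in definitions) {
          res <- evaluate_phenotype(pert, defn)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            axis = axis, phenotype = defn$name,
            data_type_target = target_label, level = level,
            replicate_seed = seed, n_identified = res$n_identified,
            n_cohort = res$n_cohort
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  base <- dplyr::filter(out, .data$level == 0)
  base <- dplyr::select(base, "phenotype", "data_type_target",
                        "replicate_seed", baseline_n = "n_identified")
  out <- dplyr::left_join(
    out, base, by = c("phenotype", "data_type_target", "replicate_seed")
  )
  out <- dplyr::mutate(
    out,
    retention = ifelse(.data$baseline_n > 0,
                       .data$n_identified / .data$baseline_n, NA_real_),
    fraction_of_cohort = .data$n_identified / .data$n_cohort
  )
  out <- dplyr::select(out, -"n_cohort")
  class(out) <- c("dq_grid", class(out))
  out
}

#' Overlap partition of identified populations
#'
#' Partitions the union of identified patients into the 2^k - 1 disjoint
#' membership regions (31 for the five shipped definitions): each region
#' counts the patients identified by *exactly* that subset of phenotypes.
#'
#' @param results List of `phenotype_result` objects from the same cohort;
#'   duplicate phenotype names are a usage error.
#' @param denominator_n Total cohort size (default: taken from the results).
#' @return A `dq_overlap` tibble with columns `region` (e.g. `"CCW+DDC"`),
#'   `k` (subset size) and `n`, covering all non-empty subsets; attributes
#'   `denominator_n`, `union_n` (patients in >= 1 phenotype) and
#'   `intersection_n` (patients in all phenotypes).
#' @export
overlap_partition <- function(results, denominator_n = NULL) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "phenotype_result")))
  nms <- vapply(results, `[[`, "", "phenotype")
  if (anyDuplicated(nms)) {
    stop("usage error: duplicate phenotype names in results", call. = FALSE)
  }
  denominator_n <- denominator_n %||% results[[1]]$n_cohort
  ids <- unique(unlist(lapply(results, `[[`, "identified")))
  member <- vapply(results, function(r) ids %in% r$identified,
                   logical(length(ids)))
  member <- matrix(member, nrow = length(ids), dimnames = list(NULL, nms))
  key <- apply(member, 1, function(m) paste(nms[m], collapse = "+"))
  counts <- table(key)

  subsets <- unlist(lapply(seq_along(nms), function(k) {
    apply(utils::combn(nms, k), 2, paste, collapse = "+")
  }))
  out <- tibble::tibble(
    region = subsets,
    k = lengths(strsplit(subsets, "+", fixed = TRUE)),
    n = as.integer(ifelse(is.na(counts[subsets]), 0L, counts[subsets]))
  )
  attr(out, "denominator_n") <- denominator_n
  attr(out, "union_n") <- length(ids)
  attr(out, "intersection_n") <- out$n[out$region == paste(nms, collapse = "+")]
  class(out) <- c("dq_overlap", class(out))
  out
}

#' One-row summary of an overlap partition
#' @param x A `dq_overlap`.
#' @param ... Unused.
#' @return One-row tibble: denominator, union and intersection counts.
#' @importFrom generics glance
#' @method glance dq_overlap
#' @export
glance.dq_overlap <- function(x, ...) {
  tibble::tibble(
    denominator_n = attr(x, "denominator_n"),
    union_n = attr(x, "union_n"),
    intersection_n = attr(x, "intersection_n"),
    fraction_any = attr(x, "union_n") / attr(x, "denominator_n"),
    fraction_all = attr(x, "intersection_n") / attr(x, "denominator_n")
  )
}

#' Table-1-style characteristics of a patient subset
#'
#' Descriptive summary of demographics, health-care use and Charlson burden
#' for a subset of a cohort (by default everyone): mean/SD/median age,
#' counts and percentages per categorical block, mean/SD visit counts and
#' mean/SD/median Charlson index.
#'
#' @param cohort An [ehr_cohort()].
#' @param subset Character vector of patient ids (default: all patients).
#' @param map A [charlson_map()] used for the comorbidity block.
#' @return Tidy tibble `block`, `level`, `statistic`, `value`; an empty
#'   subset yields `NaN`/zero rows flagged by the `empty` attribute.
#' @export
characteristics <- function(cohort, subset = NULL, map = charlson_map()) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  subset <- subset %||% cohort$patients$patient_id
  bad <- setdiff(subset, cohort$patients$patient_id)
  if (length(bad) > 0) {
    stop("subset contains unknown patient id(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  p <- cohort$patients[cohort$patients$patient_id %in% subset, , drop = FALSE]
  n <- nrow(p)

  num_block <- function(block, x, median_too = TRUE) {
    rows <- tibble::tibble(
      block = block, level = NA_character_,
      statistic = c("mean", "sd", if (median_too) "median"),
      value = c(mean(x), stats::sd(x), if (median_too) stats::median(x))
    )
    rows
  }
  cat_block <- function(block, x, levels) {
    counts <- table(factor(x, levels = levels))
    tibble::tibble(
      block = block,
      level = rep(levels, 2),
      statistic = rep(c("n", "pct"), each = length(levels)),
      value = c(as.numeric(counts),
                if (n > 0) 100 * as.numeric(counts) / n
                else rep(NaN, length(levels)))
    )
  }

  if (n == 0) {
    out <- tibble::tibble(block = "n", level = NA_character_,
                          statistic = "n", value = 0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  age <- patient_age(p, cohort$study_window)
  cci <- cohort_charlson(cohort, map)
  cci <- cci$charlson_index[cci$patient_id %in% subset]

  out <- dplyr::bind_rows(
    tibble::tibble(block = "n", level = NA_character_, statistic = "n",
                   value = n),
    num_block("age", age),
    cat_block("sex", p$sex, SEX_LEVELS),
    cat_block("race", p$race, RACE_LEVELS),
    cat_block("ethnicity", p$ethnicity, ETHNICITY_LEVELS),
    cat_block("state", p$state, STATE_LEVELS),
    num_block("inpatient_visits", p$inpatient_visits, median_too = FALSE),
    num_block("ed_visits", p$ed_visits, median_too = FALSE),
    num_block("charlson_index", cci)
  )
  attr(out, "empty") <- FALSE
  out
}

#' Export report artifacts
#'
#' Writes tidy CSVs with deterministic names under `out_dir`: one retention
#' table per axis present in the grid, one file per overlap partition, and
#' optional strata/characteristics tables. Rerunning on the same inputs
#' yields byte-identical files.
#'
#' @param grid A `dq_grid` (or `NULL`).
#' @param partitions List of `dq_overlap` objects.
#' @param out_dir Output directory (created if absent).
#' @param strata Optional strata tibble (from [data_type_stratum()]).
#' @param characteristics_tables Optional named list of tibbles from
#'   [characteristics()], written as `characteristics_<name>.csv`.
#' @return Invisibly, the paths written.
#' @export
export_report <- function(grid = NULL, partitions = list(), out_dir,
                          strata = NULL, characteristics_tables = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (!is.null(grid) && nrow(grid) > 0) {
    for (ax in sort(unique(grid$axis))) {
      f <- file.path(out_dir, paste0("retention_", ax, ".csv"))
      readr::write_csv(dplyr::filter(grid, .data$axis == ax), f, na = "")
      paths <- c(paths, f)
    }
  }
  for (i in seq_along(partitions)) {
    f <- file.path(out_dir, sprintf("overlap_partition_%02d.csv", i))
    part <- partitions[[i]]
    meta <- glance.dq_overlap(part)
    readr::write_csv(
      dplyr::mutate(tibble::as_tibble(part),
                    denominator_n = meta$denominator_n,
                    union_n = meta$union_n),
      f, na = ""
    )
    paths <- c(paths, f)
  }
  if (!is.null(strata)) {
    f <- file.path(out_dir, "strata.csv")
    readr::write_csv(strata, f, na = "")
    paths <- c(paths, f)
  }
  for (nm in names(characteristics_tables)) {
    f <- file.path(out_dir, paste0("characteristics_", nm, ".csv"))
    readr::write_csv(characteristics_tables[[nm]], f, na = "")
    paths <- c(paths, f)
  }
  invisible(paths)
}
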