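# Seeded, nestable data-quality perturbation operators: incompleteness
# (random event deletion), inaccuracy (code replacement, laboratory value
# scaling, unit corruption) and timeliness (uniform forward date shifts),
# plus compounded combinations.
#
# Each event carries a stable integer identity (`event_id`); every stochastic
# operator derives its per-event uniform draw from (seed, stream, event_id),
# so the selected set at fraction f1 is a subset of the selected set at
# f2 >= f1 under the same seed ("nested increments"), without storing masks.

.STREAMS <- c(drop_DX = 0L, drop_RX = 1L, drop_LAB = 2L,
              sel_DX = 3L, sel_RX = 4L, sel_LAB = 5L,
              pick_DX = 6L, pick_RX = 7L, pick_LAB = 8L)

# uniform(0,1) draw per event identity, reproducible and independent across
# (seed, stream) pairs
.event_uniform <- function(seed, ids, stream) {
  if (length(ids) == 0) return(numeric())
  s <- (as.double(seed) * 97L + stream) %% 2147483647
  withr::with_seed(as.integer(s), stats::runif(max(ids)))[ids]
}

.ensure_event_ids <- function(events) {
  if (!"event_id" %in% names(events)) events$event_id <- seq_len(nrow(events))
  events
}

#' Randomly drop events (induced incompleteness)
#'
#' Removes targeted events whose per-event uniform draw falls below
#' `fraction`. For a fixed seed the removed sets are nested across fractions,
#' so identified cohorts shrink monotonically along the increment grid.
#'
#' @param events Clinical event table (gains an `event_id` if absent).
#' @param data_types Data types to target (subset of `DX`, `RX`, `LAB`).
#' @param fraction Drop fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return Event table with targeted events removed.
#' @export
drop_events <- function(events, data_types = DATA_TYPES, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  events <- .ensure_event_ids(events)
  if (fraction == 0 || nrow(events) == 0) return(events)
  keep <- rep(TRUE, nrow(events))
  for (dt in intersect(data_types, DATA_TYPES)) {
    i <- which(events$data_type == dt)
    u <- .event_uniform(seed, events$event_id[i], .STREAMS[[paste0("drop_", dt)]])
    keep[i[u < fraction]] <- FALSE
  }
  events[keep, , drop = FALSE]
}

#' Randomly replace codes (induced inaccuracy)
#'
#' Selected events (per-event uniform below `fraction`, nested across
#' fractions) receive a code drawn uniformly from the replacement pool of
#' their data type, excluding the event's current code — a replaced event
#' never keeps its code. Dates, values and types are untouched, so event
#' counts and per-data-type totals are conserved.
#'
#' @inheritParams drop_events
#' @param pool Named list (`DX`/`RX`/`LAB`) of replacement code vectors;
#'   default: all distinct codes of that data type observed in `events`
#'   (so diabetes and non-diabetes codes both occur). Each targeted pool
#'   needs at least 2 codes.
#' @return Event table with codes replaced.
#' @export
replace_codes <- function(events, data_types = c("DX", "RX"), fraction,
                          pool = NULL, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  events <- .ensure_event_ids(events)
  if (fraction == 0 || nrow(events) == 0) return(events)
  for (dt in intersect(data_types, DATA_TYPES)) {
    i <- which(events$data_type == dt)
    if (length(i) == 0) next
    pl <- pool[[dt]] %||% sort(unique(events$code[i]))
    if (length(pl) < 2) {
      stop("config error: replacement pool for ", dt,
           " needs at least 2 codes", call. = FALSE)
    }
    u <- .event_uniform(seed, events$event_id[i], .STREAMS[[paste0("sel_", dt)]])
    sel <- i[u < fraction]
    if (length(sel) == 0) next
    r <- .event_uniform(seed, events$event_id[sel], .STREAMS[[paste0("pick_", dt)]])
    cur <- match(events$code[sel], pl)           # NA if current code not pooled
    m <- ifelse(is.na(cur), length(pl), length(pl) - 1L)
    k <- pmin(floor(r * m) + 1L, m)              # index among candidates
    k <- ifelse(!is.na(cur) & k >= cur, k + 1L, k)  # skip the current code
    events$code[sel] <- pl[k]
  }
  events
}

#' Scale all laboratory values (induced inaccuracy)
#'
#' Every LAB value v becomes `v * (1 + delta)`; deterministic, no sampling,
#' units unchanged. The study grid runs from -100% to +10% in 2% increments.
#'
#' @param events Clinical event table.
#' @param delta Signed relative change in `[-1, 0.1]`.
#' @return Event table with scaled LAB values.
#' @export
scale_lab_values <- function(events, delta) {
  stopifnot(delta >= -1, delta <= 0.1)
  i <- events$data_type == "LAB"
  events$value[i] <- events$value[i] * (1 + delta)
  events
}

#' Default unit-corruption rules (US -> UK reporting standards)
#'
#' Glucose mg/dL is divided by 18.016 (molar mass of glucose) to mmol/L;
#' HbA1c percent (NGSP) maps to mmol/mol (IFCC) by the master equation
#' `10.93 * x - 23.50`.
#'
#' @return Tibble of rules: `loinc`, `from_unit`, `to_unit`, `scale`, `offset`.
#' @export
default_unit_rules <- function() {
  tibble::tibble(
    loinc = c("2345-7", "1558-6", "55454-3", "4548-4"),
    from_unit = c("mg/dL", "mg/dL", "%", "%"),
    to_unit = c("mmol/L", "mmol/L", "mmol/mol", "mmol/mol"),
    scale = c(1 / 18.016, 1 / 18.016, 10.93, 10.93),
    offset = c(0, 0, -23.50, -23.50)
  )
}

#' Corrupt laboratory units (induced inaccuracy)
#'
#' LAB events matching a rule's LOINC code and source unit get
#' `value * scale + offset` and the new unit label. Events matching no rule
#' are unchanged. Because value predicates require an exact unit match,
#' corrupted results stop satisfying percent- or mg/dL-denominated criteria.
#'
#' @param events Clinical event table.
#' @param rules Rule table as in [default_unit_rules()].
#' @return Event table with converted values and relabelled units.
#' @export
corrupt_units <- function(events, rules = default_unit_rules()) {
  if (any(rules$scale == 0)) {
    stop("config error: unit-conversion rule with zero scale", call. = FALSE)
  }
  for (k in seq_len(nrow(rules))) {
    i <- events$data_type == "LAB" &
      events$code == rules$loinc[k] &
      !is.na(events$unit) & events$unit == rules$from_unit[k]
    events$value[i] <- events$value[i] * rules$scale[k] + rules$offset[k]
    events$unit[i] <- rules$to_unit[k]
  }
  events
}

#' Shift event dates forward (induced lack of timeliness)
#'
#' Advances targeted events by exactly `days` calendar days (no resampling).
#' Combined with the fixed study window this pushes late events out of the
#' analysable period.
#'
#' @inheritParams drop_events
#' @param days Non-negative integer number of days.
#' @return Event table with shifted dates.
#' @export
shift_dates <- function(events, days, data_types = DATA_TYPES) {
  stopifnot(days >= 0)
  i <- events$data_type %in% data_types
  events$event_date[i] <- events$event_date[i] + as.integer(days)
  events
}

#' Describe a perturbation declaratively
#'
#' @param kind One of `"drop"`, `"replace_code"`, `"scale_lab_value"`,
#'   `"corrupt_units"`, `"shift_dates"`, `"compound"`.
#' @param data_types Targeted data types.
#' @param level Fraction (drop/replace), signed delta (scale), or days
#'   (shift); ignored for `corrupt_units`/`compound`.
#' @param seed Integer seed for the stochastic kinds.
#' @param children For `compound`: list of child `perturbation` objects,
#'   applied in order.
#' @param pool,rules Optional overrides passed to [replace_codes()] /
#'   [corrupt_units()].
#' @return A `perturbation` spec.
#' @export
perturbation <- function(kind = c("drop", "replace_code", "scale_lab_value",
                                  "corrupt_units", "shift_dates", "compound"),
                         data_types = DATA_TYPES, level = 0, seed = 1L,
                         children = list(), pool = NULL, rules = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("drop", "replace_code")) {
    stopifnot(level >= 0, level <= 1)
  }
  if (kind == "scale_lab_value") stopifnot(level >= -1, level <= 0.1)
  if (kind == "shift_dates") stopifnot(level >= 0, level == round(level))
  if (kind == "compound") {
    stopifnot(all(vapply(children, inherits, TRUE, "perturbation")))
  }
  structure(
    list(kind = kind, data_types = data_types, level = level,
         seed = as.integer(seed), children = children, pool = pool,
         rules = rules),
    class = "perturbation"
  )
}

#' Read a perturbation spec (possibly compound) from YAML
#' @param path YAML file with fields `kind`, `data_types`, `level`, `seed`,
#'   and `children` for compound specs.
#' @return A [perturbation()].
#' @export
read_perturbation <- function(path) {
  parse1 <- function(x) {
    perturbation(
      kind = x$kind,
      data_types = x$data_types %||% DATA_TYPES,
      level = x$level %||% 0,
      seed = x$seed %||% 1L,
      children = purrr::map(x$children %||% list(), parse1)
    )
  }
  parse1(yaml::read_yaml(path))
}

#' Apply a perturbation to a cohort
#'
#' Pure function of `(cohort, spec)`: dispatches to the operator named by the
#' spec; `compound` applies its children in listed order. The patients table
#' is never modified.
#'
#' @param cohort An [ehr_cohort()].
#' @param spec A [perturbation()].
#' @return A perturbed [ehr_cohort()].
#' @export
apply_perturbation <- function(cohort, spec) {
  stopifnot(inherits(cohort, "ehr_cohort"), inherits(spec, "perturbation"))
  ev <- cohort$events
  ev <- switch(
    spec$kind,
    drop = drop_events(ev, spec$data_types, spec$level, spec$seed),
    replace_code = replace_codes(ev, spec$data_types, spec$level,
                                 pool = spec$pool, seed = spec$seed),
    scale_lab_value = scale_lab_values(ev, spec$level),
    corrupt_units = corrupt_units(ev, rules = spec$rules %||% default_unit_rules()),
    shift_dates = shift_dates(ev, spec$level, spec$data_types),
    compound = {
      out <- cohort
      for (child in spec$children) out <- apply_perturbation(out, child)
      out$events
    }
  )
  cohort$events <- ev
  cohort
}

#' Grids of perturbation levels used by the study design
#'
#' `drop_grid()`: 10% increments from 0 to 100%. `lab_scale_grid()`: 2%
#' increments from -100% to +10% (56 points). `shift_grid()`: 30-day
#' increments from 30 to 360 days, plus 365.
#'
#' @return Numeric vector of levels.
#' @export
drop_grid <- function() round(seq(0, 1, by = 0.1), 2)

#' @rdname drop_grid
#' @export
lab_scale_grid <- function() round(seq(-1, 0.1, by = 0.02), 2)

#' @rdname drop_grid
#' @export
shift_grid <- function() c(seq(30L, 360L, by = 30L), 365L)
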