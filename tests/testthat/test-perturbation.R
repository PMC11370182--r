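defs <- shipped_definitions()

test_that("every operator at level 0 leaves phenotype output unchanged", {
  co <- test_cohort(n = 1500, seed = 19)
  specs <- list(
    perturbation("drop", level = 0, seed = 3),
    perturbation("replace_code", c("DX", "RX"), level = 0, seed = 3),
    perturbation("scale_lab_value", level = 0),
    perturbation("shift_dates", level = 0),
    perturbation("compound")
  )
  base <- evaluate_phenotype(co, defs$JHU)
  for (spec in specs) {
    out <- apply_perturbation(co, spec)
    res <- evaluate_phenotype(out, defs$JHU)
    expect_setequal(res$identified, base$identified)
    expect_equal(nrow(out$events), nrow(co$events))
  }
})

test_that("dropping removes the right events at the right rate", {
  ev <- dplyr::bind_rows(
    dx_event(rep("P1", 10000), "E11.9", "2018-01-01"),
    rx_event(rep("P1", 50), "6809", "2018-01-01")
  )
  ev$event_id <- seq_len(nrow(ev))

  # fraction 1 on DX: no DX left, RX untouched
  out <- drop_events(ev, "DX", 1, seed = 1)
  expect_equal(sum(out$data_type == "DX"), 0)
  expect_equal(sum(out$data_type == "RX"), 50)

  # binomial oracle at fraction 0.5
  out <- drop_events(ev, "DX", 0.5, seed = 9)
  removed <- 10000 - sum(out$data_type == "DX")
  expect_lt(abs(removed - 5000), 3 * sqrt(10000 * 0.25))

  # nesting: the removed set grows monotonically along the grid
  prev_kept <- NULL
  for (f in drop_grid()) {
    kept <- drop_events(ev, "DX", f, seed = 5)$event_id
    if (!is.null(prev_kept)) expect_true(all(kept %in% prev_kept))
    prev_kept <- kept
  }
})

test_that("code replacement conserves structure and never keeps the code", {
  ev <- dx_event(rep("P1", 500), "E08", "2018-01-01")
  ev$event_id <- seq_len(nrow(ev))
  out <- replace_codes(ev, "DX", 1, pool = list(DX = c("E08", "E09")), seed = 2)
  expect_true(all(out$code == "E09"))
  expect_equal(nrow(out), nrow(ev))
  expect_equal(out$event_date, ev$event_date)

  co <- test_cohort(n = 1500, seed = 19)
  out <- replace_codes(co$events, c("DX", "RX"), 0.4, seed = 6)
  expect_equal(table(out$data_type), table(co$events$data_type))
  changed <- out$code != co$events$code
  pool_dx <- sort(unique(co$events$code[co$events$data_type == "DX"]))
  expect_true(all(out$code[changed & out$data_type == "DX"] %in% pool_dx))
  # a selected event never keeps its original code: at fraction 1 every
  # targeted event's code differs
  all_changed <- replace_codes(co$events, "DX", 1, seed = 6)
  i <- co$events$data_type == "DX"
  expect_true(all(all_changed$code[i] != co$events$code[i]))
  expect_error(replace_codes(ev, "DX", 0.5, pool = list(DX = "E08"), seed = 1),
               "config error")
})

test_that("lab scaling is exact arithmetic and kills positive thresholds at -1", {
  ev <- lab_event("P1", "55454-3", "2018-06-01", 7.0)
  expect_equal(scale_lab_values(ev, 0.10)$value, 7.7)
  expect_equal(scale_lab_values(ev, 0)$value, 7.0)
  co <- test_cohort(n = 1500, seed = 19)
  dead <- apply_perturbation(co, perturbation("scale_lab_value", level = -1))
  expect_true(all(dead$events$value[dead$events$data_type == "LAB"] == 0))
  res <- evaluate_phenotype(dead, defs$JHU)
  expect_equal(sum(res$evidence_profile$profile == "LAB"), 0)
})

test_that("unit corruption applies the US->UK conversions", {
  glu <- lab_event("P1", "2345-7", "2018-06-01", 180, "mg/dL")
  out <- corrupt_units(glu)
  expect_equal(out$unit, "mmol/L")
  expect_lt(abs(out$value - 9.99), 0.005)
  a1c <- lab_event("P1", "55454-3", "2018-06-01", 6.5, "%")
  out <- corrupt_units(a1c)
  expect_equal(out$unit, "mmol/mol")
  expect_lt(abs(out$value - 47.5), 0.05)
  odd <- lab_event("P1", "2160-0", "2018-06-01", 1.0, "mg/dL")
  expect_equal(corrupt_units(odd), odd)
  expect_error(corrupt_units(glu, rules = tibble::tibble(
    loinc = "2345-7", from_unit = "mg/dL", to_unit = "x",
    scale = 0, offset = 0)), "zero scale")
})

test_that("date shifts are exact forward moves interacting with the window", {
  ev <- dx_event("P1", "E11.9", "2019-12-01")
  expect_equal(shift_dates(ev, 30)$event_date, as.Date("2019-12-31"))
  expect_equal(shift_dates(ev, 0), ev)
  late <- dx_event("P1", "E11.9", "2019-12-15")
  shifted <- shift_dates(late, 30)
  expect_equal(nrow(filter_window(shifted, default_study_window())), 0)
})

test_that("compound application composes, commutes on disjoint fields, and is pure", {
  co <- test_cohort(n = 1500, seed = 19)
  wipe <- perturbation("compound", children = list(
    perturbation("drop", "DX", 1, seed = 1),
    perturbation("drop", "RX", 1, seed = 1),
    perturbation("drop", "LAB", 1, seed = 1)
  ))
  gone <- apply_perturbation(co, wipe)
  expect_equal(nrow(gone$events), 0)
  for (nm in names(defs)) {
    expect_equal(evaluate_phenotype(gone, defs[[nm]])$n_identified, 0, info = nm)
  }
  expect_identical(apply_perturbation(co, perturbation("compound")), co)

  a <- apply_perturbation(co, perturbation("compound", children = list(
    perturbation("drop", "DX", 0.3, seed = 4),
    perturbation("shift_dates", level = 30)
  )))
  b <- apply_perturbation(co, perturbation("compound", children = list(
    perturbation("shift_dates", level = 30),
    perturbation("drop", "DX", 0.3, seed = 4)
  )))
  expect_equal(a$events, b$events)

  # purity: identical spec, identical output
  s <- perturbation("drop", level = 0.5, seed = 12)
  expect_identical(apply_perturbation(co, s), apply_perturbation(co, s))
})

test_that("perturbation specs round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "kind: compound",
    "children:",
    "  - {kind: drop, data_types: [DX], level: 0.3, seed: 4}",
    "  - {kind: shift_dates, level: 30}"
  ), f)
  spec <- read_perturbation(f)
  expect_equal(spec$kind, "compound")
  expect_length(spec$children, 2)
  expect_equal(spec$children[[1]]$level, 0.3)
  expect_equal(spec$children[[2]]$kind, "shift_dates")
})
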