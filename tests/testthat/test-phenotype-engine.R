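defs <- shipped_definitions()
sets <- default_code_sets()

test_that("shipped definitions compile with their structural invariants", {
  ccw <- defs$CCW
  expect_true(all(vapply(ccw$pathways, function(p)
    identical(p$data_types, "DX"), TRUE)))
  expect_equal(ccw$reference_period_days, 730L)

  jhu <- defs$JHU
  expect_length(jhu$pathways, 3)
  expect_true(all(vapply(jhu$pathways, function(p) length(p$criteria), 1L) == 1L))
  expect_setequal(vapply(jhu$pathways, function(p) p$data_types, ""),
                  c("DX", "RX", "LAB"))

  key <- function(d) vapply(d$pathways, function(p)
    paste(p$data_types, collapse = "+"), "")
  expect_false(any(key(defs$EMERGE) %in% c("DX", "RX", "LAB+RX")))
  expect_false(any(key(defs$SUPREME_DM) == "RX"))
})

test_that("structurally invalid configs are rejected at compile time", {
  rx_only <- list(name = "pw", criteria = list(
    list(data_type = "RX", code_set = "t2d_rx", min_count = 1)))
  dx_only <- list(name = "pw", criteria = list(
    list(data_type = "DX", code_set = "t2d_dx", min_count = 1)))
  expect_error(
    compile_definition(list(name = "CCW", reference_period_days = 730,
                            pathways = list(rx_only))),
    "structural violation.*CCW")
  expect_error(
    compile_definition(list(name = "EMERGE", pathways = list(rx_only))),
    "structural violation.*eMERGE")
  expect_error(
    compile_definition(list(name = "SUPREME_DM", pathways = list(rx_only))),
    "structural violation.*SUPREME")
  expect_error(
    compile_definition(list(name = "JHU", pathways = list(dx_only))),
    "structural violation.*JHU")
  expect_error(
    compile_definition(list(name = "DDC", pathways = list(
      list(name = "pw", criteria = list(
        list(data_type = "DX", code_set = "nope", min_count = 1)))))),
    "resolution error.*nope")
})

test_that("criterion evaluation handles counts, days, settings and values", {
  w <- default_study_window()
  two_days <- criterion("DX", sets$t2d_dx, min_count = 2, distinct_days = TRUE)
  ev <- dplyr::bind_rows(dx_event("P1", "E11.9", "2018-03-01"),
                         dx_event("P1", "E11.9", "2018-03-15"))
  expect_true(evaluate_criterion(ev, two_days, w))
  same_day <- dplyr::bind_rows(dx_event("P1", "E11.9", "2018-03-01"),
                               dx_event("P1", "E11.9", "2018-03-01"))
  expect_false(evaluate_criterion(same_day, two_days, w))
  expect_false(evaluate_criterion(ev[0, ], two_days, w))

  a1c <- criterion("LAB", sets$hba1c, min_count = 1,
                   predicate = list(op = ">=", threshold = 6.5, unit = "%"))
  expect_true(evaluate_criterion(lab_event("P1", "55454-3", "2018-06-01", 6.6),
                                 a1c, w))
  expect_false(evaluate_criterion(lab_event("P1", "55454-3", "2018-06-01", 6.4),
                                  a1c, w))
  # unit mismatch never satisfies the predicate, even if numerically larger
  expect_false(evaluate_criterion(
    lab_event("P1", "55454-3", "2018-06-01", 48, "mmol/mol"), a1c, w))

  inpt <- criterion("DX", sets$t2d_dx, min_count = 1, setting = "inpatient")
  expect_false(evaluate_criterion(ev, inpt, w))
  expect_true(evaluate_criterion(
    dx_event("P1", "E11.9", "2018-03-01", "inpatient"), inpt, w))

  # span rule against the exhaustive day-pair oracle
  span <- criterion("DX", sets$t2d_dx, min_count = 2, distinct_days = TRUE,
                    window_days = 30)
  for (gap in c(10, 30, 31, 300)) {
    ev2 <- dplyr::bind_rows(
      dx_event("P1", "E11.9", "2018-03-01"),
      dx_event("P1", "E11.9", as.Date("2018-03-01") + gap)
    )
    expect_equal(evaluate_criterion(ev2, span, w),
                 oracle_criterion(ev2, span, w), info = paste("gap", gap))
  }
})

test_that("phenotype evaluation respects pathway structure", {
  patients <- make_patients(c("P1", "P2"))
  rx_only <- ehr_cohort(patients, rx_event("P1", "6809", "2018-06-01"))
  expect_equal(evaluate_phenotype(rx_only, defs$CCW)$n_identified, 0)
  res <- evaluate_phenotype(rx_only, defs$JHU)
  expect_equal(res$identified, "P1")
  expect_equal(res$evidence_profile$profile, "RX")

  empty <- ehr_cohort(make_patients(character(0))[0, ])
  expect_equal(evaluate_phenotype(empty, defs$JHU)$n_identified, 0)

  # CCW reference period: trailing 730 days of the window
  early <- ehr_cohort(patients, dplyr::bind_rows(
    dx_event("P1", "E11.9", "2017-02-01"),
    dx_event("P1", "E11.9", "2017-03-01")
  ))
  expect_equal(evaluate_phenotype(early, defs$CCW)$n_identified, 0)
  expect_equal(evaluate_phenotype(early, defs$DDC)$n_identified, 1)
})

test_that("strata partition identified patients and respect structural zeros", {
  co <- test_cohort(n = 2000, seed = 7)
  for (nm in names(defs)) {
    res <- evaluate_phenotype(co, defs[[nm]])
    strata <- data_type_stratum(res)
    expect_equal(sum(strata$n), res$n_identified, info = nm)
  }
  em <- data_type_stratum(evaluate_phenotype(co, defs$EMERGE))
  expect_equal(em$n[em$stratum %in% c("DX", "RX", "RX+LAB")], c(0L, 0L, 0L))
  ccw <- data_type_stratum(evaluate_phenotype(co, defs$CCW))
  expect_true(all(ccw$n[ccw$stratum != "DX"] == 0))
})

test_that("evaluator agrees with the brute-force oracle on small cohorts", {
  for (seed in c(101, 102, 103, 104)) {
    co <- random_small_cohort(seed)
    for (nm in names(defs)) {
      want <- oracle_evaluate_phenotype(co, defs[[nm]])
      got <- evaluate_phenotype(co, defs[[nm]])
      expect_setequal(got$identified, names(want))
      prof <- got$evidence_profile
      expect_equal(prof$profile[order(prof$patient_id)],
                   as.character(unlist(want)[sort(names(want))]),
                   ignore_attr = TRUE,
                   info = paste(nm, "seed", seed))
    }
  }
})

test_that("adding events never removes a patient from an identified set", {
  co <- random_small_cohort(201)
  extra <- dplyr::bind_rows(
    dx_event(co$patients$patient_id, "E11.9", "2019-06-01"),
    lab_event(co$patients$patient_id, "55454-3", "2019-07-01", 7.1)
  )
  bigger <- ehr_cohort(co$patients, dplyr::bind_rows(
    co$events[, names(extra)], extra))
  for (nm in names(defs)) {
    before <- evaluate_phenotype(co, defs[[nm]])$identified
    after <- evaluate_phenotype(bigger, defs[[nm]])$identified
    expect_true(all(before %in% after), info = nm)
  }
})

test_that("JHU is a superset of every single-data-type stratum elsewhere", {
  co <- test_cohort(n = 2000, seed = 7)
  jhu_ids <- evaluate_phenotype(co, defs$JHU)$identified
  for (nm in setdiff(names(defs), "JHU")) {
    prof <- evaluate_phenotype(co, defs[[nm]])$evidence_profile
    single <- prof$patient_id[prof$profile %in% c("DX", "RX", "LAB")]
    expect_true(all(single %in% jhu_ids), info = nm)
  }
})

test_that("tidy and glance summarise identification results", {
  co <- random_small_cohort(301)
  res <- evaluate_phenotype(co, defs$JHU)
  td <- tidy(res)
  expect_equal(nrow(td), res$n_identified)
  expect_named(td, c("phenotype", "patient_id", "profile"))
  gl <- glance(res)
  expect_equal(gl$fraction_identified, res$n_identified / nrow(co$patients))
})
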