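# Dashboard indicator sets: hand computations, ground-truth consistency,
# filter additivity.

test_that("population indicators match the generator's truth", {
  p <- small_pipeline()
  tr <- p$truth$operations
  pop <- population_summary(p$store)
  ind <- setNames(pop$indicators$value, pop$indicators$indicator)
  expect_equal(ind[["n_operations"]], nrow(tr))
  expect_equal(ind[["n_patients"]], length(unique(tr$patient_id)))
  expect_equal(ind[["n_urgent"]], sum(tr$urgent))
  expect_equal(ind[["pct_urgent"]],
               round(100 * sum(tr$urgent) / nrow(tr), 1))
  # bin counts (including unknown) sum to the number of operations
  expect_equal(sum(pop$age_hist$n), nrow(tr))
  expect_equal(sum(pop$bmi_hist$n), nrow(tr))
  expect_equal(sum(pop$weight_hist$n), nrow(tr))
  expect_equal(sum(pop$asa_bar$n), nrow(tr))
  expect_equal(pop$asa_bar$n,
               as.integer(table(tr$asa)[as.character(pop$asa_bar$asa)]))
})

test_that("year filters partition the population additively", {
  p <- small_pipeline()
  pop_all <- population_summary(p$store)
  years <- pop_all$per_year$year
  n_by_year <- vapply(years, function(y) {
    s <- population_summary(p$store, dashboard_filter(years = y))
    s$indicators$value[s$indicators$indicator == "n_operations"]
  }, numeric(1))
  expect_equal(sum(n_by_year),
               pop_all$indicators$value[
                 pop_all$indicators$indicator == "n_operations"])
  # department filter restricts to that department's rooms
  d <- "Cardiac surgery"
  s <- population_summary(p$store, dashboard_filter(departments = d))
  expect_equal(s$indicators$value[s$indicators$indicator == "n_operations"],
               sum(p$truth$operations$department == d))
})

test_that("hemodynamic counts equal the ground-truth hypotension burden", {
  p <- small_pipeline()
  tr <- p$truth$operations
  h <- hemodynamics_summary(p$store)
  expect_equal(h$indicators$n_operations[h$indicators$rule == "MAP<65 mmHg"],
               sum(tr$n_episodes > 0))
  expect_true(all(h$indicators$n_operations <= nrow(tr)))
  # duration bars: one bar set per breaching rule, counts match breachers
  map_bars <- h$duration_bars[h$duration_bars$variable == "MAP<65 mmHg", ]
  expect_equal(sum(map_bars$n), sum(tr$n_episodes > 0))
})

test_that("a store without features warns and reports zero breaches", {
  ms <- micro_store()
  expect_warning(h <- hemodynamics_summary(ms$store),
                 class = "periomop_no_features")
  expect_true(all(h$indicators$n_operations == 0))
})

test_that("tidal volume normalization reproduces the hand-computed ml/kg", {
  # male, 172.4 cm -> IBW 68.2 kg; Vt 500 ml -> 7.33, not counted at >8;
  # Vt 600 ml -> 8.80, counted at >8 but not >10
  fx_store <- function(vt_ml) {
    reg <- load_registry()
    store <- cdm_create()
    store$CONCEPT <- reg$concepts
    store$PERSON <- tibble::tibble(person_id = 1, gender_concept_id = 8507,
                                   year_of_birth = 1970, source = "PMSI")
    store$VISIT_DETAIL <- tibble::tibble(
      visit_detail_id = 501, person_id = 1, visit_occurrence_id = 1,
      visit_detail_concept_id = periomop:::concept_id_of(reg, "VIS_OR"),
      visit_detail_start_datetime = dt("2019-01-01 08:00:00"),
      visit_detail_end_datetime = dt("2019-01-01 12:00:00"),
      care_site_id = NA_real_, source = "AIMS")
    store$OBSERVATION <- tibble::tibble(
      observation_id = 1, person_id = 1,
      observation_concept_id = periomop:::concept_id_of(reg, "DEMO_HEIGHT"),
      observation_datetime = dt("2019-01-01 08:00:00"),
      value_as_number = 172.4, value_as_string = NA_character_,
      unit_concept_id = periomop:::concept_id_of(reg, "UNIT_CM"),
      visit_occurrence_id = 1, visit_detail_id = 501,
      observation_source_value = "DEMO_HEIGHT", source = "AIMS")
    store$PERIOD <- tibble::tibble(
      period_id = 1, person_id = 1, visit_detail_id = 501,
      period_concept_id = periomop:::concept_id_of(reg, "PER_ANESTHESIA"),
      start_event_concept_id = NA_real_, end_event_concept_id = NA_real_,
      start_datetime = dt("2019-01-01 08:00:00"),
      end_datetime = dt("2019-01-01 12:00:00"))
    store$FEATURE <- tibble::tibble(
      feature_id = 1, person_id = 1, visit_detail_id = 501, period_id = 1,
      signal_concept_id = periomop:::concept_id_of(reg, "MEAS_TVEXP"),
      aggregation_concept_id = periomop:::concept_id_of(reg, "FEAT_MEDIAN"),
      value_as_number = vt_ml,
      unit_concept_id = periomop:::concept_id_of(reg, "UNIT_ML"))
    store
  }
  v500 <- ventilation_summary(fx_store(500))
  expect_equal(round(v500$per_operation$vt_ml_kg, 2), 7.33)
  expect_equal(v500$indicators$value[v500$indicators$indicator == "n_vt_gt8"], 0)

  v600 <- ventilation_summary(fx_store(600))
  expect_equal(round(v600$per_operation$vt_ml_kg, 2), 8.8)
  expect_equal(v600$indicators$value[v600$indicators$indicator == "n_vt_gt8"], 1)
  expect_equal(v600$indicators$value[v600$indicators$indicator == "n_vt_gt10"], 0)
})

test_that("ventilation ml/kg agrees with the generator's tidal volumes", {
  p <- small_pipeline()
  v <- ventilation_summary(p$store)
  expect_equal(nrow(v$per_operation), nrow(p$truth$operations))
  expect_true(all(v$per_operation$vt_ml_kg > 0))
  expect_equal(
    v$indicators$value[v$indicators$indicator == "n_vt_gt8"],
    sum(v$per_operation$vt_ml_kg > 8))
})

test_that("outcome indicators agree with q7 and the discharge dispositions", {
  p <- small_pipeline()
  tr <- p$truth$operations
  o <- outcome_summary(p$store)
  ind <- setNames(o$indicators$value, o$indicators$indicator)
  expect_equal(ind[["n_icu"]], length(q7_icu_after_surgery(p$store)))
  expect_equal(ind[["n_death"]], sum(tr$death))
  expect_equal(ind[["pct_death"]],
               round(100 * sum(tr$death) / nrow(tr), 1))
  expect_equal(sum(o$per_year$n_operations), nrow(tr))
})

test_that("one death among four operations gives 25%", {
  b <- micro_bundle()
  b$patients <- tibble::tibble(patient_id = 1:4, sex = "F",
                               year_of_birth = 1980, height_cm = 165,
                               weight_kg = 60)
  b$stays <- tibble::tibble(
    stay_id = 1:4, patient_id = 1:4,
    admit_datetime = dt("2019-05-01 08:00:00"),
    discharge_datetime = dt("2019-05-05 11:00:00"),
    stay_type = "inpatient",
    discharge_disposition = c("death", "home", "home", "home"))
  b$unit_moves <- tibble::tibble(
    stay_id = 1:4, unit_code = "VIS_WARD",
    move_start = b$stays$admit_datetime,
    move_end = b$stays$discharge_datetime)
  b$operations <- tibble::tibble(
    op_id = 1:4, stay_id = 1:4, patient_id = 1:4, room_id = 1, urgent = 0,
    asa = 2, op_start = b$stays$admit_datetime + 3600,
    op_end = b$stays$admit_datetime + 7200)
  b$steps <- b$steps[0, ]; b$drugs <- b$drugs[0, ]; b$notes <- b$notes[0, ]
  ms <- micro_store(b)
  o <- outcome_summary(ms$store)
  expect_equal(o$indicators$value[o$indicators$indicator == "pct_death"], 25)
  expect_equal(o$indicators$value[o$indicators$indicator == "n_death"], 1)
})
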