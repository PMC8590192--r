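# The eight audit queries: hand fixtures for the windowed logic,
# ground-truth membership on the generated pipeline, invariants.

test_that("q1 counts operations per year and department (hand fixture)", {
  b <- micro_bundle()
  b$rooms <- tibble::tibble(room_id = 1:2, room_name = c("OR-1", "OR-2"),
                            department = c("A", "B"))
  b$patients <- tibble::tibble(patient_id = 1:3, sex = "F",
                               year_of_birth = 1980, height_cm = 165,
                               weight_kg = 60)
  b$stays <- tibble::tibble(
    stay_id = 1:3, patient_id = 1:3,
    admit_datetime = dt(c("2019-05-01 08:00:00", "2019-06-01 08:00:00",
                          "2020-02-01 08:00:00")),
    discharge_datetime = dt(c("2019-05-03 11:00:00", "2019-06-03 11:00:00",
                              "2020-02-03 11:00:00")),
    stay_type = "inpatient", discharge_disposition = "home")
  b$unit_moves <- tibble::tibble(
    stay_id = 1:3, unit_code = "VIS_WARD",
    move_start = b$stays$admit_datetime,
    move_end = b$stays$discharge_datetime)
  b$operations <- tibble::tibble(
    op_id = 1:3, stay_id = 1:3, patient_id = 1:3, room_id = c(1, 1, 2),
    urgent = 0, asa = 1,
    op_start = b$stays$admit_datetime + 3600,
    op_end = b$stays$admit_datetime + 7200)
  b$steps <- b$steps[0, ]; b$drugs <- b$drugs[0, ]; b$notes <- b$notes[0, ]
  ms <- micro_store(b)
  q1 <- q1_operations_by_year_department(ms$store)
  expect_equal(q1$n_operations[q1$year == 2019 & q1$department == "A"], 2)
  expect_equal(q1$n_operations[q1$year == 2020 & q1$department == "B"], 1)
  expect_equal(sum(q1$n_operations), 3)
})

test_that("q1 on an empty store is empty and conserves on the pipeline", {
  expect_equal(nrow(q1_operations_by_year_department(cdm_create())), 0)
  p <- small_pipeline()
  q1 <- q1_operations_by_year_department(p$store)
  expect_equal(sum(q1$n_operations), nrow(p$truth$operations))
})

test_that("q2/q3/q7 recover the generator's membership sets exactly", {
  p <- small_pipeline()
  tr <- p$truth$operations
  expect_identical(q2_outpatient_anesthesia(p$store),
                   truth_vd(p$truth, tr$outpatient))
  expect_identical(q3_fast_track(p$store), truth_vd(p$truth, tr$fast_track))
  expect_identical(q7_icu_after_surgery(p$store),
                   truth_vd(p$truth, tr$icu_after))
  # q3 partition: fast-track plus PACU operations cover all operations
  pacu_ops <- truth_vd(p$truth, !tr$fast_track)
  expect_setequal(c(q3_fast_track(p$store), pacu_ops),
                  op_visit_detail_id(tr$op_id))
})

# builds a store with one OR visit, an anesthesia period starting at 09:00
# and a hypotension period at the given offset (minutes)
q4_fixture <- function(offset_min) {
  reg <- load_registry()
  store <- cdm_create()
  store$CONCEPT <- reg$concepts
  store$PERSON <- tibble::tibble(person_id = 1, gender_concept_id = 8507,
                                 year_of_birth = 1970, source = "PMSI")
  store$VISIT_OCCURRENCE <- tibble::tibble(
    visit_occurrence_id = 1, person_id = 1,
    visit_concept_id = periomop:::concept_id_of(reg, "VIS_INPATIENT"),
    visit_start_datetime = dt("2019-01-01 06:00:00"),
    visit_end_datetime = dt("2019-01-03 12:00:00"),
    discharge_to_concept_id = NA_real_, source = "PMSI")
  store$VISIT_DETAIL <- tibble::tibble(
    visit_detail_id = 501, person_id = 1, visit_occurrence_id = 1,
    visit_detail_concept_id = periomop:::concept_id_of(reg, "VIS_OR"),
    visit_detail_start_datetime = dt("2019-01-01 08:50:00"),
    visit_detail_end_datetime = dt("2019-01-01 12:00:00"),
    care_site_id = NA_real_, source = "AIMS")
  t0 <- dt("2019-01-01 09:00:00")
  store$PERIOD <- tibble::tibble(
    period_id = 1:2, person_id = 1, visit_detail_id = 501,
    period_concept_id = c(periomop:::concept_id_of(reg, "PER_ANESTHESIA"),
                          periomop:::concept_id_of(reg, "PER_HYPOTENSION")),
    start_event_concept_id = NA_real_, end_event_concept_id = NA_real_,
    start_datetime = c(t0, t0 + offset_min * 60),
    end_datetime = c(t0 + 7200, t0 + offset_min * 60 + 300))
  list(store = store, registry = reg, t0 = t0)
}

test_that("q4 includes hypotension within 30 minutes of induction only", {
  expect_equal(q4_early_hypotension(q4_fixture(10)$store), 501)
  expect_equal(length(q4_early_hypotension(q4_fixture(45)$store)), 0)
  # boundary: exactly 30 minutes is outside the half-open window
  expect_equal(length(q4_early_hypotension(q4_fixture(30)$store)), 0)
  fx <- q4_fixture(10)
  fx$store$PERIOD <- fx$store$PERIOD[1, ]  # anesthesia only
  expect_equal(length(q4_early_hypotension(fx$store)), 0)
})

test_that("q5 counts rescue administrations inside the 15-minute window", {
  fx <- q4_fixture(10)  # first hypotension starts at 09:10
  reg <- fx$registry
  drug_id <- function(code) periomop:::concept_id_of(reg, code)
  p1 <- dt("2019-01-01 09:10:00")
  fx$store$DRUG_EXPOSURE <- tibble::tibble(
    drug_exposure_id = 1:4, person_id = 1,
    drug_concept_id = c(drug_id("DRUG_EPHEDRINE"), drug_id("DRUG_EPHEDRINE"),
                        drug_id("DRUG_NOREPINEPHRINE"),
                        drug_id("DRUG_PROPOFOL")),
    drug_exposure_start_datetime = c(p1 + 300, p1 + 600, p1 + 1200, p1 + 300),
    quantity = 1, visit_occurrence_id = 1, visit_detail_id = 501,
    drug_source_value = "x", source = "AIMS")
  q5 <- q5_rescue_drugs(fx$store)
  expect_equal(q5$n_administrations[q5$ingredient == "ephedrine"], 2)
  # norepinephrine at +20 min and propofol (not a rescue drug) don't count
  expect_false("norepinephrine" %in% q5$ingredient)
  expect_equal(sum(q5$n_administrations), 2)
})

test_that("q5 matches the generator's rescue bookkeeping", {
  p <- small_pipeline()
  expected <- p$truth$rescue |>
    dplyr::filter(within_15) |>
    dplyr::count(ingredient_code, name = "n_administrations") |>
    dplyr::mutate(ingredient = tolower(sub("^DRUG_", "", ingredient_code))) |>
    dplyr::select(ingredient, n_administrations) |>
    dplyr::arrange(ingredient)
  got <- q5_rescue_drugs(p$store)
  expect_equal(as.data.frame(got), as.data.frame(expected))
})

test_that("q6 aggregates length of stay by ASA status", {
  ms <- micro_store()  # one stay of ~4 days, ASA 2
  q6 <- q6_los_by_asa(ms$store)
  expect_equal(nrow(q6), 1)
  expect_equal(q6$asa, 2)
  expect_equal(q6$n_stays, 1)
  expect_equal(q6$median_days,
               as.numeric(difftime(dt("2019-03-05 11:00:00"),
                                   dt("2019-03-01 10:00:00"),
                                   units = "days")))
  expect_equal(nrow(q6_los_by_asa(cdm_create())), 0)

  p <- small_pipeline()
  q6p <- q6_los_by_asa(p$store)
  expect_equal(sum(q6p$n_stays), nrow(p$truth$operations))
})

test_that("q8 tallies parsed Mallampati grades with unknown fallback", {
  store <- cdm_create()
  store$NOTE <- tibble::tibble(
    note_id = 1:4, person_id = 1, note_datetime = dt("2019-01-01 08:00:00"),
    note_title = "Preanesthesia consultation",
    note_text = c("Mallampati: I\n", "mallampati: i",
                  "Mallampati: III\n", "Mallampati: not assessed"),
    visit_occurrence_id = 1, visit_detail_id = 1, source = "AIMS")
  q8 <- q8_mallampati(store)
  expect_equal(q8$n[q8$grade == "I"], 2)
  expect_equal(q8$n[q8$grade == "III"], 1)
  expect_equal(q8$n[q8$grade == "unknown"], 1)
  expect_equal(nrow(q8_mallampati(cdm_create())), 0)

  # arabic numerals map onto roman grades
  store$NOTE$note_text <- c("Mallampati: 2", "Mallampati: 4",
                            "Mallampati: II", "Mallampati: IV")
  q8b <- q8_mallampati(store)
  expect_equal(q8b$n[q8b$grade == "II"], 2)
  expect_equal(q8b$n[q8b$grade == "IV"], 2)
})

test_that("q8 matches the generator's Mallampati distribution", {
  p <- small_pipeline()
  expected <- p$truth$operations |>
    dplyr::count(grade = mallampati) |>
    dplyr::arrange(factor(grade, levels = c("I", "II", "III", "IV",
                                            "unknown")))
  got <- q8_mallampati(p$store)
  expect_equal(as.data.frame(got), as.data.frame(expected))
})

test_that("queries leave the store unchanged", {
  p <- small_pipeline()
  before <- lapply(cdm_table_names(), function(tb) p$store[[tb]])
  invisible(q1_operations_by_year_department(p$store))
  invisible(q2_outpatient_anesthesia(p$store))
  invisible(q3_fast_track(p$store))
  invisible(q4_early_hypotension(p$store))
  invisible(q5_rescue_drugs(p$store))
  invisible(q6_los_by_asa(p$store))
  invisible(q7_icu_after_surgery(p$store))
  invisible(q8_mallampati(p$store))
  after <- lapply(cdm_table_names(), function(tb) p$store[[tb]])
  expect_identical(before, after)
})
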