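# Hand-built fixtures and a cached small pipeline shared across test files.

dt <- function(x) as.POSIXct(x, tz = "UTC")

# one stay, one operation, three drug administrations (hand-countable)
micro_bundle <- function() {
  b <- periomop:::empty_bundle()
  b$patients <- tibble::tibble(patient_id = 1, sex = "M",
                               year_of_birth = 1970, height_cm = 172.4,
                               weight_kg = 80)
  b$rooms <- tibble::tibble(room_id = 1, room_name = "OR-1",
                            department = "Cardiac surgery")
  b$stays <- tibble::tibble(stay_id = 1, patient_id = 1,
                            admit_datetime = dt("2019-03-01 10:00:00"),
                            discharge_datetime = dt("2019-03-05 11:00:00"),
                            stay_type = "inpatient",
                            discharge_disposition = "home")
  b$unit_moves <- tibble::tibble(stay_id = 1, unit_code = "VIS_WARD",
                                 move_start = dt("2019-03-01 10:00:00"),
                                 move_end = dt("2019-03-05 11:00:00"))
  b$operations <- tibble::tibble(op_id = 1, stay_id = 1, patient_id = 1,
                                 room_id = 1, urgent = 0, asa = 2,
                                 op_start = dt("2019-03-02 07:50:00"),
                                 op_end = dt("2019-03-02 10:10:00"))
  b$steps <- tibble::tibble(
    op_id = 1,
    step_code = c("STEP_ANESTH_START", "STEP_INDUCTION", "STEP_INCISION",
                  "STEP_CLOSURE", "STEP_ANESTH_END"),
    step_datetime = dt(c("2019-03-02 08:00:00", "2019-03-02 08:05:00",
                         "2019-03-02 08:20:00", "2019-03-02 09:50:00",
                         "2019-03-02 10:00:00")))
  b$drugs <- tibble::tibble(
    op_id = 1,
    drug_code = c("DRUG_PROPOFOL", "DRUG_SUFENTANIL", "DRUG_EPHEDRINE"),
    admin_datetime = dt(c("2019-03-02 08:05:00", "2019-03-02 08:05:00",
                          "2019-03-02 08:40:00")),
    dose = c(150, 20, 6))
  b$notes <- tibble::tibble(op_id = 1,
                            note_datetime = dt("2019-02-20 14:00:00"),
                            note_title = "Preanesthesia consultation",
                            note_text = "Mallampati: II\n")
  b
}

# registry + ETL'd store for a micro bundle
micro_store <- function(bundle = micro_bundle()) {
  reg <- load_registry()
  store <- cdm_create()
  report <- run_etl(bundle, reg, store)
  list(store = store, registry = reg, report = report)
}

# small seeded end-to-end pipeline, built once per test run
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      reg <- load_registry()
      gb <- synth_generate(synth_config(n_patients = 30, seed = 101))
      store <- cdm_create()
      report <- run_etl(gb$bundle, reg, store)
      derive_periods(store, reg)
      compute_feature_set(store, reg)
      cache <<- list(store = store, registry = reg, bundle = gb$bundle,
                     truth = gb$truth, report = report)
    }
    cache
  }
})

truth_vd <- function(truth, flag) {
  sort(op_visit_detail_id(truth$operations$op_id[flag]))
}
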