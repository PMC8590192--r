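# The four dashboard indicator sets (population, hemodynamics,
# ventilation, postoperative outcome), computed as tables from the CDM
# store alone — PERSON, VISIT_OCCURRENCE, VISIT_DETAIL, OBSERVATION,
# FEATURE and the care-site links. Each can be filtered by operation year
# and specialty department; an empty filter means all data.

#' Dashboard filter
#'
#' @param years Optional numeric vector of calendar years.
#' @param departments Optional character vector of department names.
#' @return A `dashboard_filter`.
#' @export
dashboard_filter <- function(years = NULL, departments = NULL) {
  structure(list(years = years, departments = departments),
            class = "dashboard_filter")
}

# operating-room visit details with year and department attached, filtered
filtered_ops <- function(store, filter) {
  stopifnot(inherits(filter, "dashboard_filter"))
  dept <- store$CARE_SITE_LINK |>
    left_join(store$CARE_SITE |> select("care_site_id", "care_site_name"),
              by = c(department_care_site_id = "care_site_id"))
  ops <- or_visits(store) |>
    left_join(dept |> select("room_care_site_id", department = "care_site_name"),
              by = c(care_site_id = "room_care_site_id")) |>
    mutate(year = as.numeric(format(.data$visit_detail_start_datetime, "%Y")))
  if (!is.null(filter$years)) {
    ops <- ops |> filter(.data$year %in% filter$years)
  }
  if (!is.null(filter$departments)) {
    ops <- ops |> filter(.data$department %in% filter$departments)
  }
  ops
}

obs_for_ops <- function(store, ops, source_value) {
  concept <- store$OBSERVATION |>
    filter(.data$observation_source_value == source_value,
           .data$visit_detail_id %in% ops$visit_detail_id)
  concept
}

hist_table <- function(values, breaks, total, label) {
  binned <- cut(values[!is.na(values)], breaks = breaks, right = FALSE,
                include.lowest = FALSE)
  counts <- table(binned)
  out <- tibble(bin = names(counts), n = as.integer(counts))
  n_known <- sum(out$n)
  if (total > n_known) {
    out <- bind_rows(out, tibble(bin = "unknown", n = total - n_known))
  }
  out$variable <- label
  out[c("variable", "bin", "n")]
}

#' Population dashboard
#'
#' Overview of the population cared for in the operating room: operation
#' and patient counts, sex ratio, urgent-operation share, and binned age,
#' BMI and weight distributions plus the ASA bar table. Bin counts (with
#' the `"unknown"` bin) sum to the number of operations.
#'
#' @param store A `cdm_store` after ETL (and, for the other dashboards,
#'   feature derivation).
#' @param filter A [dashboard_filter()].
#' @return List with `indicators` (name/value tibble) and binned tables
#'   `age_hist`, `bmi_hist`, `weight_hist`, `asa_bar`, `per_year`.
#' @export
population_summary <- function(store, filter = dashboard_filter()) {
  ops <- filtered_ops(store, filter)
  n_ops <- nrow(ops)
  patients <- store$PERSON |> filter(.data$person_id %in% ops$person_id)
  n_male <- sum(patients$gender_concept_id == GENDER_CONCEPTS[["M"]])
  n_female <- sum(patients$gender_concept_id == GENDER_CONCEPTS[["F"]])
  urgent <- obs_for_ops(store, ops, "DEMO_URGENT")
  n_urgent <- sum(urgent$value_as_number == 1, na.rm = TRUE)
  age <- obs_for_ops(store, ops, "DEMO_AGE")$value_as_number
  bmi <- obs_for_ops(store, ops, "DEMO_BMI")$value_as_number
  weight <- obs_for_ops(store, ops, "DEMO_WEIGHT")$value_as_number
  asa <- obs_for_ops(store, ops, "DEMO_ASA")

  indicators <- tibble(
    indicator = c("n_operations", "n_patients", "pct_male",
                  "n_urgent", "pct_urgent"),
    value = c(n_ops, nrow(patients),
              if (n_male + n_female > 0) {
                round(100 * n_male / (n_male + n_female), 1)
              } else NA_real_,
              n_urgent,
              if (n_ops > 0) round(100 * n_urgent / n_ops, 1) else NA_real_)
  )
  asa_bar <- tibble(asa = asa$value_as_number) |>
    count(.data$asa) |> arrange(.data$asa)
  list(
    indicators = indicators,
    age_hist = hist_table(age, seq(0, 120, 10), n_ops, "age"),
    bmi_hist = hist_table(bmi, seq(10, 60, 5), n_ops, "bmi"),
    weight_hist = hist_table(weight, seq(20, 200, 10), n_ops, "weight"),
    asa_bar = asa_bar,
    per_year = ops |> count(.data$year, name = "n_operations")
  )
}

feature_by_code <- function(store, ops, feature_name) {
  store$FEATURE |>
    filter(.data$aggregation_concept_id ==
             concept_by_name(store, feature_name),
           .data$visit_detail_id %in% ops$visit_detail_id)
}

#' Hemodynamics dashboard
#'
#' Counts of operations breaching each hemodynamic rule (MAP < 65 mmHg,
#' MAP > 120 mmHg, HR < 60 bpm, SpO2 < 90 %), with binned
#' time-beyond-threshold tables (minutes), all sourced from FEATURE rows.
#' Warns (and returns zeros) when no FEATURE rows are present.
#'
#' @inheritParams population_summary
#' @return List with `indicators` and `duration_bars` (per rule, binned
#'   minutes beyond threshold among breaching operations).
#' @export
hemodynamics_summary <- function(store, filter = dashboard_filter()) {
  ops <- filtered_ops(store, filter)
  if (nrow(store$FEATURE) == 0) {
    rlang::warn("no FEATURE rows in store; hemodynamics indicators are zero",
                class = "periomop_no_features")
  }
  rules <- tibble(
    rule = c("MAP<65 mmHg", "MAP>120 mmHg", "HR<60 bpm", "SpO2<90 %"),
    count_feature = c("number of episodes MAP<65 mmHg",
                      "number of episodes MAP>120 mmHg",
                      "number of episodes HR<60 bpm",
                      "number of episodes SpO2<90%"),
    time_feature = c("time with MAP<65 mmHg", "time with MAP>120 mmHg",
                     "time with HR<60 bpm", "time with SpO2<90%")
  )
  per_rule <- purrr::pmap_dfr(rules, function(rule, count_feature,
                                              time_feature) {
    counts <- feature_by_code(store, ops, count_feature)
    tibble(rule = rule,
           n_operations = sum(counts$value_as_number > 0))
  })
  duration_bars <- purrr::pmap_dfr(rules, function(rule, count_feature,
                                                   time_feature) {
    times <- feature_by_code(store, ops, time_feature)
    mins <- times$value_as_number[times$value_as_number > 0] / 60
    if (length(mins) == 0) return(NULL)
    hist_table(mins, c(0, 5, 10, 20, 30, 60, Inf), length(mins), rule)
  })
  list(indicators = per_rule, duration_bars = duration_bars)
}

#' Ventilation dashboard
#'
#' Per-operation median expiratory tidal volume over the anesthesia
#' period, normalized by Devine ideal body weight, with counts of
#' operations above the 8 and 10 ml/kg IBW guideline thresholds (strict)
#' and a per-year trend.
#'
#' @inheritParams population_summary
#' @return List with `indicators`, `per_operation` (visit_detail_id,
#'   vt_ml, ibw_kg, vt_ml_kg) and `per_year` trend.
#' @export
ventilation_summary <- function(store, filter = dashboard_filter()) {
  ops <- filtered_ops(store, filter)
  vt <- feature_by_code(store, ops, "median over period") |>
    filter(.data$signal_concept_id ==
             concept_by_name(store, "expiratory tidal volume")) |>
    select("visit_detail_id", vt_ml = "value_as_number")
  height <- obs_for_ops(store, ops, "DEMO_HEIGHT") |>
    select("visit_detail_id", "person_id", height_cm = "value_as_number")
  sex <- store$PERSON |>
    transmute(.data$person_id,
              sex = ifelse(.data$gender_concept_id == GENDER_CONCEPTS[["M"]],
                           "M", "F"))
  per_op <- vt |>
    inner_join(height, by = "visit_detail_id") |>
    inner_join(sex, by = "person_id") |>
    mutate(ibw_kg = ideal_body_weight(.data$sex, .data$height_cm),
           vt_ml_kg = .data$vt_ml / .data$ibw_kg) |>
    left_join(ops |> select("visit_detail_id", "year"),
              by = "visit_detail_id")
  indicators <- tibble(
    indicator = c("n_operations_vt", "n_vt_gt8", "n_vt_gt10",
                  "median_vt_ml", "median_vt_ml_kg"),
    value = c(nrow(per_op), sum(per_op$vt_ml_kg > 8),
              sum(per_op$vt_ml_kg > 10),
              stats::median(per_op$vt_ml),
              round(stats::median(per_op$vt_ml_kg), 2))
  )
  per_year <- per_op |>
    group_by(.data$year) |>
    summarise(n_operations = dplyr::n(),
              pct_gt8 = round(100 * mean(.data$vt_ml_kg > 8), 1),
              median_vt_ml_kg = round(stats::median(.data$vt_ml_kg), 2),
              .groups = "drop")
  list(indicators = indicators,
       per_operation = per_op |>
         select("visit_detail_id", "vt_ml", "ibw_kg", "vt_ml_kg"),
       per_year = per_year)
}

#' Postoperative outcome dashboard
#'
#' In-hospital mortality (from the PMSI-side discharge disposition),
#' hospital length of stay, and ICU passage after surgery (consistent with
#' [q7_icu_after_surgery()] on the same store), with per-year tables.
#'
#' @inheritParams population_summary
#' @return List with `indicators` and `per_year`.
#' @export
outcome_summary <- function(store, filter = dashboard_filter()) {
  ops <- filtered_ops(store, filter)
  n_ops <- nrow(ops)
  death_concept <- concept_by_name(store, "discharged deceased")
  vo <- store$VISIT_OCCURRENCE |>
    filter(.data$visit_occurrence_id %in% ops$visit_occurrence_id)
  dead_stays <- vo$visit_occurrence_id[
    !is.na(vo$discharge_to_concept_id) &
      vo$discharge_to_concept_id == death_concept]
  ops <- ops |>
    mutate(death = .data$visit_occurrence_id %in% dead_stays,
           icu = .data$visit_detail_id %in% q7_icu_after_surgery(store))
  los <- vo |>
    mutate(los_days = as.numeric(difftime(.data$visit_end_datetime,
                                          .data$visit_start_datetime,
                                          units = "days")))
  indicators <- tibble(
    indicator = c("n_operations", "n_death", "pct_death", "n_icu",
                  "pct_icu", "median_los_days"),
    value = c(n_ops, sum(ops$death),
              if (n_ops > 0) round(100 * sum(ops$death) / n_ops, 1) else 0,
              sum(ops$icu),
              if (n_ops > 0) round(100 * sum(ops$icu) / n_ops, 1) else 0,
              if (nrow(los) > 0) stats::median(los$los_days) else NA_real_)
  )
  per_year <- ops |>
    group_by(.data$year) |>
    summarise(n_operations = dplyr::n(), n_death = sum(.data$death),
              n_icu = sum(.data$icu), .groups = "drop")
  list(indicators = indicators, per_year = per_year)
}
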