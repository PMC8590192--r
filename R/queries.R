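# The eight audit/research queries over operating-room visits and hospital
# stays. All are read-only; results are deterministic given the store and
# parameters. Time windows are half-open: "within 30 minutes" includes
# minute 0 and excludes minute 30.

concept_by_name <- function(store, name) {
  hit <- store$CONCEPT$concept_id[store$CONCEPT$name == name]
  if (length(hit) == 0) NA_real_ else hit[[1]]
}

periods_of <- function(store, concept_name) {
  store$PERIOD |>
    filter(.data$period_concept_id == concept_by_name(store, concept_name))
}

#' Q1: operations per year and specialty department
#'
#' Counts operating-room visit details by calendar year of their start and
#' by the department their room links to; rooms without a department link
#' are reported with department `NA`.
#'
#' @param store A `cdm_store` after [run_etl()].
#' @return Tibble (`year`, `department`, `n_operations`).
#' @export
q1_operations_by_year_department <- function(store) {
  dept <- store$CARE_SITE_LINK |>
    left_join(store$CARE_SITE |>
                select("care_site_id", "care_site_name"),
              by = c(department_care_site_id = "care_site_id"))
  or_visits(store) |>
    left_join(dept |> select("room_care_site_id", "care_site_name"),
              by = c(care_site_id = "room_care_site_id")) |>
    mutate(year = as.numeric(format(.data$visit_detail_start_datetime, "%Y"))) |>
    count(.data$year, department = .data$care_site_name,
          name = "n_operations") |>
    arrange(.data$year, .data$department)
}

#' Q2: anesthesia procedures during an outpatient visit
#'
#' Operating-room visit details whose parent visit occurrence carries the
#' outpatient visit type.
#'
#' @inheritParams q1_operations_by_year_department
#' @return Sorted vector of visit_detail ids.
#' @export
q2_outpatient_anesthesia <- function(store) {
  outpatient <- concept_by_name(store, "outpatient stay")
  vo <- store$VISIT_OCCURRENCE |>
    filter(.data$visit_concept_id == outpatient)
  sort(or_visits(store) |>
         filter(.data$visit_occurrence_id %in% vo$visit_occurrence_id) |>
         pull(.data$visit_detail_id))
}

#' Q3: fast-track operations (no PACU admission)
#'
#' Operating-room visit details with no PACU-concept PERIOD row.
#'
#' @inheritParams q1_operations_by_year_department
#' @return Sorted vector of visit_detail ids.
#' @export
q3_fast_track <- function(store) {
  pacu_vd <- periods_of(store, "PACU period")$visit_detail_id
  sort(setdiff(or_visits(store)$visit_detail_id, pacu_vd))
}

#' Q4: hypotension within 30 minutes of inducing anesthesia
#'
#' Operations having a hypotension period P1 and an anesthesia period P2
#' with `P1.start` in `[P2.start, P2.start + window)`.
#'
#' @inheritParams q1_operations_by_year_department
#' @param window_s Window after anesthesia start, seconds (default 30 min).
#' @return Sorted vector of visit_detail ids.
#' @export
q4_early_hypotension <- function(store, window_s = 1800) {
  p1 <- periods_of(store, "hypotension episode (MAP<65 mmHg)")
  p2 <- periods_of(store, "anesthesia period")
  hits <- p1 |>
    inner_join(p2 |> select("visit_detail_id", anesth_start = "start_datetime"),
               by = "visit_detail_id") |>
    filter(.data$start_datetime >= .data$anesth_start,
           .data$start_datetime < .data$anesth_start + window_s)
  sort(unique(hits$visit_detail_id))
}

#' Q5: rescue drugs within 15 minutes of the first MAP drop below 65
#'
#' Administrations of norepinephrine, epinephrine, ephedrine,
#' phenylephrine, dobutamine or atropine whose datetime lies within the
#' window after the start of the operation's first hypotension period,
#' aggregated by ingredient.
#'
#' @inheritParams q1_operations_by_year_department
#' @param window_s Window after the first hypotension start, seconds
#'   (default 15 min).
#' @return Tibble (`ingredient`, `n_administrations`), ingredients with
#'   zero qualifying administrations omitted.
#' @export
q5_rescue_drugs <- function(store, window_s = 900) {
  ingredients <- c("norepinephrine", "epinephrine", "ephedrine",
                   "phenylephrine", "dobutamine", "atropine")
  ing_ids <- tibble(
    ingredient = ingredients,
    concept_id = vapply(ingredients, function(nm) concept_by_name(store, nm),
                        numeric(1))
  )
  first_p1 <- periods_of(store, "hypotension episode (MAP<65 mmHg)") |>
    group_by(.data$visit_detail_id) |>
    slice_min(.data$start_datetime, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("visit_detail_id", p1_start = "start_datetime")
  store$DRUG_EXPOSURE |>
    inner_join(ing_ids, by = c(drug_concept_id = "concept_id")) |>
    inner_join(first_p1, by = "visit_detail_id") |>
    filter(.data$drug_exposure_start_datetime >= .data$p1_start,
           .data$drug_exposure_start_datetime < .data$p1_start + window_s) |>
    count(.data$ingredient, name = "n_administrations") |>
    arrange(.data$ingredient)
}

#' Q6: length of stay by ASA status
#'
#' Stay duration (visit occurrence end minus start, days) grouped by the
#' ASA status condition attached to the stay's operation(s).
#'
#' @inheritParams q1_operations_by_year_department
#' @return Tibble (`asa`, `n_stays`, `median_days`, `q25_days`,
#'   `q75_days`).
#' @export
q6_los_by_asa <- function(store) {
  asa_concept <- concept_by_name(store, "ASA physical status")
  asa <- store$CONDITION_OCCURRENCE |>
    filter(.data$condition_concept_id == asa_concept) |>
    transmute(.data$visit_occurrence_id,
              asa = as.numeric(sub("^ASA ", "", .data$condition_source_value)))
  store$VISIT_OCCURRENCE |>
    inner_join(asa, by = "visit_occurrence_id") |>
    mutate(los_days = as.numeric(difftime(.data$visit_end_datetime,
                                          .data$visit_start_datetime,
                                          units = "days"))) |>
    group_by(.data$asa) |>
    summarise(n_stays = dplyr::n_distinct(.data$visit_occurrence_id),
              median_days = stats::median(.data$los_days),
              q25_days = unname(stats::quantile(.data$los_days, 0.25)),
              q75_days = unname(stats::quantile(.data$los_days, 0.75)),
              .groups = "drop") |>
    arrange(.data$asa)
}

#' Q7: operations followed by an intensive care unit stay
#'
#' Pairs an operating-room visit detail VD1 with an ICU visit detail VD2
#' of the same visit occurrence such that VD2 starts after VD1 ends.
#'
#' @inheritParams q1_operations_by_year_department
#' @return Sorted vector of operating-room visit_detail ids.
#' @export
q7_icu_after_surgery <- function(store) {
  icu_concept <- concept_by_name(store, "intensive care unit visit")
  icu <- store$VISIT_DETAIL |>
    filter(.data$visit_detail_concept_id == icu_concept) |>
    select("visit_occurrence_id", icu_start = "visit_detail_start_datetime")
  hits <- or_visits(store) |>
    inner_join(icu, by = "visit_occurrence_id",
               relationship = "many-to-many") |>
    filter(.data$icu_start > .data$visit_detail_end_datetime)
  sort(unique(hits$visit_detail_id))
}

ROMAN_GRADES <- c("I", "II", "III", "IV")

#' Q8: characterization of the Mallampati grade
#'
#' Parses the templated pattern `"Mallampati: <grade>"` (case-insensitive;
#' roman I-IV or arabic 1-4) out of NOTE text and aggregates by grade.
#' Notes without a parseable grade count as `"unknown"`.
#'
#' @inheritParams q1_operations_by_year_department
#' @return Tibble (`grade`, `n`).
#' @export
q8_mallampati <- function(store) {
  notes <- store$NOTE
  if (nrow(notes) == 0) return(tibble(grade = character(), n = integer()))
  m <- stringr::str_match(
    notes$note_text,
    stringr::regex("Mallampati\\s*[:=]?\\s*(IV|III|II|I|[1-4])\\b",
                   ignore_case = TRUE))[, 2]
  arabic <- m %in% as.character(1:4)
  m[arabic] <- ROMAN_GRADES[as.numeric(m[arabic])]
  m <- toupper(m)
  grade <- ifelse(is.na(m) | !m %in% ROMAN_GRADES, "unknown", m)
  tibble(grade = grade) |>
    count(.data$grade) |>
    arrange(factor(.data$grade, levels = c(ROMAN_GRADES, "unknown")))
}
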