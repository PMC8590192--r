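# Structural mapping of a source bundle into the CDM store.
#
# Routing (source table -> target table), mirroring the structural mapping
# of the preanesthesia consultation, operating-room and PACU data:
#   stays        -> VISIT_OCCURRENCE (one per stay; visit type from stay_type)
#   unit_moves   -> VISIT_DETAIL (care-unit visits)
#   operations   -> VISIT_DETAIL tagged with the local "operating room
#                   visit" concept, care_site = the room
#   diagnoses    -> CONDITION_OCCURRENCE (ICD-10 passthrough, concept 0)
#   ASA          -> CONDITION_OCCURRENCE and OBSERVATION (both: the audit
#                   queries source ASA from conditions while it is also a
#                   day-of-procedure characteristic)
#   drugs        -> DRUG_EXPOSURE at ingredient level (registry-resolved)
#   steps        -> PROCEDURE_OCCURRENCE (registry-resolved)
#   procedures   -> PROCEDURE_OCCURRENCE (CCAM passthrough, concept 0)
#   demographics -> OBSERVATION rows per operation (ASA, urgency, height,
#                   weight, age, BMI)
#   notes        -> NOTE
#   samples      -> WAVEFORM side store only, never OBSERVATION
#
# Ids are deterministic functions of the source keys (re-running the ETL on
# the same inputs reproduces the same store): person_id = patient_id,
# visit_occurrence_id = stay_id, operating-room visit_detail_id =
# 500000 + op_id, unit-move visit_detail_id = 100000 + stable row rank.
# Rows that cannot be resolved (unmapped source code, orphan operation) are
# rejected into a quarantine table, never silently dropped.

GENDER_CONCEPTS <- c(M = 8507, F = 8532)
UNMAPPED_CONCEPT <- 0
OR_VD_BASE <- 500000
MOVE_VD_BASE <- 100000

#' Deterministic visit_detail id of an operation
#'
#' The ETL assigns operating-room visit details the id `500000 + op_id`,
#' so ground-truth operations can be matched to query output.
#' @param op_id Operation id(s) from the source bundle.
#' @export
op_visit_detail_id <- function(op_id) OR_VD_BASE + op_id

#' Link operating rooms to their specialty departments
#'
#' Populates CARE_SITE (rooms and departments) and one CARE_SITE_LINK row
#' per room. A room with no department is an error naming the room.
#'
#' @param bundle A `source_bundle` (uses its `rooms` table).
#' @param store A `cdm_store`, updated in place.
#' @return Number of link rows (invisibly).
#' @export
link_care_sites <- function(bundle, store) {
  rooms <- bundle$rooms
  if (nrow(rooms) == 0) {
    store$CARE_SITE <- cdm_schemas()$CARE_SITE
    store$CARE_SITE_LINK <- cdm_schemas()$CARE_SITE_LINK
    return(invisible(0L))
  }
  orphan <- rooms$room_id[is.na(rooms$department) | rooms$department == ""]
  if (length(orphan) > 0) {
    po_abort(paste0("room(s) without department: ",
                    paste(orphan, collapse = ", ")),
             "periomop_orphan_room")
  }
  depts <- sort(unique(rooms$department))
  dept_id <- setNames(9000 + seq_along(depts), depts)
  store$CARE_SITE <- bind_rows(
    tibble(care_site_id = rooms$room_id, care_site_name = rooms$room_name,
           place_of_service = "room", source = "AIMS"),
    tibble(care_site_id = unname(dept_id), care_site_name = depts,
           place_of_service = "department", source = "AIMS")
  )
  store$CARE_SITE_LINK <- tibble(
    room_care_site_id = rooms$room_id,
    department_care_site_id = unname(dept_id[rooms$department]),
    relationship_label = "room of department"
  )
  invisible(nrow(store$CARE_SITE_LINK))
}

#' Run the structural ETL
#'
#' Maps a source bundle into a CDM store using the semantic mapping of the
#' registry. The returned report accounts, per target table, for the rows
#' whose writing was attempted (`rows_read`), written and rejected;
#' `rows_read = rows_written + rows_rejected` always holds, and rejected
#' rows are returned in the report's `"quarantine"` attribute (and
#' optionally written to a quarantine file).
#'
#' @param bundle A `source_bundle` ([synth_generate()], [read_bundle()]).
#' @param registry A `concept_registry`; unmapped source codes cause row
#'   rejection, not failure.
#' @param store An empty `cdm_store` (or `append = TRUE`).
#' @param append Allow loading into a non-empty store.
#' @param quarantine_path Optional CSV path for rejected rows.
#' @return The ETL report (tibble `table`, `rows_read`, `rows_written`,
#'   `rows_rejected`) with attribute `"quarantine"`.
#' @export
run_etl <- function(bundle, registry, store, append = FALSE,
                    quarantine_path = NULL) {
  stopifnot(inherits(bundle, "source_bundle"),
            inherits(registry, "concept_registry"),
            inherits(store, "cdm_store"))
  clinical <- setdiff(cdm_table_names(),
                      c("CONCEPT", "CONCEPT_RELATIONSHIP"))
  if (!append && any(vapply(clinical, function(tb) nrow(store[[tb]]) > 0,
                            logical(1)))) {
    po_abort("store is not empty; use append = TRUE to load anyway",
             "periomop_store_not_empty")
  }

  code_of <- setNames(registry$mappings$target_concept_id,
                      registry$mappings$source_code)
  death_concept <- add_local_concept(registry, "discharged deceased",
                                     "demographics")$concept_id
  report <- list(); quarantine <- list()
  note_reject <- function(table, keys, reason) {
    if (length(keys) == 0) return(invisible(NULL))
    quarantine[[length(quarantine) + 1]] <<-
      tibble(table = table, source_key = as.character(keys), reason = reason)
    invisible(NULL)
  }
  tally <- function(table, read, written) {
    report[[length(report) + 1]] <<-
      tibble(table = table, rows_read = read, rows_written = written,
             rows_rejected = read - written)
    invisible(NULL)
  }

  # concepts and care sites -------------------------------------------------
  link_care_sites(bundle, store)
  store$CONCEPT <- registry$concepts

  # PERSON ------------------------------------------------------------------
  pat <- bundle$patients |>
    mutate(ok = .data$sex %in% names(GENDER_CONCEPTS))
  note_reject("PERSON", pat$patient_id[!pat$ok], "unknown sex code")
  persons <- pat |>
    filter(.data$ok) |>
    transmute(person_id = .data$patient_id,
              gender_concept_id = unname(GENDER_CONCEPTS[.data$sex]),
              year_of_birth = .data$year_of_birth, source = "PMSI") |>
    arrange(.data$person_id)
  cdm_append(store, "PERSON", persons)
  tally("PERSON", nrow(pat), nrow(persons))

  # VISIT_OCCURRENCE ---------------------------------------------------------
  stays <- bundle$stays |>
    mutate(visit_code = dplyr::case_when(
      .data$stay_type == "inpatient" ~ "VIS_INPATIENT",
      .data$stay_type == "outpatient" ~ "VIS_OUTPATIENT",
      TRUE ~ NA_character_),
      ok = !is.na(.data$visit_code) & .data$patient_id %in% persons$person_id)
  note_reject("VISIT_OCCURRENCE", stays$stay_id[!stays$ok],
              "unknown stay type or person")
  vo <- stays |>
    filter(.data$ok) |>
    transmute(visit_occurrence_id = .data$stay_id,
              person_id = .data$patient_id,
              visit_concept_id = unname(code_of[.data$visit_code]),
              visit_start_datetime = .data$admit_datetime,
              visit_end_datetime = .data$discharge_datetime,
              discharge_to_concept_id =
                ifelse(.data$discharge_disposition == "death",
                       death_concept, NA_real_),
              source = "PMSI") |>
    arrange(.data$visit_occurrence_id)
  cdm_append(store, "VISIT_OCCURRENCE", vo)
  tally("VISIT_OCCURRENCE", nrow(stays), nrow(vo))
  stay_person <- setNames(vo$person_id, vo$visit_occurrence_id)

  # VISIT_DETAIL: unit moves -------------------------------------------------
  moves <- bundle$unit_moves |>
    arrange(.data$stay_id, .data$move_start, .data$unit_code) |>
    mutate(concept = unname(code_of[.data$unit_code]),
           ok = !is.na(.data$concept) &
             .data$stay_id %in% vo$visit_occurrence_id)
  note_reject("VISIT_DETAIL", moves$stay_id[!moves$ok],
              "unmapped unit code or orphan move")
  vd_moves <- moves |>
    filter(.data$ok) |>
    mutate(visit_detail_id = MOVE_VD_BASE + dplyr::row_number()) |>
    transmute(.data$visit_detail_id,
              person_id = unname(stay_person[as.character(.data$stay_id)]),
              visit_occurrence_id = .data$stay_id,
              visit_detail_concept_id = .data$concept,
              visit_detail_start_datetime = .data$move_start,
              visit_detail_end_datetime = .data$move_end,
              care_site_id = NA_real_, source = "PMSI")

  # VISIT_DETAIL: operations -------------------------------------------------
  or_concept <- unname(code_of["VIS_OR"])
  ops <- bundle$operations |>
    mutate(ok = .data$stay_id %in% vo$visit_occurrence_id)
  note_reject("VISIT_DETAIL", ops$op_id[!ops$ok], "operation without stay")
  vd_ops <- ops |>
    filter(.data$ok) |>
    transmute(visit_detail_id = op_visit_detail_id(.data$op_id),
              person_id = unname(stay_person[as.character(.data$stay_id)]),
              visit_occurrence_id = .data$stay_id,
              visit_detail_concept_id = or_concept,
              visit_detail_start_datetime = .data$op_start,
              visit_detail_end_datetime = .data$op_end,
              care_site_id = .data$room_id, source = "AIMS") |>
    arrange(.data$visit_detail_id)
  vd_all <- bind_rows(vd_moves, vd_ops)
  cdm_append(store, "VISIT_DETAIL", vd_all)
  tally("VISIT_DETAIL", nrow(moves) + nrow(ops), nrow(vd_all))

  op_keys <- vd_ops$visit_detail_id - OR_VD_BASE
  op_vd <- setNames(vd_ops$visit_detail_id, op_keys)
  op_person <- setNames(vd_ops$person_id, op_keys)
  op_stay <- setNames(vd_ops$visit_occurrence_id, op_keys)
  # first unit move per stay, for linking stay-level clinical events
  first_move <- vd_moves |>
    group_by(.data$visit_occurrence_id) |>
    slice_min(.data$visit_detail_start_datetime, n = 1, with_ties = FALSE) |>
    ungroup()
  stay_first_vd <- setNames(first_move$visit_detail_id,
                            first_move$visit_occurrence_id)

  # CONDITION_OCCURRENCE -----------------------------------------------------
  diag <- bundle$diagnoses |>
    mutate(vd = unname(stay_first_vd[as.character(.data$stay_id)]),
           ok = !is.na(.data$vd))
  note_reject("CONDITION_OCCURRENCE", diag$stay_id[!diag$ok],
              "diagnosis without resolvable stay unit move")
  asa_src <- ops |> filter(.data$ok, !is.na(.data$asa))
  cond <- bind_rows(
    diag |>
      filter(.data$ok) |>
      transmute(person_id = unname(stay_person[as.character(.data$stay_id)]),
                condition_concept_id = UNMAPPED_CONCEPT,
                condition_start_datetime = .data$diag_datetime,
                visit_occurrence_id = .data$stay_id,
                visit_detail_id = .data$vd,
                condition_source_value = .data$icd10_code, source = "PMSI"),
    asa_src |>
      transmute(person_id = unname(op_person[as.character(.data$op_id)]),
                condition_concept_id = unname(code_of["DEMO_ASA"]),
                condition_start_datetime = .data$op_start,
                visit_occurrence_id = .data$stay_id,
                visit_detail_id = op_visit_detail_id(.data$op_id),
                condition_source_value = paste0("ASA ", .data$asa),
                source = "AIMS")
  ) |>
    arrange(.data$source, .data$visit_detail_id,
            .data$condition_start_datetime, .data$condition_source_value) |>
    mutate(condition_occurrence_id = dplyr::row_number())
  cdm_append(store, "CONDITION_OCCURRENCE", cond)
  tally("CONDITION_OCCURRENCE", nrow(diag) + nrow(asa_src), nrow(cond))

  # DRUG_EXPOSURE ------------------------------------------------------------
  dr <- bundle$drugs |>
    mutate(concept = unname(code_of[.data$drug_code]),
           vd = unname(op_vd[as.character(.data$op_id)]),
           ok = !is.na(.data$concept) & !is.na(.data$vd))
  note_reject("DRUG_EXPOSURE",
              paste(dr$op_id[!dr$ok], dr$drug_code[!dr$ok]),
              "unmapped drug code or orphan operation")
  drug_rows <- dr |>
    filter(.data$ok) |>
    arrange(.data$vd, .data$admin_datetime, .data$drug_code) |>
    transmute(drug_exposure_id = dplyr::row_number(),
              person_id = unname(op_person[as.character(.data$op_id)]),
              drug_concept_id = .data$concept,
              drug_exposure_start_datetime = .data$admin_datetime,
              quantity = .data$dose,
              visit_occurrence_id = unname(op_stay[as.character(.data$op_id)]),
              visit_detail_id = .data$vd,
              drug_source_value = .data$drug_code, source = "AIMS")
  cdm_append(store, "DRUG_EXPOSURE", drug_rows)
  tally("DRUG_EXPOSURE", nrow(dr), nrow(drug_rows))

  # PROCEDURE_OCCURRENCE -----------------------------------------------------
  st <- bundle$steps |>
    mutate(concept = unname(code_of[.data$step_code]),
           vd = unname(op_vd[as.character(.data$op_id)]),
           ok = !is.na(.data$concept) & !is.na(.data$vd))
  note_reject("PROCEDURE_OCCURRENCE",
              paste(st$op_id[!st$ok], st$step_code[!st$ok]),
              "unmapped step code or orphan operation")
  pmsi_proc <- bundle$procedures |>
    mutate(vd = unname(stay_first_vd[as.character(.data$stay_id)]),
           ok = !is.na(.data$vd))
  note_reject("PROCEDURE_OCCURRENCE", pmsi_proc$stay_id[!pmsi_proc$ok],
              "procedure without resolvable stay unit move")
  proc <- bind_rows(
    st |>
      filter(.data$ok) |>
      transmute(person_id = unname(op_person[as.character(.data$op_id)]),
                procedure_concept_id = .data$concept,
                procedure_datetime = .data$step_datetime,
                visit_occurrence_id = unname(op_stay[as.character(.data$op_id)]),
                visit_detail_id = .data$vd,
                procedure_source_value = .data$step_code, source = "AIMS"),
    pmsi_proc |>
      filter(.data$ok) |>
      transmute(person_id = unname(stay_person[as.character(.data$stay_id)]),
                procedure_concept_id = UNMAPPED_CONCEPT,
                procedure_datetime = .data$proc_datetime,
                visit_occurrence_id = .data$stay_id,
                visit_detail_id = .data$vd,
                procedure_source_value = .data$ccam_code, source = "PMSI")
  ) |>
    arrange(.data$source, .data$visit_detail_id, .data$procedure_datetime,
            .data$procedure_source_value) |>
    mutate(procedure_occurrence_id = dplyr::row_number())
  cdm_append(store, "PROCEDURE_OCCURRENCE", proc)
  tally("PROCEDURE_OCCURRENCE", nrow(st) + nrow(pmsi_proc), nrow(proc))

  # OBSERVATION (day-of-procedure characteristics, per operation) -----------
  obs_src <- ops |>
    filter(.data$ok) |>
    left_join(bundle$patients, by = "patient_id")
  mk_obs <- function(code, value, unit_code = NA_character_) {
    tibble(person_id = unname(op_person[as.character(obs_src$op_id)]),
           observation_concept_id = unname(code_of[code]),
           observation_datetime = obs_src$op_start,
           value_as_number = value, value_as_string = NA_character_,
           unit_concept_id = if (is.na(unit_code)) NA_real_
                             else unname(code_of[unit_code]),
           visit_occurrence_id = unname(op_stay[as.character(obs_src$op_id)]),
           visit_detail_id = op_visit_detail_id(obs_src$op_id),
           observation_source_value = code, source = "AIMS")
  }
  age <- as.numeric(format(obs_src$op_start, "%Y")) - obs_src$year_of_birth
  bmi <- obs_src$weight_kg / (obs_src$height_cm / 100)^2
  obs <- bind_rows(
    mk_obs("DEMO_ASA", obs_src$asa),
    mk_obs("DEMO_URGENT", obs_src$urgent),
    mk_obs("DEMO_HEIGHT", obs_src$height_cm, "UNIT_CM"),
    mk_obs("DEMO_WEIGHT", obs_src$weight_kg, "UNIT_KG"),
    mk_obs("DEMO_AGE", age, "UNIT_YEAR"),
    mk_obs("DEMO_BMI", round(bmi, 1), "UNIT_KG_M2")
  ) |>
    filter(!is.na(.data$value_as_number)) |>
    arrange(.data$visit_detail_id, .data$observation_source_value) |>
    mutate(observation_id = dplyr::row_number())
  cdm_append(store, "OBSERVATION", obs)
  tally("OBSERVATION", 6 * nrow(obs_src), nrow(obs))

  # NOTE ---------------------------------------------------------------------
  nt <- bundle$notes |>
    mutate(vd = unname(op_vd[as.character(.data$op_id)]),
           ok = !is.na(.data$vd))
  note_reject("NOTE", nt$op_id[!nt$ok], "note without resolvable operation")
  notes <- nt |>
    filter(.data$ok) |>
    arrange(.data$vd, .data$note_datetime, .data$note_title) |>
    transmute(note_id = dplyr::row_number(),
              person_id = unname(op_person[as.character(.data$op_id)]),
              note_datetime = .data$note_datetime,
              note_title = .data$note_title, note_text = .data$note_text,
              visit_occurrence_id = unname(op_stay[as.character(.data$op_id)]),
              visit_detail_id = .data$vd, source = "AIMS")
  cdm_append(store, "NOTE", notes)
  tally("NOTE", nrow(nt), nrow(notes))

  # WAVEFORM side store ------------------------------------------------------
  sm <- bundle$samples |>
    mutate(concept = unname(code_of[.data$parameter_code]),
           unit = unname(code_of[.data$unit_code]),
           vd = unname(op_vd[as.character(.data$op_id)]),
           ok = !is.na(.data$concept) & !is.na(.data$vd))
  note_reject("WAVEFORM",
              unique(sm$parameter_code[!sm$ok]),
              "unmapped parameter code or orphan operation")
  wf <- sm |>
    filter(.data$ok) |>
    arrange(.data$vd, .data$concept, .data$sample_datetime) |>
    transmute(person_id = unname(op_person[as.character(.data$op_id)]),
              visit_detail_id = .data$vd, signal_concept_id = .data$concept,
              sample_datetime = .data$sample_datetime,
              value_as_number = .data$value, unit_concept_id = .data$unit)
  cdm_append(store, "WAVEFORM", wf)
  tally("WAVEFORM", nrow(sm), nrow(wf))

  store$meta$or_concept_id <- or_concept
  out <- bind_rows(report)
  q <- if (length(quarantine)) bind_rows(quarantine) else
    tibble(table = character(), source_key = character(),
           reason = character())
  if (!is.null(quarantine_path)) po_write_csv(q, quarantine_path)
  attr(out, "quarantine") <- q
  out
}
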