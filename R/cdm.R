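# The CDM store: an OMOP v5.x-style table subset plus the two extension
# tables (PERIOD, FEATURE) and the WAVEFORM side store for raw monitor
# samples (deliberately kept out of the OMOP clinical tables).
#
# A store is an environment holding one tibble per table, with reference
# semantics so ETL and derivation steps populate it in place. Only the
# columns the structural mapping needs are modelled. Every clinical row
# carries a `source` tag (AIMS | PMSI) so record accounting can be split by
# origin. Persistence is a directory of delimited text files, one per
# table, which round-trips losslessly.

CDM_SCHEMA_VERSION <- "periomop-5.3+pf.1"

# column prototypes; dt_* columns are parsed/serialized as ISO 8601
cdm_schemas <- function() {
  dt <- as.POSIXct(character(), tz = po_tz)
  list(
    PERSON = tibble(person_id = numeric(), gender_concept_id = numeric(),
                    year_of_birth = numeric(), source = character()),
    VISIT_OCCURRENCE = tibble(visit_occurrence_id = numeric(),
                              person_id = numeric(),
                              visit_concept_id = numeric(),
                              visit_start_datetime = dt,
                              visit_end_datetime = dt,
                              discharge_to_concept_id = numeric(),
                              source = character()),
    VISIT_DETAIL = tibble(visit_detail_id = numeric(), person_id = numeric(),
                          visit_occurrence_id = numeric(),
                          visit_detail_concept_id = numeric(),
                          visit_detail_start_datetime = dt,
                          visit_detail_end_datetime = dt,
                          care_site_id = numeric(), source = character()),
    CONDITION_OCCURRENCE = tibble(condition_occurrence_id = numeric(),
                                  person_id = numeric(),
                                  condition_concept_id = numeric(),
                                  condition_start_datetime = dt,
                                  visit_occurrence_id = numeric(),
                                  visit_detail_id = numeric(),
                                  condition_source_value = character(),
                                  source = character()),
    DRUG_EXPOSURE = tibble(drug_exposure_id = numeric(),
                           person_id = numeric(),
                           drug_concept_id = numeric(),
                           drug_exposure_start_datetime = dt,
                           quantity = numeric(),
                           visit_occurrence_id = numeric(),
                           visit_detail_id = numeric(),
                           drug_source_value = character(),
                           source = character()),
    PROCEDURE_OCCURRENCE = tibble(procedure_occurrence_id = numeric(),
                                  person_id = numeric(),
                                  procedure_concept_id = numeric(),
                                  procedure_datetime = dt,
                                  visit_occurrence_id = numeric(),
                                  visit_detail_id = numeric(),
                                  procedure_source_value = character(),
                                  source = character()),
    OBSERVATION = tibble(observation_id = numeric(), person_id = numeric(),
                         observation_concept_id = numeric(),
                         observation_datetime = dt,
                         value_as_number = numeric(),
                         value_as_string = character(),
                         unit_concept_id = numeric(),
                         visit_occurrence_id = numeric(),
                         visit_detail_id = numeric(),
                         observation_source_value = character(),
                         source = character()),
    NOTE = tibble(note_id = numeric(), person_id = numeric(),
                  note_datetime = dt, note_title = character(),
                  note_text = character(), visit_occurrence_id = numeric(),
                  visit_detail_id = numeric(), source = character()),
    CARE_SITE = tibble(care_site_id = numeric(),
                       care_site_name = character(),
                       place_of_service = character(), source = character()),
    CONCEPT = tibble(concept_id = numeric(), name = character(),
                     vocabulary_id = character(), domain_id = character(),
                     concept_class = character(), is_standard = logical()),
    CONCEPT_RELATIONSHIP = tibble(concept_id_1 = numeric(),
                                  concept_id_2 = numeric(),
                                  relationship_id = character()),
    CARE_SITE_LINK = tibble(room_care_site_id = numeric(),
                            department_care_site_id = numeric(),
                            relationship_label = character()),
    PERIOD = tibble(period_id = numeric(), person_id = numeric(),
                    visit_detail_id = numeric(),
                    period_concept_id = numeric(),
                    start_event_concept_id = numeric(),
                    end_event_concept_id = numeric(),
                    start_datetime = dt, end_datetime = dt),
    FEATURE = tibble(feature_id = numeric(), person_id = numeric(),
                     visit_detail_id = numeric(), period_id = numeric(),
                     signal_concept_id = numeric(),
                     aggregation_concept_id = numeric(),
                     value_as_number = numeric(),
                     unit_concept_id = numeric()),
    WAVEFORM = tibble(person_id = numeric(), visit_detail_id = numeric(),
                      signal_concept_id = numeric(), sample_datetime = dt,
                      value_as_number = numeric(), unit_concept_id = numeric())
  )
}

#' Table names of the CDM store
#'
#' The OMOP subset, the two extension tables (PERIOD, FEATURE) and the
#' WAVEFORM side store (not an OMOP table; raw monitor samples are kept
#' apart from the clinical tables by design).
#' @export
cdm_table_names <- function() names(cdm_schemas())

#' Create an empty CDM store
#'
#' @param path Optional directory for on-disk persistence; created and
#'   initialized with empty tables. Refuses an already-initialized
#'   directory unless `overwrite = TRUE`.
#' @param overwrite Allow re-initializing an existing store directory.
#' @return A `cdm_store` object (environment of tibbles, reference
#'   semantics) with the schema version recorded in `$meta`.
#' @examples
#' store <- cdm_create()
#' cdm_nrow(store)
#' @export
cdm_create <- function(path = NULL, overwrite = FALSE) {
  store <- new.env(parent = emptyenv())
  schemas <- cdm_schemas()
  for (tbl in names(schemas)) assign(tbl, schemas[[tbl]], envir = store)
  store$meta <- list(schema_version = CDM_SCHEMA_VERSION, path = path)
  class(store) <- "cdm_store"
  if (!is.null(path)) {
    if (dir.exists(path) && file.exists(file.path(path, "meta.csv")) &&
        !overwrite) {
      po_abort(paste0("store already initialized at ", path,
                      "; use overwrite = TRUE to re-initialize"),
               "periomop_store_exists")
    }
    cdm_write(store, path, overwrite = TRUE)
  }
  store
}

#' Row counts of every table in a store
#' @param store A `cdm_store`.
#' @return Named integer vector.
#' @export
cdm_nrow <- function(store) {
  vapply(cdm_table_names(), function(tbl) nrow(store[[tbl]]), integer(1))
}

#' Export a store to a directory of delimited text files
#'
#' One comma-separated UTF-8 file per table, header row, ISO 8601
#' datetimes, NULL as empty field. [cdm_read()] restores an identical
#' store.
#'
#' @param store A `cdm_store`.
#' @param path Target directory (created if needed).
#' @param overwrite Allow writing into an already-initialized directory.
#' @export
cdm_write <- function(store, path, overwrite = FALSE) {
  if (dir.exists(path) && file.exists(file.path(path, "meta.csv")) &&
      !overwrite) {
    po_abort(paste0("store already exists at ", path), "periomop_store_exists")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (tbl in cdm_table_names()) {
    po_write_csv(store[[tbl]], file.path(path, paste0(tbl, ".csv")))
  }
  po_write_csv(tibble(key = "schema_version", value = CDM_SCHEMA_VERSION),
               file.path(path, "meta.csv"))
  invisible(path)
}

#' Import a store from a directory written by [cdm_write()]
#' @param path Store directory.
#' @return A `cdm_store`.
#' @export
cdm_read <- function(path) {
  store <- cdm_create()
  schemas <- cdm_schemas()
  for (tbl in names(schemas)) {
    f <- file.path(path, paste0(tbl, ".csv"))
    if (!file.exists(f)) {
      po_abort(paste0("missing table file: ", f), "periomop_missing_file")
    }
    proto <- schemas[[tbl]]
    spec <- lapply(proto, function(col) {
      if (inherits(col, "POSIXct")) {
        readr::col_datetime(format = "%Y-%m-%d %H:%M:%S")
      } else if (is.numeric(col)) readr::col_double()
      else if (is.logical(col)) readr::col_logical()
      else readr::col_character()
    })
    store[[tbl]] <- po_read_csv(f, col_types = do.call(readr::cols, spec))
  }
  store$meta$path <- path
  store
}

#' Append rows to a store table, coercing to the table schema
#' @noRd
cdm_append <- function(store, table, rows) {
  proto <- cdm_schemas()[[table]]
  missing_cols <- setdiff(names(proto), names(rows))
  for (col in missing_cols) rows[[col]] <- rep(proto[[col]][NA_integer_], nrow(rows))
  rows <- rows[names(proto)]
  store[[table]] <- bind_rows(store[[table]], rows)
  invisible(store)
}

or_concept_id <- function(store) {
  hit <- store$CONCEPT$concept_id[store$CONCEPT$name == "operating room visit"]
  if (length(hit) == 0) NA_real_ else hit[[1]]
}

#' Operating-room visit details of a store
#' @noRd
or_visits <- function(store) {
  store$VISIT_DETAIL |>
    filter(.data$visit_detail_concept_id == or_concept_id(store))
}

#' Check the referential and temporal integrity of a store
#'
#' Verifies the contracts of the structural mapping: all foreign keys
#' resolve; every visit detail lies within its parent visit occurrence
#' window; every clinical-event row carries a resolvable visit detail;
#' periods are well ordered; every feature resolves to a period of the same
#' person and visit detail with a finite value; every operating room links
#' to exactly one department; and no raw-waveform signal concept appears in
#' OBSERVATION (the side-store rule).
#'
#' @param store A `cdm_store`.
#' @return Tibble of violations (`table`, `rule`, `row_id`), ordered by
#'   (table, rule, id); zero rows iff the store is consistent.
#' @export
cdm_integrity_check <- function(store) {
  v <- list()
  bad <- function(table, rule, ids) {
    if (length(ids) == 0) return(NULL)
    tibble(table = table, rule = rule, row_id = as.numeric(ids))
  }
  persons <- store$PERSON$person_id
  vo <- store$VISIT_OCCURRENCE
  vd <- store$VISIT_DETAIL

  event_tables <- list(
    CONDITION_OCCURRENCE = c(id = "condition_occurrence_id"),
    DRUG_EXPOSURE = c(id = "drug_exposure_id"),
    PROCEDURE_OCCURRENCE = c(id = "procedure_occurrence_id"),
    OBSERVATION = c(id = "observation_id"),
    NOTE = c(id = "note_id")
  )

  v <- c(v, list(
    bad("VISIT_OCCURRENCE", "fk_person",
        vo$visit_occurrence_id[!vo$person_id %in% persons]),
    bad("VISIT_DETAIL", "fk_person",
        vd$visit_detail_id[!vd$person_id %in% persons]),
    bad("VISIT_DETAIL", "fk_visit_occurrence",
        vd$visit_detail_id[!vd$visit_occurrence_id %in% vo$visit_occurrence_id])
  ))

  # visit-detail window within the parent visit-occurrence window
  win <- vd |>
    inner_join(vo |> select("visit_occurrence_id", "visit_start_datetime",
                            "visit_end_datetime"),
               by = "visit_occurrence_id") |>
    filter(.data$visit_detail_start_datetime < .data$visit_start_datetime |
             .data$visit_detail_end_datetime > .data$visit_end_datetime)
  v <- c(v, list(bad("VISIT_DETAIL", "window_within_parent",
                     win$visit_detail_id)))

  for (tbl in names(event_tables)) {
    dat <- store[[tbl]]
    idc <- event_tables[[tbl]][["id"]]
    v <- c(v, list(
      bad(tbl, "fk_person", dat[[idc]][!dat$person_id %in% persons]),
      bad(tbl, "fk_visit_detail",
          dat[[idc]][is.na(dat$visit_detail_id) |
                       !dat$visit_detail_id %in% vd$visit_detail_id])
    ))
  }

  per <- store$PERIOD
  v <- c(v, list(
    bad("PERIOD", "fk_visit_detail",
        per$period_id[!per$visit_detail_id %in% vd$visit_detail_id]),
    bad("PERIOD", "start_before_end",
        per$period_id[per$start_datetime > per$end_datetime]),
    bad("PERIOD", "concept_registered",
        per$period_id[!per$period_concept_id %in% store$CONCEPT$concept_id])
  ))

  fe <- store$FEATURE
  fe_join <- fe |>
    left_join(per |> select("period_id", per_person = "person_id",
                            per_vd = "visit_detail_id"),
              by = "period_id")
  v <- c(v, list(
    bad("FEATURE", "fk_period", fe_join$feature_id[is.na(fe_join$per_person)]),
    bad("FEATURE", "person_visit_match",
        fe_join$feature_id[!is.na(fe_join$per_person) &
                             (fe_join$per_person != fe_join$person_id |
                                fe_join$per_vd != fe_join$visit_detail_id)]),
    bad("FEATURE", "value_finite",
        fe$feature_id[!is.finite(fe$value_as_number)])
  ))

  rooms <- store$CARE_SITE |>
    filter(.data$place_of_service == "room")
  nlink <- table(factor(store$CARE_SITE_LINK$room_care_site_id,
                        levels = rooms$care_site_id))
  v <- c(v, list(bad("CARE_SITE", "room_linked_to_one_department",
                     rooms$care_site_id[nlink[as.character(rooms$care_site_id)] != 1])))

  wf_concepts <- unique(store$WAVEFORM$signal_concept_id)
  obs <- store$OBSERVATION
  v <- c(v, list(bad("OBSERVATION", "waveform_kept_out_of_observation",
                     obs$observation_id[obs$observation_concept_id %in% wf_concepts])))

  out <- bind_rows(v)
  if (nrow(out) == 0) {
    return(tibble(table = character(), rule = character(),
                  row_id = numeric()))
  }
  out |> arrange(.data$table, .data$rule, .data$row_id)
}

#' Record counts per table and source, with per-operation/per-stay medians
#'
#' Splits row counts of every clinical table by source system (AIMS vs
#' PMSI) and summarises records per operation (operating-room visit detail,
#' AIMS side) and per hospital stay (visit occurrence, PMSI side) as
#' median and interquartile range.
#'
#' @param store A `cdm_store`.
#' @return List with `totals` (table, source, n) and `per_unit` (table,
#'   unit, median, q25, q75).
#' @export
cdm_record_counts <- function(store) {
  tagged <- c("PERSON", "VISIT_OCCURRENCE", "VISIT_DETAIL",
              "CONDITION_OCCURRENCE", "DRUG_EXPOSURE",
              "PROCEDURE_OCCURRENCE", "OBSERVATION", "NOTE")
  totals <- purrr::map_dfr(tagged, function(tbl) {
    dat <- store[[tbl]]
    if (nrow(dat) == 0) {
      return(tibble(table = tbl, source = NA_character_, n = 0L))
    }
    dat |> count(.data$source) |> mutate(table = tbl) |>
      select("table", "source", "n")
  })
  totals <- bind_rows(
    totals,
    tibble(table = c("PERIOD", "FEATURE", "WAVEFORM"),
           source = "AIMS",
           n = c(nrow(store$PERIOD), nrow(store$FEATURE),
                 nrow(store$WAVEFORM)))
  )

  or_vd <- or_visits(store)$visit_detail_id
  per_op <- purrr::map_dfr(
    c("CONDITION_OCCURRENCE", "DRUG_EXPOSURE", "PROCEDURE_OCCURRENCE",
      "OBSERVATION", "NOTE", "PERIOD", "FEATURE"),
    function(tbl) {
      dat <- store[[tbl]]
      if (!nrow(dat) || !length(or_vd)) return(NULL)
      counts <- dat |>
        filter(.data$visit_detail_id %in% or_vd) |>
        count(.data$visit_detail_id) |>
        pull(.data$n)
      counts <- c(counts, rep(0L, length(or_vd) - length(counts)))
      tibble(table = tbl, unit = "operation",
             median = stats::median(counts),
             q25 = unname(stats::quantile(counts, 0.25)),
             q75 = unname(stats::quantile(counts, 0.75)))
    })
  vo_ids <- store$VISIT_OCCURRENCE$visit_occurrence_id
  per_stay <- purrr::map_dfr(
    c("VISIT_DETAIL", "CONDITION_OCCURRENCE", "PROCEDURE_OCCURRENCE"),
    function(tbl) {
      dat <- store[[tbl]]
      if (!nrow(dat) || !length(vo_ids)) return(NULL)
      dat <- dat |> filter(.data$source == "PMSI")
      if (!nrow(dat)) return(NULL)
      counts <- dat |> count(.data$visit_occurrence_id) |> pull(.data$n)
      tibble(table = tbl, unit = "stay",
             median = stats::median(counts),
             q25 = unname(stats::quantile(counts, 0.25)),
             q75 = unname(stats::quantile(counts, 0.75)))
    })
  list(totals = totals, per_unit = bind_rows(per_op, per_stay))
}

#' @export
print.cdm_store <- function(x, ...) {
  n <- cdm_nrow(x)
  cat("<cdm_store>", x$meta$schema_version, "\n")
  for (tbl in names(n)) cat(sprintf("  %-22s %d\n", tbl, n[[tbl]]))
  invisible(x)
}
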