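# Concept registry: local source vocabulary, semantic mapping to standard
# concepts, local-concept creation and the coverage report.
#
# A registry is an environment (reference semantics, like a vocabulary
# service) holding three tibbles:
#   sources  : source_code, source_name, category
#   mappings : source_code, target_concept_id, status (mapped | added_local)
#   concepts : concept_id, name, vocabulary_id, domain_id, concept_class,
#              is_standard
# Locally created concepts live in the OHDSI site-local id block starting at
# 2,000,000,000 and carry is_standard = FALSE.

#' Source vocabulary categories
#'
#' The eight source vocabularies used to describe patients and the
#' anesthesia procedure: patient characteristics on the day of the
#' procedure, visit types, units, monitored parameters, operation steps,
#' drugs, periods of interest and computed features.
#'
#' @export
CONCEPT_CATEGORIES <- c("demographics", "visits", "units", "measurements",
                        "operation_steps", "drugs", "period", "feature")

LOCAL_ID_BASE <- 2e9

category_domain <- c(
  demographics = "Observation", visits = "Visit", units = "Unit",
  measurements = "Measurement", operation_steps = "Procedure",
  drugs = "Drug", period = "Period", feature = "Feature"
)

empty_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$sources <- tibble(source_code = character(), source_name = character(),
                        category = character())
  reg$mappings <- tibble(source_code = character(),
                         target_concept_id = numeric(), status = character())
  reg$concepts <- tibble(concept_id = numeric(), name = character(),
                         vocabulary_id = character(), domain_id = character(),
                         concept_class = character(), is_standard = logical())
  reg$next_local_id <- LOCAL_ID_BASE
  class(reg) <- "concept_registry"
  reg
}

#' Load a concept registry
#'
#' Reads a delimited registry file (columns `source_code`, `source_name`,
#' `category`, `target_concept_id`, `target_vocabulary`, `status`) into a
#' registry object. With no `path`, the packaged registry is loaded; its
#' per-category composition reproduces the published accounting of the
#' source vocabularies (522 concepts, of which 353 map to standard OHDSI
#' concepts and 169 were created locally).
#'
#' @param path Path to a registry CSV. `NULL` (default) loads the packaged
#'   registry fixture.
#' @return A `concept_registry` object (an environment with tibbles
#'   `sources`, `mappings`, `concepts`).
#' @examples
#' reg <- load_registry()
#' coverage_report(reg)
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "concept_registry.csv",
                        package = "periomop", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    po_abort(paste0("registry file does not exist: ", path),
             "periomop_missing_file")
  }
  reg <- empty_registry()
  if (file.size(path) == 0) return(reg)
  raw <- po_read_csv(path, col_types = readr::cols(
    source_code = readr::col_character(),
    source_name = readr::col_character(),
    category = readr::col_character(),
    target_concept_id = readr::col_double(),
    target_vocabulary = readr::col_character(),
    status = readr::col_character()
  ))
  if (nrow(raw) == 0) return(reg)

  dup <- raw$source_code[duplicated(raw$source_code)]
  if (length(dup) > 0) {
    po_abort(paste0("duplicate source_code in registry: ",
                    paste(unique(dup), collapse = ", ")),
             "periomop_duplicate_code")
  }
  bad_cat <- setdiff(unique(raw$category), CONCEPT_CATEGORIES)
  if (length(bad_cat) > 0) {
    po_abort(paste0("unknown category: ", paste(bad_cat, collapse = ", "),
                    " (expected one of: ",
                    paste(CONCEPT_CATEGORIES, collapse = ", "), ")"),
             "periomop_unknown_category")
  }
  bad_status <- setdiff(unique(raw$status), c("mapped", "added_local"))
  if (length(bad_status) > 0) {
    po_abort(paste0("unknown mapping status: ",
                    paste(bad_status, collapse = ", ")),
             "periomop_bad_status")
  }
  local_bad <- raw$status == "added_local" &
    (is.na(raw$target_concept_id) | raw$target_concept_id < LOCAL_ID_BASE)
  # added_local rows without a pre-assigned id get one from the local block
  if (any(is.na(raw$target_concept_id) & raw$status == "added_local")) {
    n_missing <- sum(is.na(raw$target_concept_id) & raw$status == "added_local")
    existing <- raw$target_concept_id[raw$status == "added_local"]
    start <- max(c(LOCAL_ID_BASE - 1, existing), na.rm = TRUE) + 1
    raw$target_concept_id[is.na(raw$target_concept_id) &
                            raw$status == "added_local"] <-
      seq(start, length.out = n_missing)
  } else if (any(local_bad)) {
    po_abort(paste0("added_local concept id below the site-local block: ",
                    paste(raw$source_code[local_bad], collapse = ", ")),
             "periomop_bad_local_id")
  }

  reg$sources <- raw |> select("source_code", "source_name", "category")
  reg$mappings <- raw |> select("source_code", "target_concept_id", "status")
  reg$concepts <- raw |>
    transmute(
      concept_id = .data$target_concept_id,
      name = .data$source_name,
      vocabulary_id = ifelse(.data$status == "added_local", "local",
                             .data$target_vocabulary),
      domain_id = unname(category_domain[.data$category]),
      concept_class = ifelse(.data$category == "drugs", "ingredient",
                             "Clinical concept"),
      is_standard = .data$status == "mapped"
    ) |>
    distinct(.data$concept_id, .keep_all = TRUE)
  reg$next_local_id <-
    max(c(LOCAL_ID_BASE - 1, reg$concepts$concept_id[!reg$concepts$is_standard])) + 1
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  stopifnot(!anyDuplicated(reg$sources$source_code),
            !anyDuplicated(reg$concepts$concept_id),
            all(reg$mappings$source_code %in% reg$sources$source_code),
            nrow(reg$mappings) == nrow(reg$sources))
  local <- reg$concepts[!reg$concepts$is_standard, ]
  stopifnot(all(local$concept_id >= LOCAL_ID_BASE))
  invisible(reg)
}

#' Save a registry back to a delimited file
#'
#' Inverse of [load_registry()]; a saved registry re-loads to an identical
#' object (bit-exact round trip of codes, names, ids and statuses).
#'
#' @param registry A `concept_registry`.
#' @param path Output CSV path.
#' @export
save_registry <- function(registry, path) {
  voc <- registry$concepts |>
    select("concept_id", "vocabulary_id")
  out <- registry$sources |>
    left_join(registry$mappings, by = "source_code") |>
    left_join(voc, by = c(target_concept_id = "concept_id")) |>
    transmute(.data$source_code, .data$source_name, .data$category,
              target_concept_id = sprintf("%.0f", .data$target_concept_id),
              target_vocabulary = .data$vocabulary_id, .data$status)
  po_write_csv(out, path)
  invisible(path)
}

#' Resolve the semantic mapping of one source code
#'
#' @param registry A `concept_registry`.
#' @param source_code A registered source code.
#' @return One-row tibble: `source_code`, `target_concept_id`, `status`.
#' @export
map_source <- function(registry, source_code) {
  hit <- registry$mappings[registry$mappings$source_code == source_code, ]
  if (nrow(hit) == 0) {
    po_abort(paste0("source code not registered: ", source_code),
             "periomop_not_found")
  }
  hit
}

#' Look up the concept id a source code maps to
#' @noRd
concept_id_of <- function(registry, source_code) {
  map_source(registry, source_code)$target_concept_id
}

#' Create (or retrieve) a locally defined concept
#'
#' Adds a non-standard concept to the registry's CONCEPT table, assigning
#' the next id in the site-local block (>= 2,000,000,000). Idempotent on
#' `(name, category)`: re-adding returns the existing concept. The registry
#' is modified in place (reference semantics).
#'
#' @param registry A `concept_registry`.
#' @param name Concept name (nonempty).
#' @param category One of [CONCEPT_CATEGORIES].
#' @return One-row tibble describing the concept.
#' @export
add_local_concept <- function(registry, name, category) {
  stopifnot(is.character(name), nzchar(name))
  category <- match.arg(category, CONCEPT_CATEGORIES)
  domain <- unname(category_domain[category])
  existing <- registry$concepts |>
    filter(!.data$is_standard, .data$name == .env$name,
           .data$domain_id == .env$domain)
  if (nrow(existing) > 0) return(existing[1, ])
  concept <- tibble(
    concept_id = registry$next_local_id, name = name,
    vocabulary_id = "local", domain_id = domain,
    concept_class = if (category == "drugs") "ingredient" else "Clinical concept",
    is_standard = FALSE
  )
  registry$concepts <- bind_rows(registry$concepts, concept)
  registry$next_local_id <- registry$next_local_id + 1
  concept
}

#' Vocabulary coverage report
#'
#' Per-category accounting of the semantic mapping: concepts identified in
#' the source vocabularies, concepts mapped to standard OHDSI concepts, and
#' concepts added locally, with a totals row. Percentages are recomputed
#' from the counts (1 decimal).
#'
#' @param registry A `concept_registry`.
#' @return Tibble with columns `category`, `n_source`, `n_mapped`,
#'   `n_added`, `pct_mapped`; last row is the total.
#' @export
coverage_report <- function(registry) {
  joined <- registry$sources |>
    left_join(registry$mappings, by = "source_code")
  per_cat <- tibble(category = CONCEPT_CATEGORIES) |>
    left_join(
      joined |>
        group_by(.data$category) |>
        summarise(n_source = dplyr::n(),
                  n_mapped = sum(.data$status == "mapped"),
                  n_added = sum(.data$status == "added_local"),
                  .groups = "drop"),
      by = "category"
    ) |>
    mutate(across(c("n_source", "n_mapped", "n_added"),
                  ~ tidyr::replace_na(.x, 0L)))
  total <- per_cat |>
    summarise(category = "total", n_source = sum(.data$n_source),
              n_mapped = sum(.data$n_mapped), n_added = sum(.data$n_added))
  bind_rows(per_cat, total) |>
    mutate(pct_mapped = ifelse(.data$n_source == 0, NA_real_,
                               round(100 * .data$n_mapped / .data$n_source, 1)))
}

#' @export
print.concept_registry <- function(x, ...) {
  cat("<concept_registry>", nrow(x$sources), "source concepts,",
      nrow(x$concepts), "concepts (",
      sum(!x$concepts$is_standard), "local )\n")
  invisible(x)
}
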