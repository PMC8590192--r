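# Derivation of PERIOD rows. Three mechanisms:
#   * milestone periods  — [first start event, first subsequent end event)
#   * offset periods     — anchor event plus/minus a fixed duration
#   * threshold episodes — maximal runs of monitor samples beyond a
#     threshold, the signature intraoperative computation (hypotension
#     burden and friends)
#
# All intervals are half-open [start, end). Episode semantics, stated once:
# values outside the rule's plausibility bounds are dropped as artifacts;
# a sample qualifies if it satisfies the comparator strictly; two
# qualifying samples continue one episode iff their time difference is at
# most (nominal interval + gap tolerance); an episode ends at the next
# observed sample's time when that sample lies within the same span,
# otherwise (gap or series end) at the last qualifying time + one nominal
# interval; runs whose separation is <= gap tolerance are merged; episodes
# shorter than the minimum duration are then discarded.

#' Threshold rule for episode detection
#'
#' @param parameter Source code of the monitored parameter (e.g.
#'   `"MEAS_MAP"`).
#' @param comparator `"<"` or `">"`, applied strictly (a sample equal to
#'   the threshold does not qualify).
#' @param threshold Threshold value, in `unit`.
#' @param unit Unit source code (e.g. `"UNIT_MMHG"`).
#' @param min_duration_s Episodes shorter than this are discarded
#'   (seconds; default 0).
#' @param gap_tolerance_s Runs separated by at most this are merged
#'   (seconds; default 0).
#' @param bounds Plausibility bounds; samples outside are dropped as
#'   artifacts before detection. Default `c(-Inf, Inf)`; mean arterial
#'   pressure conventionally uses `c(20, 250)` mmHg.
#' @param period_code Source code of the period concept for derived PERIOD
#'   rows (e.g. `"PER_HYPOTENSION"`).
#' @return A `threshold_rule`.
#' @examples
#' map_hypotension_rule()
#' @export
threshold_rule <- function(parameter, comparator = c("<", ">"), threshold,
                           unit, min_duration_s = 0, gap_tolerance_s = 0,
                           bounds = c(-Inf, Inf), period_code = NULL) {
  comparator <- match.arg(comparator)
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            min_duration_s >= 0, gap_tolerance_s >= 0,
            length(bounds) == 2, bounds[1] < bounds[2],
            threshold >= bounds[1], threshold <= bounds[2])
  structure(list(parameter = parameter, comparator = comparator,
                 threshold = threshold, unit = unit,
                 min_duration_s = min_duration_s,
                 gap_tolerance_s = gap_tolerance_s, bounds = bounds,
                 period_code = period_code),
            class = "threshold_rule")
}

#' @rdname threshold_rule
#' @export
map_hypotension_rule <- function(min_duration_s = 0, gap_tolerance_s = 0) {
  threshold_rule("MEAS_MAP", "<", 65, "UNIT_MMHG", min_duration_s,
                 gap_tolerance_s, bounds = c(20, 250),
                 period_code = "PER_HYPOTENSION")
}

#' Default threshold rules
#'
#' The four expert rules surfaced by the audit queries and dashboards:
#' MAP < 65 mmHg, MAP > 120 mmHg, HR < 60 bpm, SpO2 < 90 %.
#' @export
default_threshold_rules <- function() {
  list(
    map_hypotension_rule(),
    threshold_rule("MEAS_MAP", ">", 120, "UNIT_MMHG", bounds = c(20, 250),
                   period_code = "PER_HYPERTENSION"),
    threshold_rule("MEAS_HR", "<", 60, "UNIT_BPM", bounds = c(10, 300),
                   period_code = "PER_BRADYCARDIA"),
    threshold_rule("MEAS_SPO2", "<", 90, "UNIT_PCT", bounds = c(40, 100),
                   period_code = "PER_DESATURATION")
  )
}

qualifies <- function(values, rule) {
  if (rule$comparator == "<") values < rule$threshold
  else values > rule$threshold
}

#' Detect threshold episodes in one signal series
#'
#' Finds maximal runs of consecutive samples strictly satisfying the
#' rule's comparator, after dropping artifacts (values outside the
#' plausibility bounds) and missing values. Runs separated by at most the
#' gap tolerance are merged; episodes shorter than the minimum duration
#' are discarded. An episode starts at its first qualifying sample and
#' ends at the first disqualifying sample time, or at the last sample time
#' plus one nominal interval when the series (or a data gap) ends it.
#'
#' @param times Sample times: POSIXct or numeric seconds, strictly
#'   increasing.
#' @param values Sample values (same length; `NA` allowed).
#' @param rule A [threshold_rule()].
#' @param interval_s Nominal sampling interval in seconds (default 30).
#' @return Tibble of episodes: `start`, `end` (same class as `times`),
#'   `duration_s`, `n_samples`, `extremum` (minimum value for `"<"` rules,
#'   maximum for `">"`), sorted and pairwise disjoint.
#' @examples
#' detect_episodes(c(0, 30, 60, 90, 120), c(70, 60, 60, 70, 60),
#'                 map_hypotension_rule())
#' @export
detect_episodes <- function(times, values, rule, interval_s = 30) {
  stopifnot(inherits(rule, "threshold_rule"), length(times) == length(values))
  is_dt <- inherits(times, "POSIXct")
  t <- as.numeric(times)
  stopifnot(!is.unsorted(t, strictly = TRUE))

  keep <- !is.na(values) & values >= rule$bounds[1] & values <= rule$bounds[2]
  t <- t[keep]; v <- values[keep]
  empty <- tibble(start = times[0], end = times[0], duration_s = numeric(),
                  n_samples = integer(), extremum = numeric())
  if (length(t) == 0) {
    rlang::warn("no samples left after artifact filtering",
                class = "periomop_empty_series")
    return(empty)
  }

  q <- qualifies(v, rule)
  qi <- which(q)
  if (length(qi) == 0) return(empty)

  span <- interval_s + rule$gap_tolerance_s
  n <- length(t)
  # end of the episode that closes at qualifying sample k
  close_end <- function(k) {
    if (k < n && (t[k + 1] - t[k]) <= span) t[k + 1] else t[k] + interval_s
  }

  starts <- ends <- numeric(0)
  members <- list()
  cur_start <- t[qi[1]]; cur_members <- qi[1]; last_q <- qi[1]
  for (i in qi[-1]) {
    if (t[i] - close_end(last_q) <= rule$gap_tolerance_s) {
      cur_members <- c(cur_members, i)
    } else {
      starts <- c(starts, cur_start); ends <- c(ends, close_end(last_q))
      members <- c(members, list(cur_members))
      cur_start <- t[i]; cur_members <- i
    }
    last_q <- i
  }
  starts <- c(starts, cur_start); ends <- c(ends, close_end(last_q))
  members <- c(members, list(cur_members))

  out <- tibble(
    start = starts, end = ends,
    duration_s = ends - starts,
    n_samples = lengths(members),
    extremum = vapply(members, function(m) {
      if (rule$comparator == "<") min(v[m]) else max(v[m])
    }, numeric(1))
  )
  out <- out[out$duration_s >= rule$min_duration_s, , drop = FALSE]
  if (is_dt) {
    out$start <- as.POSIXct(out$start, origin = "1970-01-01", tz = po_tz)
    out$end <- as.POSIXct(out$end, origin = "1970-01-01", tz = po_tz)
  }
  out
}

#' Clip episodes to a half-open window
#'
#' Episodes straddling a window boundary contribute only their inside
#' part; episodes fully outside are dropped.
#' @param episodes Output of [detect_episodes()].
#' @param start,end Window bounds (half-open).
#' @return Clipped episode tibble.
#' @export
clip_episodes <- function(episodes, start, end) {
  out <- episodes |>
    filter(.data$end > .env$start, .data$start < .env$end) |>
    mutate(start = pmax(.data$start, .env$start),
           end = pmin(.data$end, .env$end),
           duration_s = as.numeric(.data$end) - as.numeric(.data$start))
  out[out$duration_s > 0, , drop = FALSE]
}

#' Milestone definitions
#'
#' A period is defined by two milestones, a start event and an end event;
#' the first occurrence of the start event is paired with the first
#' subsequent occurrence of the end event.
#'
#' @param period_code,start_code,end_code Source codes of the period
#'   concept and the two milestone event concepts.
#' @return One-row tibble; combine with [dplyr::bind_rows()].
#' @export
milestone_definition <- function(period_code, start_code, end_code) {
  stopifnot(start_code != end_code)
  tibble(period_code = period_code, start_code = start_code,
         end_code = end_code)
}

#' The default milestone periods: anesthesia, surgery, PACU
#' @export
default_milestone_definitions <- function() {
  bind_rows(
    milestone_definition("PER_ANESTHESIA", "STEP_ANESTH_START", "STEP_ANESTH_END"),
    milestone_definition("PER_SURGERY", "STEP_INCISION", "STEP_CLOSURE"),
    milestone_definition("PER_PACU", "STEP_PACU_IN", "STEP_PACU_OUT")
  )
}

#' Offset definitions
#'
#' A period anchored on one event plus or minus a duration: a positive
#' offset d gives [t, t+d), a negative one [t-|d|, t).
#' @param period_code,anchor_code Source codes.
#' @param offset_s Signed offset in seconds (nonzero).
#' @export
offset_definition <- function(period_code, anchor_code, offset_s) {
  stopifnot(offset_s != 0)
  tibble(period_code = period_code, anchor_code = anchor_code,
         offset_s = offset_s)
}

#' Default offset periods: 30 min after induction, 10 min before incision
#' @export
default_offset_definitions <- function() {
  bind_rows(
    offset_definition("PER_POST_INDUCTION_30", "STEP_INDUCTION", 1800),
    offset_definition("PER_PRE_INCISION_10", "STEP_INCISION", -600)
  )
}

#' Derive milestone periods from timed events
#'
#' @param events Tibble with `visit_detail_id`, `event_code`,
#'   `event_datetime` (one row per event occurrence).
#' @param definitions Tibble of [milestone_definition()] rows.
#' @return Tibble of periods (`visit_detail_id`, `period_code`,
#'   `start_code`, `end_code`, `start_datetime`, `end_datetime`). Visits
#'   missing a milestone yield no period and one entry in the `"log"`
#'   attribute; a zero-length period (coincident milestones) is kept and
#'   logged as flagged.
#' @export
derive_milestone_periods <- function(events, definitions) {
  log <- list()
  out <- list()
  vds <- unique(events$visit_detail_id)
  for (d in seq_len(nrow(definitions))) {
    def <- definitions[d, ]
    for (vd in vds) {
      ev <- events[events$visit_detail_id == vd, ]
      st <- sort(ev$event_datetime[ev$event_code == def$start_code])
      if (length(st) == 0) {
        log <- c(log, list(tibble(visit_detail_id = vd,
                                  period_code = def$period_code,
                                  reason = "missing start milestone")))
        next
      }
      s <- st[1]
      en <- sort(ev$event_datetime[ev$event_code == def$end_code])
      en <- en[en >= s]
      if (length(en) == 0) {
        log <- c(log, list(tibble(visit_detail_id = vd,
                                  period_code = def$period_code,
                                  reason = "missing end milestone")))
        next
      }
      e <- en[1]
      if (e == s) {
        log <- c(log, list(tibble(visit_detail_id = vd,
                                  period_code = def$period_code,
                                  reason = "zero-length period")))
      }
      out <- c(out, list(tibble(visit_detail_id = vd,
                                period_code = def$period_code,
                                start_code = def$start_code,
                                end_code = def$end_code,
                                start_datetime = s, end_datetime = e)))
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(visit_detail_id = numeric(), period_code = character(),
           start_code = character(), end_code = character(),
           start_datetime = po_dt(character()),
           end_datetime = po_dt(character()))
  attr(res, "log") <- if (length(log)) bind_rows(log) else
    tibble(visit_detail_id = numeric(), period_code = character(),
           reason = character())
  res
}

#' Derive offset periods from timed events
#'
#' Uses the first occurrence of the anchor event per visit detail; visits
#' without the anchor yield no period.
#' @inheritParams derive_milestone_periods
#' @param definitions Tibble of [offset_definition()] rows.
#' @export
derive_offset_periods <- function(events, definitions) {
  anchors <- events |>
    group_by(.data$visit_detail_id, .data$event_code) |>
    summarise(t = min(.data$event_datetime), .groups = "drop")
  out <- definitions |>
    inner_join(anchors, by = c(anchor_code = "event_code"),
               relationship = "many-to-many") |>
    transmute(.data$visit_detail_id, .data$period_code,
              start_code = .data$anchor_code, end_code = .data$anchor_code,
              start_datetime = dplyr::if_else(.data$offset_s > 0, .data$t,
                                              .data$t + .data$offset_s),
              end_datetime = dplyr::if_else(.data$offset_s > 0,
                                            .data$t + .data$offset_s, .data$t))
  out
}

#' Convert detected episodes to period rows
#'
#' One PERIOD row per episode, carrying the rule's period concept;
#' boundaries preserved to the second.
#' @param episodes Output of [detect_episodes()] with POSIXct times.
#' @param rule The [threshold_rule()] used (supplies `period_code`).
#' @param visit_detail_id Visit detail the series belongs to.
#' @return Tibble in the shape of [derive_milestone_periods()] output.
#' @export
episodes_to_periods <- function(episodes, rule, visit_detail_id) {
  stopifnot(!is.null(rule$period_code))
  tibble(visit_detail_id = visit_detail_id,
         period_code = rule$period_code,
         start_code = rule$parameter, end_code = rule$parameter,
         start_datetime = episodes$start, end_datetime = episodes$end)
}

#' Derive and store all PERIOD rows for a CDM store
#'
#' Runs milestone, offset and threshold-episode derivation over every
#' operating-room visit detail: milestones come from the
#' PROCEDURE_OCCURRENCE step events, signals from the WAVEFORM side store.
#' Replaces the PERIOD table (deterministic ids; re-running reproduces the
#' same table).
#'
#' @param store A `cdm_store` populated by [run_etl()].
#' @param registry The `concept_registry` used at ETL time.
#' @param milestone_defs,offset_defs,threshold_rules Definitions; defaults
#'   cover anesthesia, surgery, PACU, the two offset examples, and the
#'   four expert threshold rules.
#' @param interval_s Nominal sampling interval, seconds.
#' @return Number of PERIOD rows written (invisibly, the store is updated
#'   in place).
#' @export
derive_periods <- function(store, registry,
                           milestone_defs = default_milestone_definitions(),
                           offset_defs = default_offset_definitions(),
                           threshold_rules = default_threshold_rules(),
                           interval_s = 30) {
  code_of <- setNames(registry$mappings$target_concept_id,
                      registry$mappings$source_code)
  id_to_code <- setNames(registry$mappings$source_code,
                         as.character(registry$mappings$target_concept_id))
  or_vd <- or_visits(store)

  events <- store$PROCEDURE_OCCURRENCE |>
    filter(.data$visit_detail_id %in% or_vd$visit_detail_id) |>
    transmute(.data$visit_detail_id,
              event_code = unname(id_to_code[as.character(.data$procedure_concept_id)]),
              event_datetime = .data$procedure_datetime) |>
    filter(!is.na(.data$event_code))

  pieces <- list(
    derive_milestone_periods(events, milestone_defs),
    derive_offset_periods(events, offset_defs)
  )

  wf <- store$WAVEFORM
  for (rule in threshold_rules) {
    sig_id <- unname(code_of[rule$parameter])
    sig <- wf |> filter(.data$signal_concept_id == sig_id)
    if (nrow(sig) == 0) next
    per_vd <- split(sig, sig$visit_detail_id)
    eps <- purrr::map_dfr(per_vd, function(s) {
      s <- s[order(s$sample_datetime), ]
      ep <- detect_episodes(s$sample_datetime, s$value_as_number, rule,
                            interval_s = interval_s)
      if (nrow(ep) == 0) return(NULL)
      episodes_to_periods(ep, rule, s$visit_detail_id[[1]])
    })
    if (nrow(eps) > 0) pieces <- c(pieces, list(eps))
  }

  all_periods <- bind_rows(pieces)
  if (nrow(all_periods) == 0) {
    store$PERIOD <- cdm_schemas()$PERIOD
    return(invisible(0L))
  }
  person_of <- setNames(store$VISIT_DETAIL$person_id,
                        store$VISIT_DETAIL$visit_detail_id)
  all_periods <- all_periods |>
    arrange(.data$visit_detail_id, .data$period_code, .data$start_datetime,
            .data$end_datetime) |>
    mutate(period_id = dplyr::row_number(),
           person_id = unname(person_of[as.character(.data$visit_detail_id)]),
           period_concept_id = unname(code_of[.data$period_code]),
           start_event_concept_id = unname(code_of[.data$start_code]),
           end_event_concept_id = unname(code_of[.data$end_code]))
  store$PERIOD <- all_periods |>
    select("period_id", "person_id", "visit_detail_id", "period_concept_id",
           "start_event_concept_id", "end_event_concept_id",
           "start_datetime", "end_datetime")
  invisible(nrow(store$PERIOD))
}
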