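# FEATURE computation: a feature is the combination of three concepts — a
# period, a raw signal and an aggregation method. Plain statistics (mean,
# median, min, max, range) reduce the samples inside the half-open period
# window; the threshold aggregations (episode count, time beyond
# threshold, area beyond threshold) reuse the episode detector. Areas and
# durations use rectangular (sample-and-hold) integration: each qualifying
# sample holds its value until the next sample, for at most one nominal
# interval, clipped to the window — 30-second monitor snapshots are
# step-wise by nature and this keeps the per-sample oracle exact.

AGGREGATION_KINDS <- c("mean", "median", "min", "max", "range",
                       "episode_count", "time_beyond_threshold",
                       "auc_beyond_threshold")

#' Aggregation specification
#'
#' @param kind One of `r paste(AGGREGATION_KINDS, collapse = ", ")`.
#' @param rule A [threshold_rule()]; required for (and only for) the
#'   threshold-based kinds.
#' @param unit_code Output unit source code; for plain statistics this is
#'   the signal's unit, for `episode_count` a count, for
#'   `time_beyond_threshold` seconds, for `auc_beyond_threshold` the
#'   signal unit times minutes.
#' @return An `aggregation_spec`.
#' @export
aggregation_spec <- function(kind, rule = NULL, unit_code = NULL) {
  kind <- match.arg(kind, AGGREGATION_KINDS)
  threshold_based <- kind %in% c("episode_count", "time_beyond_threshold",
                                 "auc_beyond_threshold")
  if (threshold_based && is.null(rule)) {
    po_abort(paste0("aggregation '", kind, "' requires a threshold rule"),
             "periomop_spec_error")
  }
  if (!threshold_based && !is.null(rule)) {
    po_abort(paste0("aggregation '", kind, "' does not take a threshold rule"),
             "periomop_spec_error")
  }
  structure(list(kind = kind, rule = rule, unit_code = unit_code),
            class = "aggregation_spec")
}

default_bounds <- function(parameter_code) {
  switch(parameter_code,
         MEAS_MAP = c(20, 250), MEAS_HR = c(10, 300),
         MEAS_SPO2 = c(40, 100), c(-Inf, Inf))
}

#' Compute one feature value over a period window
#'
#' Statistics are computed over the samples whose time lies in the
#' half-open window `[start, end)`. `time_beyond_threshold` is the summed
#' duration (seconds) of detected episodes clipped to the window;
#' `auc_beyond_threshold` is the rectangular area between the signal and
#' the threshold over qualifying samples, in signal-unit x minutes, with
#' each sample's holding time capped at one nominal interval and at the
#' window end (missing samples contribute no area).
#'
#' @param period List or one-row tibble with `start_datetime` and
#'   `end_datetime` (or `start` / `end`).
#' @param times,values The signal series (times POSIXct or numeric
#'   seconds, strictly increasing).
#' @param spec An [aggregation_spec()].
#' @param interval_s Nominal sampling interval, seconds.
#' @return One-row tibble (`value_as_number`, `unit_code`, `n_samples`),
#'   or `NULL` (with a warning) when no sample falls inside the window.
#' @examples
#' compute_feature(list(start = 0, end = 150), c(0, 30, 60, 90, 120),
#'                 c(70, 60, 60, 70, 60),
#'                 aggregation_spec("auc_beyond_threshold",
#'                                  rule = map_hypotension_rule(),
#'                                  unit_code = "UNIT_MMHG_MIN"))
#' @export
compute_feature <- function(period, times, values, spec, interval_s = 30) {
  stopifnot(inherits(spec, "aggregation_spec"))
  ws <- period[["start_datetime"]] %||% period[["start"]]
  we <- period[["end_datetime"]] %||% period[["end"]]
  ws_n <- as.numeric(ws); we_n <- as.numeric(we)
  t <- as.numeric(times)
  inside <- po_within(t, ws_n, we_n) & !is.na(values)
  if (!any(inside)) {
    rlang::warn("no samples inside the period window",
                class = "periomop_empty_window")
    return(NULL)
  }
  v_in <- values[inside]
  n_in <- sum(inside)

  value <- switch(
    spec$kind,
    mean = mean(v_in), median = stats::median(v_in), min = min(v_in),
    max = max(v_in), range = max(v_in) - min(v_in),
    episode_count = {
      ep <- detect_episodes(times, values, spec$rule, interval_s)
      nrow(clip_episodes(ep, ws, we))
    },
    time_beyond_threshold = {
      ep <- detect_episodes(times, values, spec$rule, interval_s)
      sum(clip_episodes(ep, ws, we)$duration_s)
    },
    auc_beyond_threshold = {
      rule <- spec$rule
      keep <- inside & values >= rule$bounds[1] & values <= rule$bounds[2]
      tk <- t[keep]; vk <- values[keep]
      q <- qualifies(vk, rule)
      if (!any(q)) 0 else {
        nxt <- c(tk[-1], Inf)
        dt <- pmin(nxt - tk, interval_s, we_n - tk)
        dev <- if (rule$comparator == "<") rule$threshold - vk
               else vk - rule$threshold
        sum(dev[q] * dt[q]) / 60
      }
    }
  )
  tibble(value_as_number = value, unit_code = spec$unit_code %||% NA_character_,
         n_samples = n_in)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ideal body weight (Devine)
#'
#' `50 + 0.91 * (height - 152.4)` kg for males, `45.5 + 0.91 * (height -
#' 152.4)` for females; used to normalize tidal volume to ml/kg IBW.
#'
#' @param sex `"M"`/`"F"` (or `"male"`/`"female"`, case-insensitive).
#' @param height_cm Height in cm, within \[100, 250\].
#' @return IBW in kg (vectorized).
#' @examples
#' ideal_body_weight("M", 172.4)
#' @export
ideal_body_weight <- function(sex, height_cm) {
  s <- toupper(substr(sex, 1, 1))
  if (!all(s %in% c("M", "F"))) {
    po_abort("sex must be male ('M') or female ('F')", "periomop_bad_input")
  }
  if (any(is.na(height_cm)) || any(height_cm < 100 | height_cm > 250)) {
    po_abort("height must lie within [100, 250] cm", "periomop_bad_input")
  }
  ifelse(s == "M", 50, 45.5) + 0.91 * (height_cm - 152.4)
}

#' Default feature plan
#'
#' Period x signal x aggregation combinations covering the published
#' examples: MAP range/min/max/mean over anesthesia and surgery,
#' hypotension burden (episode count, time and area below 65 mmHg),
#' hypertension, bradycardia and desaturation burden, and the median
#' expiratory tidal volume used by the ventilation indicators.
#'
#' @return Tibble with columns `period_code`, `signal_code`,
#'   `aggregation`, `feature_code`, `comparator`, `threshold`,
#'   `unit_code`.
#' @export
default_feature_plan <- function() {
  p <- function(period_code, signal_code, aggregation, feature_code,
                unit_code, comparator = NA_character_,
                threshold = NA_real_) {
    tibble(period_code = period_code, signal_code = signal_code,
           aggregation = aggregation, feature_code = feature_code,
           comparator = comparator, threshold = threshold,
           unit_code = unit_code)
  }
  bind_rows(
    p("PER_ANESTHESIA", "MEAS_MAP", "min", "FEAT_MIN", "UNIT_MMHG"),
    p("PER_ANESTHESIA", "MEAS_MAP", "max", "FEAT_MAX", "UNIT_MMHG"),
    p("PER_ANESTHESIA", "MEAS_MAP", "range", "FEAT_RANGE", "UNIT_MMHG"),
    p("PER_ANESTHESIA", "MEAS_MAP", "mean", "FEAT_MEAN", "UNIT_MMHG"),
    p("PER_SURGERY", "MEAS_MAP", "range", "FEAT_RANGE", "UNIT_MMHG"),
    p("PER_ANESTHESIA", "MEAS_MAP", "episode_count", "FEAT_COUNT_MAP_LT65",
      "UNIT_COUNT", "<", 65),
    p("PER_ANESTHESIA", "MEAS_MAP", "time_beyond_threshold",
      "FEAT_TIME_MAP_LT65", "UNIT_S", "<", 65),
    p("PER_ANESTHESIA", "MEAS_MAP", "auc_beyond_threshold",
      "FEAT_AUC_MAP_LT65", "UNIT_MMHG_MIN", "<", 65),
    p("PER_ANESTHESIA", "MEAS_MAP", "episode_count", "FEAT_COUNT_MAP_GT120",
      "UNIT_COUNT", ">", 120),
    p("PER_ANESTHESIA", "MEAS_MAP", "time_beyond_threshold",
      "FEAT_TIME_MAP_GT120", "UNIT_S", ">", 120),
    p("PER_ANESTHESIA", "MEAS_HR", "episode_count", "FEAT_COUNT_HR_LT60",
      "UNIT_COUNT", "<", 60),
    p("PER_ANESTHESIA", "MEAS_HR", "time_beyond_threshold",
      "FEAT_TIME_HR_LT60", "UNIT_S", "<", 60),
    p("PER_ANESTHESIA", "MEAS_SPO2", "episode_count", "FEAT_COUNT_SPO2_LT90",
      "UNIT_COUNT", "<", 90),
    p("PER_ANESTHESIA", "MEAS_SPO2", "time_beyond_threshold",
      "FEAT_TIME_SPO2_LT90", "UNIT_S", "<", 90),
    p("PER_ANESTHESIA", "MEAS_TVEXP", "median", "FEAT_MEDIAN", "UNIT_ML")
  )
}

#' Compute and store FEATURE rows from a plan
#'
#' One FEATURE row per (period, signal, aggregation) combination in the
#' plan with data. Deterministic ids; re-running on the same store yields
#' an identical FEATURE table (idempotent upsert on the plan's
#' combinations). Unknown concepts in the plan raise an error before
#' anything is written.
#'
#' @param store A `cdm_store` with PERIOD and WAVEFORM populated.
#' @param registry The `concept_registry` used at ETL time.
#' @param plan A feature plan, see [default_feature_plan()].
#' @param interval_s Nominal sampling interval, seconds.
#' @return Number of FEATURE rows written (invisibly; store updated in
#'   place).
#' @export
compute_feature_set <- function(store, registry,
                                plan = default_feature_plan(),
                                interval_s = 30) {
  codes <- unique(c(plan$period_code, plan$signal_code, plan$feature_code,
                    plan$unit_code))
  unknown <- setdiff(codes, registry$mappings$source_code)
  if (length(unknown) > 0) {
    po_abort(paste0("feature plan references unknown concepts: ",
                    paste(unknown, collapse = ", ")),
             "periomop_not_found")
  }
  code_of <- setNames(registry$mappings$target_concept_id,
                      registry$mappings$source_code)

  wf <- store$WAVEFORM |>
    arrange(.data$visit_detail_id, .data$signal_concept_id,
            .data$sample_datetime)
  wf_key <- paste(wf$visit_detail_id, wf$signal_concept_id)
  wf_split <- split(seq_len(nrow(wf)), wf_key)

  plan_ids <- plan |>
    mutate(period_concept_id = unname(code_of[.data$period_code]),
           signal_concept_id = unname(code_of[.data$signal_code]),
           aggregation_concept_id = unname(code_of[.data$feature_code]),
           unit_concept_id = unname(code_of[.data$unit_code]))

  rows <- list()
  for (r in seq_len(nrow(plan_ids))) {
    pr <- plan_ids[r, ]
    rule <- NULL
    if (pr$aggregation %in% c("episode_count", "time_beyond_threshold",
                              "auc_beyond_threshold")) {
      rule <- threshold_rule(pr$signal_code, pr$comparator, pr$threshold,
                             pr$unit_code,
                             bounds = default_bounds(pr$signal_code),
                             period_code = pr$period_code)
    }
    spec <- aggregation_spec(pr$aggregation, rule = rule,
                             unit_code = pr$unit_code)
    pers <- store$PERIOD |>
      filter(.data$period_concept_id == pr$period_concept_id)
    if (nrow(pers) == 0) next
    for (k in seq_len(nrow(pers))) {
      pk <- pers[k, ]
      idx <- wf_split[[paste(pk$visit_detail_id, pr$signal_concept_id)]]
      if (is.null(idx)) next
      s <- wf[idx, ]
      res <- withCallingHandlers(
        compute_feature(pk, s$sample_datetime, s$value_as_number, spec,
                        interval_s),
        periomop_empty_window = function(w) {
          invokeRestart("muffleWarning")
        }
      )
      if (is.null(res)) next
      rows <- c(rows, list(tibble(
        person_id = pk$person_id, visit_detail_id = pk$visit_detail_id,
        period_id = pk$period_id,
        signal_concept_id = pr$signal_concept_id,
        aggregation_concept_id = pr$aggregation_concept_id,
        value_as_number = res$value_as_number,
        unit_concept_id = pr$unit_concept_id
      )))
    }
  }

  new_rows <- bind_rows(rows)
  combos <- unique(plan_ids[c("signal_concept_id", "aggregation_concept_id")])
  kept <- store$FEATURE |>
    anti_join(combos, by = c("signal_concept_id", "aggregation_concept_id"))
  out <- bind_rows(kept |> select(-"feature_id"), new_rows) |>
    arrange(.data$period_id, .data$signal_concept_id,
            .data$aggregation_concept_id) |>
    mutate(feature_id = dplyr::row_number())
  store$FEATURE <- out |>
    select("feature_id", "person_id", "visit_detail_id", "period_id",
           "signal_concept_id", "aggregation_concept_id", "value_as_number",
           "unit_concept_id")
  invisible(nrow(new_rows))
}
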