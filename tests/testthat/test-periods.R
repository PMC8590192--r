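# Period derivation: milestones, offsets, threshold-episode detection and
# its equivalence with the brute-force oracle.

test_that("milestone periods pair the first start with the first later end", {
  events <- tibble::tibble(
    visit_detail_id = 1,
    event_code = c("STEP_INDUCTION", "STEP_ANESTH_END"),
    event_datetime = dt(c("2019-01-01 08:00:00", "2019-01-01 10:00:00")))
  defs <- milestone_definition("PER_ANESTHESIA", "STEP_INDUCTION",
                               "STEP_ANESTH_END")
  p <- derive_milestone_periods(events, defs)
  expect_equal(nrow(p), 1)
  expect_equal(p$start_datetime, dt("2019-01-01 08:00:00"))
  expect_equal(p$end_datetime, dt("2019-01-01 10:00:00"))
  expect_equal(nrow(attr(p, "log")), 0)
})

test_that("missing or inverted milestones yield no period plus a log entry", {
  events <- tibble::tibble(
    visit_detail_id = 1,
    event_code = c("STEP_INDUCTION"),
    event_datetime = dt("2019-01-01 08:00:00"))
  defs <- milestone_definition("PER_ANESTHESIA", "STEP_INDUCTION",
                               "STEP_ANESTH_END")
  p <- derive_milestone_periods(events, defs)
  expect_equal(nrow(p), 0)
  expect_equal(nrow(attr(p, "log")), 1)

  # end event only before the start: also no period
  events2 <- tibble::tibble(
    visit_detail_id = 1,
    event_code = c("STEP_ANESTH_END", "STEP_INDUCTION"),
    event_datetime = dt(c("2019-01-01 07:00:00", "2019-01-01 08:00:00")))
  p2 <- derive_milestone_periods(events2, defs)
  expect_equal(nrow(p2), 0)
  expect_equal(attr(p2, "log")$reason, "missing end milestone")
})

test_that("coincident milestones give a zero-length period, flagged", {
  events <- tibble::tibble(
    visit_detail_id = 1,
    event_code = c("STEP_INDUCTION", "STEP_ANESTH_END"),
    event_datetime = dt(c("2019-01-01 08:00:00", "2019-01-01 08:00:00")))
  defs <- milestone_definition("PER_ANESTHESIA", "STEP_INDUCTION",
                               "STEP_ANESTH_END")
  p <- derive_milestone_periods(events, defs)
  expect_equal(nrow(p), 1)
  expect_equal(p$start_datetime, p$end_datetime)
  expect_equal(attr(p, "log")$reason, "zero-length period")
})

test_that("offset periods extend forward or backward from the anchor", {
  events <- tibble::tibble(visit_detail_id = 1, event_code = "STEP_INDUCTION",
                           event_datetime = dt("2019-01-01 09:00:00"))
  fwd <- derive_offset_periods(
    events, offset_definition("PER_POST_INDUCTION_30", "STEP_INDUCTION", 1800))
  expect_equal(fwd$start_datetime, dt("2019-01-01 09:00:00"))
  expect_equal(fwd$end_datetime, dt("2019-01-01 09:30:00"))

  back <- derive_offset_periods(
    events, offset_definition("PER_PRE_INCISION_10", "STEP_INDUCTION", -600))
  expect_equal(back$start_datetime, dt("2019-01-01 08:50:00"))
  expect_equal(back$end_datetime, dt("2019-01-01 09:00:00"))

  none <- derive_offset_periods(
    events, offset_definition("PER_PRE_INCISION_10", "STEP_INCISION", -600))
  expect_equal(nrow(none), 0)
})

test_that("episode detection matches the hand-traced example", {
  rule <- map_hypotension_rule()
  ep <- detect_episodes(c(0, 30, 60, 90, 120), c(70, 60, 60, 70, 60), rule)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$start, c(30, 120))
  expect_equal(ep$end, c(90, 150))
  expect_equal(ep$n_samples, c(2L, 1L))
  expect_equal(ep$extremum, c(60, 60))
})

test_that("trivial series behave as specified", {
  rule <- map_hypotension_rule()
  expect_equal(nrow(detect_episodes(c(0, 30, 60), c(70, 70, 70), rule)), 0)

  all_below <- detect_episodes(c(0, 30, 60, 90), c(60, 55, 62, 58), rule)
  expect_equal(nrow(all_below), 1)
  expect_equal(all_below$start, 0)
  expect_equal(all_below$end, 120)  # last sample + nominal interval

  expect_warning(
    out <- detect_episodes(c(0, 30), c(10, 300), rule),
    class = "periomop_empty_series")
  expect_equal(nrow(out), 0)
})

test_that("detector equals the brute-force per-sample oracle on random series", {
  set.seed(4242)
  for (i in 1:1000) {
    s <- random_series()
    rule <- random_rule()
    got <- detect_episodes(s$times, s$values, rule)
    want <- oracle_detect(s$times, s$values, rule)
    expect_episodes_equal(got, want)
  }
})

test_that("episodes are sorted, pairwise disjoint, and monotone in the knobs", {
  set.seed(777)
  for (i in 1:200) {
    s <- random_series()
    base <- threshold_rule("MEAS_MAP", "<", 65, "UNIT_MMHG",
                           bounds = c(20, 250))
    ep <- detect_episodes(s$times, s$values, base)
    if (nrow(ep) > 1) {
      expect_true(all(diff(ep$start) > 0))
      expect_true(all(utils::head(ep$end, -1) <= utils::tail(ep$start, -1)))
    }
    # raising the gap tolerance never increases the episode count
    # (at zero minimum duration), nor does raising the minimum duration
    n0 <- nrow(ep)
    for (gap in c(30, 60, 120)) {
      rule_g <- threshold_rule("MEAS_MAP", "<", 65, "UNIT_MMHG",
                               gap_tolerance_s = gap, bounds = c(20, 250))
      n_gap <- nrow(detect_episodes(s$times, s$values, rule_g))
      expect_lte(n_gap, n0)
      n0 <- n_gap
    }
    n_prev <- nrow(ep)
    for (md in c(60, 120, 300)) {
      rule_m <- threshold_rule("MEAS_MAP", "<", 65, "UNIT_MMHG",
                               min_duration_s = md, bounds = c(20, 250))
      n_md <- nrow(detect_episodes(s$times, s$values, rule_m))
      expect_lte(n_md, n_prev)
      n_prev <- n_md
    }
  }
})

test_that("noise-free injected episodes are recovered exactly", {
  gb <- synth_generate(synth_config(n_patients = 15, seed = 31))
  rule <- map_hypotension_rule()
  map <- gb$bundle$samples[gb$bundle$samples$parameter_code == "MEAS_MAP", ]
  for (op in unique(gb$truth$episodes$op_id)) {
    s <- map[map$op_id == op, ]
    ep <- detect_episodes(s$sample_datetime, s$value, rule)
    tr <- gb$truth$episodes[gb$truth$episodes$op_id == op, ]
    expect_equal(nrow(ep), nrow(tr))
    expect_equal(as.numeric(ep$start), as.numeric(tr$start_datetime))
    expect_equal(as.numeric(ep$end), as.numeric(tr$end_datetime))
    expect_equal(ep$extremum, tr$min_value)
  }
})

test_that("episodes convert to period rows with boundaries kept to the second", {
  rule <- map_hypotension_rule()
  t0 <- dt("2019-01-01 08:00:00")
  times <- t0 + seq(0, 120, 30)
  ep <- detect_episodes(times, c(70, 60, 60, 70, 60), rule)
  rows <- episodes_to_periods(ep, rule, visit_detail_id = 42)
  expect_equal(nrow(rows), 2)
  expect_equal(rows$visit_detail_id, c(42, 42))
  expect_equal(rows$period_code, c("PER_HYPOTENSION", "PER_HYPOTENSION"))
  expect_equal(rows$start_datetime, t0 + c(30, 120))
  expect_equal(rows$end_datetime, t0 + c(90, 150))
  expect_equal(nrow(episodes_to_periods(ep[0, ], rule, 42)), 0)
})

test_that("store-level period derivation is deterministic and complete", {
  p <- small_pipeline()
  store <- p$store
  # every non-fast-track operation has a PACU period, fast-track none
  pacu_id <- store$CONCEPT$concept_id[store$CONCEPT$name == "PACU period"]
  pacu_vd <- store$PERIOD$visit_detail_id[
    store$PERIOD$period_concept_id == pacu_id]
  expect_setequal(pacu_vd, truth_vd(p$truth, !p$truth$operations$fast_track))
  # anesthesia periods reproduce the generator's boundaries
  an_id <- store$CONCEPT$concept_id[store$CONCEPT$name == "anesthesia period"]
  an <- store$PERIOD[store$PERIOD$period_concept_id == an_id, ]
  tr <- p$truth$operations
  an <- an[order(an$visit_detail_id), ]
  tr <- tr[order(op_visit_detail_id(tr$op_id)), ]
  expect_equal(as.numeric(an$start_datetime), as.numeric(tr$anesthesia_start))
  expect_equal(as.numeric(an$end_datetime), as.numeric(tr$anesthesia_end))
})
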