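# Feature computation: statistics over period windows, threshold burden
# metrics, ideal body weight, plan-driven FEATURE population.

win <- function(s, e) list(start = s, end = e)

test_that("plain statistics reduce the samples inside the half-open window", {
  spec <- aggregation_spec("mean", unit_code = "UNIT_MMHG")
  f <- compute_feature(win(0, 150), c(0, 30, 60, 90, 120),
                       c(70, 70, 70, 70, 70), spec)
  expect_equal(f$value_as_number, 70)
  expect_equal(f$n_samples, 5L)

  # sample at the window end is excluded
  f2 <- compute_feature(win(0, 120), c(0, 30, 60, 90, 120),
                        c(70, 70, 70, 70, 999), spec)
  expect_equal(f2$value_as_number, 70)
  expect_equal(f2$n_samples, 4L)

  expect_warning(
    out <- compute_feature(win(500, 600), c(0, 30), c(70, 70), spec),
    class = "periomop_empty_window")
  expect_null(out)
})

test_that("the worked hypotension example gives 7.5 mmHg*min and 2 episodes", {
  rule <- map_hypotension_rule()
  times <- c(0, 30, 60, 90, 120)
  values <- c(70, 60, 60, 70, 60)
  auc <- compute_feature(win(0, 150), times, values,
                         aggregation_spec("auc_beyond_threshold", rule,
                                          "UNIT_MMHG_MIN"))
  expect_equal(auc$value_as_number, 7.5)
  cnt <- compute_feature(win(0, 150), times, values,
                         aggregation_spec("episode_count", rule,
                                          "UNIT_COUNT"))
  expect_equal(cnt$value_as_number, 2)
  tm <- compute_feature(win(0, 150), times, values,
                        aggregation_spec("time_beyond_threshold", rule,
                                         "UNIT_S"))
  expect_equal(tm$value_as_number, 90)  # [30,90) + [120,150)
})

test_that("threshold aggregations require a rule and plain ones refuse it", {
  expect_error(aggregation_spec("episode_count"),
               class = "periomop_spec_error")
  expect_error(aggregation_spec("mean", rule = map_hypotension_rule()),
               class = "periomop_spec_error")
})

test_that("time beyond threshold equals the clipped episode durations", {
  set.seed(555)
  for (i in 1:100) {
    s <- random_series()
    rule <- threshold_rule("MEAS_MAP", "<", 65, "UNIT_MMHG",
                           bounds = c(20, 250))
    ep <- detect_episodes(s$times, s$values, rule)
    w_end <- max(s$times) + 30
    ws <- sort(sample(s$times, 2))
    got <- compute_feature(win(ws[1], w_end), s$times, s$values,
                           aggregation_spec("time_beyond_threshold", rule,
                                            "UNIT_S"))
    if (is.null(got)) next
    expect_equal(got$value_as_number,
                 sum(clip_episodes(ep, ws[1], w_end)$duration_s))
  }
})

test_that("the area below threshold is additive over grid-aligned partitions", {
  set.seed(556)
  for (i in 1:100) {
    s <- random_series(n = 20)
    rule <- threshold_rule("MEAS_MAP", "<", 65, "UNIT_MMHG",
                           bounds = c(20, 250))
    spec <- aggregation_spec("auc_beyond_threshold", rule, "UNIT_MMHG_MIN")
    w0 <- 0; w2 <- max(s$times) + 30
    w1 <- sample(s$times[-1], 1)  # split point on the sampling grid
    whole <- compute_feature(win(w0, w2), s$times, s$values, spec)
    left <- suppressWarnings(
      compute_feature(win(w0, w1), s$times, s$values, spec))
    right <- suppressWarnings(
      compute_feature(win(w1, w2), s$times, s$values, spec))
    if (is.null(whole)) next
    lv <- if (is.null(left)) 0 else left$value_as_number
    rv <- if (is.null(right)) 0 else right$value_as_number
    expect_equal(whole$value_as_number, lv + rv)
  }
})

test_that("order statistics are consistent on random windows", {
  set.seed(557)
  for (i in 1:50) {
    s <- random_series()
    ws <- win(0, max(s$times) + 30)
    g <- function(kind) {
      r <- compute_feature(ws, s$times, s$values, aggregation_spec(kind))
      r$value_as_number
    }
    if (all(is.na(s$values))) next
    expect_gte(g("range"), 0)
    expect_equal(g("range"), g("max") - g("min"))
    expect_lte(g("min"), g("median"))
    expect_lte(g("median"), g("max"))
  }
})

test_that("a single-sample window reduces every statistic to that sample", {
  for (kind in c("mean", "median", "min", "max")) {
    f <- compute_feature(win(30, 60), c(0, 30, 60), c(10, 42.5, 99),
                         aggregation_spec(kind))
    expect_equal(f$value_as_number, 42.5, label = kind)
  }
  expect_equal(compute_feature(win(30, 60), c(0, 30, 60), c(10, 42.5, 99),
                               aggregation_spec("range"))$value_as_number, 0)
})

test_that("ideal body weight follows the Devine estimate", {
  expect_equal(ideal_body_weight("M", 152.4), 50)
  expect_equal(ideal_body_weight("F", 152.4), 45.5)
  expect_equal(ideal_body_weight("M", 172.4), 68.2)
  expect_equal(ideal_body_weight(c("male", "Female"), c(172.4, 152.4)),
               c(68.2, 45.5))
  expect_error(ideal_body_weight("M", 90), class = "periomop_bad_input")
  expect_error(ideal_body_weight("X", 170), class = "periomop_bad_input")
})

test_that("the feature plan populates combinatorially and idempotently", {
  p <- small_pipeline()
  store <- p$store
  reg <- p$registry
  plan <- default_feature_plan()[c(1, 2), ]  # min and max of MAP, anesthesia
  an_id <- store$CONCEPT$concept_id[store$CONCEPT$name == "anesthesia period"]
  n_an <- sum(store$PERIOD$period_concept_id == an_id)

  s2 <- cdm_create()
  for (tbl in cdm_table_names()) s2[[tbl]] <- store[[tbl]]
  s2$FEATURE <- periomop:::cdm_schemas()$FEATURE
  n <- compute_feature_set(s2, reg, plan)
  expect_equal(n, 2 * n_an)

  before <- s2$FEATURE
  compute_feature_set(s2, reg, plan)
  expect_equal(s2$FEATURE, before)

  bad_plan <- plan
  bad_plan$signal_code[1] <- "MEAS_NOPE"
  s3 <- cdm_create()
  for (tbl in cdm_table_names()) s3[[tbl]] <- store[[tbl]]
  expect_error(compute_feature_set(s3, reg, bad_plan), "MEAS_NOPE",
               class = "periomop_not_found")

  expect_equal(compute_feature_set(s2, reg, default_feature_plan()[0, ]), 0)
})

test_that("stored burden features agree with the period table (conservation)", {
  p <- small_pipeline()
  store <- p$store
  hyp_id <- store$CONCEPT$concept_id[
    store$CONCEPT$name == "hypotension episode (MAP<65 mmHg)"]
  time_id <- store$CONCEPT$concept_id[
    store$CONCEPT$name == "time with MAP<65 mmHg"]
  cnt_id <- store$CONCEPT$concept_id[
    store$CONCEPT$name == "number of episodes MAP<65 mmHg"]
  per_vd <- store$PERIOD |>
    dplyr::filter(period_concept_id == hyp_id) |>
    dplyr::group_by(visit_detail_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      secs = sum(as.numeric(end_datetime) - as.numeric(start_datetime)))
  fcnt <- store$FEATURE |> dplyr::filter(aggregation_concept_id == cnt_id)
  ftime <- store$FEATURE |> dplyr::filter(aggregation_concept_id == time_id)
  j <- per_vd |>
    dplyr::inner_join(fcnt, by = "visit_detail_id") |>
    dplyr::inner_join(ftime, by = "visit_detail_id",
                      suffix = c("_cnt", "_time"))
  expect_gt(nrow(j), 0)
  expect_equal(j$value_as_number_cnt, j$n)
  expect_equal(j$value_as_number_time, j$secs)
})
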