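# Seeded generator of AIMS-like and PMSI-like source tables with recorded
# ground truth, emulating the structure (not the scale) of a perioperative
# warehouse: one stay per operation, operation steps on a fixed template,
# 30-second monitor samples with rectangular threshold deviations injected
# at known locations, templated consultation notes, and discharge data with
# unit moves, diagnoses and procedures.
#
# Injected mean-arterial-pressure episodes are separated by more than the
# detector's gap tolerance and the background noise is truncated so it
# cannot cross the 65 mmHg threshold: episode recovery is unambiguous by
# construction, which is what makes exact ground-truth comparison a fair
# test of the detection and query layers.

ICD10_CODES <- c("I10", "E11.9", "I48.0", "J44.9", "N18.3", "K21.9",
                 "E78.5", "I25.1", "M54.5", "D64.9")
CCAM_CODES <- c("DZEA002", "HHFA016", "NEKA020", "LMMA012", "GFFA004",
                "EBLA003", "HMFC004", "JVJF004")
RESCUE_DRUGS <- c("DRUG_NOREPINEPHRINE", "DRUG_EPINEPHRINE",
                  "DRUG_EPHEDRINE", "DRUG_PHENYLEPHRINE",
                  "DRUG_DOBUTAMINE", "DRUG_ATROPINE")

#' Generator configuration
#'
#' Study conditions for the synthetic source bundle. Probabilities are
#' per-operation unless noted; durations in the stated units; the sampling
#' interval of monitor signals is 30 seconds. Injected hypotension episodes
#' are rectangular deviations below the 65 mmHg threshold with grid-aligned
#' boundaries.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; a fixed seed yields an identical bundle.
#' @param start_date,end_date Operation date range (dates, inclusive).
#' @param p_second_operation Probability a patient has a second operation.
#' @param p_outpatient Probability a stay is outpatient.
#' @param p_urgent Probability an operation is urgent.
#' @param p_icu Probability of an ICU transfer after surgery (inpatients).
#' @param p_fast_track Probability the PACU is skipped (fast track).
#' @param p_death Probability of in-hospital death (inpatients).
#' @param asa_probs Distribution of ASA physical status 1-5.
#' @param mallampati_probs Distribution of Mallampati grades I-IV.
#' @param p_malformed_note Probability the consultation note is unparseable.
#' @param sampling_interval_s Monitor sampling interval, seconds.
#' @param op_duration_range_min Anesthesia duration range, minutes.
#' @param episode_count_probs Distribution of injected hypotension episode
#'   counts per operation (names "0","1",...).
#' @param episode_depth_range Depth below 65 mmHg of injected episodes.
#' @param episode_duration_range_s Injected episode duration range, seconds
#'   (rounded to the sampling grid).
#' @param episode_gap_s Minimum separation between injected episodes,
#'   seconds (must exceed the detector's gap tolerance).
#' @param p_rescue Probability a rescue vasopressor/chronotrope follows the
#'   first hypotension episode.
#' @param p_rescue_in_window Probability that administration falls within
#'   15 minutes of the episode start (otherwise 16-25 minutes after).
#' @param p_bradycardia Probability of a whole-operation heart rate below
#'   60 bpm.
#' @param p_desaturation Probability of one injected SpO2 < 90 episode.
#' @param vt_per_kg_range Per-operation expiratory tidal volume range,
#'   ml/kg of ideal body weight.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 200,
                         seed = 20211029,
                         start_date = "2018-01-01",
                         end_date = "2021-12-31",
                         p_second_operation = 0.15,
                         p_outpatient = 0.20,
                         p_urgent = 0.12,
                         p_icu = 0.10,
                         p_fast_track = 0.15,
                         p_death = 0.03,
                         asa_probs = c("1" = 0.25, "2" = 0.45, "3" = 0.22,
                                       "4" = 0.07, "5" = 0.01),
                         mallampati_probs = c(I = 0.40, II = 0.35,
                                              III = 0.18, IV = 0.07),
                         p_malformed_note = 0.02,
                         sampling_interval_s = 30,
                         op_duration_range_min = c(45, 180),
                         episode_count_probs = c("0" = 0.35, "1" = 0.35,
                                                 "2" = 0.20, "3" = 0.10),
                         episode_depth_range = c(5, 20),
                         episode_duration_range_s = c(120, 600),
                         episode_gap_s = 120,
                         p_rescue = 0.75,
                         p_rescue_in_window = 0.80,
                         p_bradycardia = 0.07,
                         p_desaturation = 0.05,
                         vt_per_kg_range = c(5.5, 11)) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_second_operation, cfg$p_outpatient, cfg$p_urgent,
             cfg$p_icu, cfg$p_fast_track, cfg$p_death, cfg$asa_probs,
             cfg$mallampati_probs, cfg$p_malformed_note, cfg$p_rescue,
             cfg$p_rescue_in_window, cfg$p_bradycardia, cfg$p_desaturation)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$sampling_interval_s > 0,
            cfg$n_patients >= 0, cfg$episode_gap_s >= 0)
  # feasibility: the worst-case episode load must fit inside the shortest
  # operation, leaving the 5-minute head and tail margins used at placement
  k_max <- max(as.integer(names(episode_count_probs)[episode_count_probs > 0]))
  worst <- k_max * max(episode_duration_range_s) +
    max(0, k_max - 1) * episode_gap_s + 600
  if (worst > min(op_duration_range_min) * 60) {
    po_abort(paste0("infeasible episode spec: up to ", k_max, " episodes of ",
                    max(episode_duration_range_s), " s cannot fit in a ",
                    min(op_duration_range_min), " min operation"),
             "periomop_config_error")
  }
  class(cfg) <- "synth_config"
  cfg
}

empty_bundle <- function() {
  dt <- as.POSIXct(character(), tz = po_tz)
  structure(list(
    patients = tibble(patient_id = numeric(), sex = character(),
                      year_of_birth = numeric(), height_cm = numeric(),
                      weight_kg = numeric()),
    rooms = tibble(room_id = numeric(), room_name = character(),
                   department = character()),
    operations = tibble(op_id = numeric(), stay_id = numeric(),
                        patient_id = numeric(), room_id = numeric(),
                        urgent = numeric(), asa = numeric(),
                        op_start = dt, op_end = dt),
    steps = tibble(op_id = numeric(), step_code = character(),
                   step_datetime = dt),
    drugs = tibble(op_id = numeric(), drug_code = character(),
                   admin_datetime = dt, dose = numeric()),
    samples = tibble(op_id = numeric(), parameter_code = character(),
                     sample_datetime = dt, value = numeric(),
                     unit_code = character()),
    notes = tibble(op_id = numeric(), note_datetime = dt,
                   note_title = character(), note_text = character()),
    stays = tibble(stay_id = numeric(), patient_id = numeric(),
                   admit_datetime = dt, discharge_datetime = dt,
                   stay_type = character(), discharge_disposition = character()),
    unit_moves = tibble(stay_id = numeric(), unit_code = character(),
                        move_start = dt, move_end = dt),
    diagnoses = tibble(stay_id = numeric(), icd10_code = character(),
                       diag_datetime = dt),
    procedures = tibble(stay_id = numeric(), ccam_code = character(),
                        proc_datetime = dt)
  ), class = "source_bundle")
}

empty_truth <- function() {
  dt <- as.POSIXct(character(), tz = po_tz)
  structure(list(
    operations = tibble(op_id = numeric(), stay_id = numeric(),
                        patient_id = numeric(), year = numeric(),
                        department = character(), outpatient = logical(),
                        urgent = logical(), fast_track = logical(),
                        icu_after = logical(), death = logical(),
                        early_hypotension = logical(),
                        rescue_within_15 = logical(), asa = numeric(),
                        mallampati = character(),
                        anesthesia_start = dt, anesthesia_end = dt,
                        n_episodes = numeric()),
    episodes = tibble(op_id = numeric(), episode_index = numeric(),
                      start_datetime = dt, end_datetime = dt,
                      min_value = numeric()),
    rescue = tibble(op_id = numeric(), ingredient_code = character(),
                    admin_datetime = dt, within_15 = logical())
  ), class = "ground_truth")
}

draw <- function(n, levels, probs) {
  if (n == 0) return(levels[0])
  sample(levels, n, replace = TRUE, prob = probs)
}

#' Generate a synthetic source bundle with ground truth
#'
#' Deterministic under the configured seed: the same configuration yields a
#' byte-identical bundle and truth. See [synth_config()] for the emulated
#' study conditions.
#'
#' @param config A [synth_config()].
#' @return List with `bundle` (a `source_bundle` of AIMS- and PMSI-like
#'   tibbles) and `truth` (a `ground_truth` with injected episodes and
#'   expected query memberships).
#' @examples
#' gb <- synth_generate(synth_config(n_patients = 5, seed = 1))
#' nrow(gb$bundle$operations)
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  bundle <- empty_bundle()
  truth <- empty_truth()
  if (config$n_patients == 0) return(list(bundle = bundle, truth = truth))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  iv <- config$sampling_interval_s

  # --- patients -----------------------------------------------------------
  np <- config$n_patients
  sex <- draw(np, c("M", "F"), c(0.5, 0.5))
  height <- pmin(200, pmax(145, round(rnorm(np, ifelse(sex == "M", 176, 163), 7))))
  bmi <- pmin(45, pmax(16, rnorm(np, 26, 4)))
  weight <- round(bmi * (height / 100)^2, 1)
  bundle$patients <- tibble(
    patient_id = seq_len(np), sex = sex,
    year_of_birth = sample(1935:2003, np, replace = TRUE),
    height_cm = height, weight_kg = weight
  )

  # --- care sites ---------------------------------------------------------
  departments <- c("Cardiac surgery", "Orthopedic surgery",
                   "Digestive surgery")
  bundle$rooms <- tibble(
    room_id = 1:8,
    room_name = paste0("OR-", 1:8),
    department = departments[c(1, 1, 2, 2, 2, 3, 3, 3)]
  )

  # --- operations / stays -------------------------------------------------
  n_ops_per_patient <- 1 + rbinom(np, 1, config$p_second_operation)
  op_patient <- rep(seq_len(np), n_ops_per_patient)
  n_ops <- length(op_patient)
  op_id <- seq_len(n_ops)
  stay_id <- op_id

  day_pool <- seq(as.Date(config$start_date), as.Date(config$end_date), by = 1)
  op_day <- sample(day_pool, n_ops, replace = TRUE)
  op_t0 <- po_dt(paste0(op_day, " 08:00:00")) +
    sample(0:16, n_ops, replace = TRUE) * 1800
  dur_min <- round(runif(n_ops, config$op_duration_range_min[1],
                         config$op_duration_range_min[2]))
  op_t0 <- po_dt(trunc(op_t0, "mins"))
  op_tend <- op_t0 + dur_min * 60

  outpatient <- runif(n_ops) < config$p_outpatient
  urgent <- runif(n_ops) < config$p_urgent
  icu_after <- !outpatient & runif(n_ops) < config$p_icu
  fast_track <- runif(n_ops) < config$p_fast_track
  death <- !outpatient & runif(n_ops) < config$p_death
  asa <- as.numeric(draw(n_ops, names(config$asa_probs), config$asa_probs))
  mallampati <- draw(n_ops, names(config$mallampati_probs),
                     config$mallampati_probs)
  malformed <- runif(n_ops) < config$p_malformed_note
  room <- sample(bundle$rooms$room_id, n_ops, replace = TRUE)

  bundle$operations <- tibble(
    op_id = op_id, stay_id = stay_id, patient_id = op_patient,
    room_id = room, urgent = as.numeric(urgent), asa = asa,
    op_start = op_t0 - 600, op_end = op_tend + 600
  )

  # --- steps --------------------------------------------------------------
  step_at <- function(code, t) tibble(op_id = op_id, step_code = code,
                                      step_datetime = t)
  steps <- bind_rows(
    step_at("STEP_ANESTH_START", op_t0),
    step_at("STEP_INDUCTION", op_t0 + 300),
    step_at("STEP_INTUBATION", op_t0 + 420),
    step_at("STEP_INCISION", op_t0 + 1200),
    step_at("STEP_CLOSURE", op_tend - 600),
    step_at("STEP_ANESTH_END", op_tend)
  )
  pacu <- !fast_track
  steps <- bind_rows(
    steps,
    tibble(op_id = op_id[pacu], step_code = "STEP_PACU_IN",
           step_datetime = op_tend[pacu] + 300),
    tibble(op_id = op_id[pacu], step_code = "STEP_PACU_OUT",
           step_datetime = op_tend[pacu] + 3600)
  )
  bundle$steps <- steps |> arrange(.data$op_id, .data$step_datetime,
                                   .data$step_code)

  # --- injected hypotension episodes (grid-aligned rectangles) ------------
  n_epi <- as.numeric(draw(n_ops, names(config$episode_count_probs),
                           config$episode_count_probs))
  epi_list <- vector("list", n_ops)
  for (i in seq_len(n_ops)) {
    k <- n_epi[i]
    if (k == 0) next
    lo <- config$episode_duration_range_s[1]
    hi <- config$episode_duration_range_s[2]
    durs <- round(runif(k, lo, hi) / iv) * iv
    durs <- pmax(iv, durs)
    # place sequentially in [t0 + 5 min, tend - 5 min] with >= episode_gap_s
    # between consecutive episodes
    avail <- (dur_min[i] * 60 - 600) - sum(durs) - (k - 1) * config$episode_gap_s
    slack <- if (k > 0) diff(c(0, sort(runif(k, 0, 1)))) * avail else numeric()
    starts <- numeric(k); cursor <- 300
    for (j in seq_len(k)) {
      cursor <- cursor + slack[j]
      starts[j] <- round(cursor / iv) * iv
      cursor <- starts[j] + durs[j] + config$episode_gap_s
    }
    depth <- runif(k, config$episode_depth_range[1],
                   config$episode_depth_range[2])
    epi_list[[i]] <- tibble(
      op_id = op_id[i], episode_index = seq_len(k),
      start_s = starts, end_s = starts + durs, depth = depth
    )
  }
  episodes <- bind_rows(epi_list)
  if (nrow(episodes) == 0) {
    episodes <- tibble(op_id = numeric(), episode_index = numeric(),
                       start_s = numeric(), end_s = numeric(),
                       depth = numeric())
  }

  # --- monitor signals ----------------------------------------------------
  tnoise <- function(n, sd, cap) pmin(cap, pmax(-cap, rnorm(n, 0, sd)))
  grid_list <- lapply(seq_len(n_ops), function(i) {
    t_rel <- seq(0, dur_min[i] * 60, by = iv)
    tibble(op_id = op_id[i], t_rel = t_rel)
  })
  grid <- bind_rows(grid_list)
  n_samp <- nrow(grid)

  map_base <- pmax(75, rnorm(n_ops, 85, 5))
  map_val <- map_base[match(grid$op_id, op_id)] + tnoise(n_samp, 2, 4)
  map_val <- pmax(68, map_val)
  if (nrow(episodes) > 0) {
    key <- paste(grid$op_id, grid$t_rel)
    epi_samples <- episodes |>
      rowwise() |>
      reframe(op_id = .data$op_id,
              t_rel = seq(.data$start_s, .data$end_s - .env$iv, by = .env$iv),
              level = 65 - .data$depth)
    hit <- match(paste(epi_samples$op_id, epi_samples$t_rel), key)
    map_val[hit] <- pmin(64, epi_samples$level + tnoise(length(hit), 1, 3))
  }

  hr_brady <- runif(n_ops) < config$p_bradycardia
  hr_base <- ifelse(hr_brady, runif(n_ops, 48, 55),
                    pmax(66, rnorm(n_ops, 78, 8)))
  hr_val <- hr_base[match(grid$op_id, op_id)] + tnoise(n_samp, 2, 4)
  hr_val <- ifelse(hr_brady[match(grid$op_id, op_id)],
                   pmin(59, hr_val), pmax(62, hr_val))

  spo2_base <- runif(n_ops, 96.5, 99)
  spo2_val <- pmin(100, pmax(95, spo2_base[match(grid$op_id, op_id)] +
                               tnoise(n_samp, 0.5, 1.4)))
  desat <- runif(n_ops) < config$p_desaturation
  desat_start <- round(runif(n_ops, 600, dur_min * 60 - 900) / iv) * iv
  desat_len <- round(runif(n_ops, 60, 300) / iv) * iv
  in_desat <- desat[match(grid$op_id, op_id)] &
    grid$t_rel >= desat_start[match(grid$op_id, op_id)] &
    grid$t_rel < (desat_start + desat_len)[match(grid$op_id, op_id)]
  spo2_val[in_desat] <- pmin(89, runif(sum(in_desat), 85, 89))

  ibw <- ideal_body_weight(bundle$patients$sex, bundle$patients$height_cm)
  vt_perkg <- runif(n_ops, config$vt_per_kg_range[1], config$vt_per_kg_range[2])
  vt_ml <- vt_perkg * ibw[match(op_patient, bundle$patients$patient_id)]
  vt_val <- pmax(100, vt_ml[match(grid$op_id, op_id)] + tnoise(n_samp, 8, 20))

  abs_time <- op_t0[match(grid$op_id, op_id)] + grid$t_rel
  bundle$samples <- bind_rows(
    tibble(op_id = grid$op_id, parameter_code = "MEAS_MAP",
           sample_datetime = abs_time, value = round(map_val, 1),
           unit_code = "UNIT_MMHG"),
    tibble(op_id = grid$op_id, parameter_code = "MEAS_HR",
           sample_datetime = abs_time, value = round(hr_val, 0),
           unit_code = "UNIT_BPM"),
    tibble(op_id = grid$op_id, parameter_code = "MEAS_SPO2",
           sample_datetime = abs_time, value = round(spo2_val, 0),
           unit_code = "UNIT_PCT"),
    tibble(op_id = grid$op_id, parameter_code = "MEAS_TVEXP",
           sample_datetime = abs_time, value = round(vt_val, 0),
           unit_code = "UNIT_ML")
  ) |> arrange(.data$op_id, .data$parameter_code, .data$sample_datetime)

  # --- drugs --------------------------------------------------------------
  has_cefa <- runif(n_ops) < 0.8
  has_rocu <- runif(n_ops) < 0.5
  drugs <- bind_rows(
    tibble(op_id = op_id, drug_code = "DRUG_PROPOFOL",
           admin_datetime = op_t0 + 300, dose = round(runif(n_ops, 100, 200))),
    tibble(op_id = op_id, drug_code = "DRUG_SUFENTANIL",
           admin_datetime = op_t0 + 300, dose = round(runif(n_ops, 10, 30))),
    tibble(op_id = op_id[has_cefa], drug_code = "DRUG_CEFAZOLIN",
           admin_datetime = op_t0[has_cefa] + 600,
           dose = rep(2000, sum(has_cefa))),
    tibble(op_id = op_id[has_rocu], drug_code = "DRUG_ROCURONIUM",
           admin_datetime = op_t0[has_rocu] + 360,
           dose = round(runif(sum(has_rocu), 30, 60)))
  )

  first_epi <- episodes |>
    group_by(.data$op_id) |>
    slice_min(.data$episode_index, n = 1) |>
    ungroup()
  gets_rescue <- first_epi$op_id[runif(nrow(first_epi)) < config$p_rescue]
  rescue <- first_epi |>
    filter(.data$op_id %in% gets_rescue) |>
    mutate(
      ingredient_code = sample(RESCUE_DRUGS, dplyr::n(), replace = TRUE),
      in_window = runif(dplyr::n()) < .env$config$p_rescue_in_window,
      latency_s = ifelse(.data$in_window, round(runif(dplyr::n(), 60, 840)),
                         round(runif(dplyr::n(), 960, 1500))),
      admin_datetime = op_t0[match(.data$op_id, .env$op_id)] +
        .data$start_s + .data$latency_s
    )
  drugs <- bind_rows(
    drugs,
    rescue |> transmute(.data$op_id, drug_code = .data$ingredient_code,
                        .data$admin_datetime,
                        dose = round(runif(dplyr::n(), 1, 10), 1))
  )
  bundle$drugs <- drugs |> arrange(.data$op_id, .data$admin_datetime,
                                   .data$drug_code)

  # --- notes --------------------------------------------------------------
  grade_txt <- ifelse(malformed, "not assessed", mallampati)
  bundle$notes <- tibble(
    op_id = op_id,
    note_datetime = op_t0 - 86400 * 7,
    note_title = "Preanesthesia consultation",
    note_text = paste0("Preanesthesia consultation.\nASA: ", asa,
                       "\nMallampati: ", grade_txt, "\n")
  )

  # --- PMSI side ----------------------------------------------------------
  admit <- dplyr::if_else(outpatient | urgent,
                          po_dt(paste0(op_day, " 06:00:00")),
                          po_dt(paste0(op_day - 1, " 10:00:00")))
  discharge <- dplyr::if_else(
    outpatient,
    po_dt(paste0(op_day, " 20:00:00")),
    po_dt(paste0(op_day + sample(2:10, n_ops, replace = TRUE), " 11:00:00"))
  )
  bundle$stays <- tibble(
    stay_id = stay_id, patient_id = op_patient,
    admit_datetime = admit, discharge_datetime = discharge,
    stay_type = ifelse(outpatient, "outpatient", "inpatient"),
    discharge_disposition = ifelse(death, "death", "home")
  )

  # ICU admission follows the PACU passage, after the OR visit has ended
  icu_in <- op_tend + 4200
  icu_out <- pmin(discharge - 3600, icu_in + sample(1:3, n_ops, TRUE) * 86400)
  moves <- bind_rows(
    tibble(stay_id = stay_id[!icu_after], unit_code = "VIS_WARD",
           move_start = admit[!icu_after], move_end = discharge[!icu_after]),
    tibble(stay_id = stay_id[icu_after], unit_code = "VIS_WARD",
           move_start = admit[icu_after], move_end = icu_in[icu_after]),
    tibble(stay_id = stay_id[icu_after], unit_code = "VIS_ICU",
           move_start = icu_in[icu_after], move_end = icu_out[icu_after]),
    tibble(stay_id = stay_id[icu_after], unit_code = "VIS_WARD",
           move_start = icu_out[icu_after], move_end = discharge[icu_after])
  )
  bundle$unit_moves <- moves |> arrange(.data$stay_id, .data$move_start)

  n_diag <- sample(1:4, n_ops, replace = TRUE)
  bundle$diagnoses <- tibble(
    stay_id = rep(stay_id, n_diag),
    icd10_code = sample(ICD10_CODES, sum(n_diag), replace = TRUE),
    diag_datetime = rep(admit, n_diag)
  )
  n_proc <- sample(1:3, n_ops, replace = TRUE)
  bundle$procedures <- tibble(
    stay_id = rep(stay_id, n_proc),
    ccam_code = sample(CCAM_CODES, sum(n_proc), replace = TRUE),
    proc_datetime = rep(op_t0, n_proc)
  )

  # --- ground truth -------------------------------------------------------
  truth$episodes <- if (nrow(episodes) > 0) {
    episodes |>
      mutate(start_datetime = op_t0[match(.data$op_id, .env$op_id)] + .data$start_s,
             end_datetime = op_t0[match(.data$op_id, .env$op_id)] + .data$end_s,
             min_value = NA_real_) |>
      select("op_id", "episode_index", "start_datetime", "end_datetime",
             "min_value")
  } else truth$episodes
  if (nrow(truth$episodes) > 0) {
    # true minimum of the generated MAP samples inside each episode
    map_samples <- bundle$samples |> filter(.data$parameter_code == "MEAS_MAP")
    truth$episodes$min_value <- purrr::pmap_dbl(
      truth$episodes[c("op_id", "start_datetime", "end_datetime")],
      function(op_id, start_datetime, end_datetime) {
        s <- map_samples[map_samples$op_id == op_id, ]
        min(s$value[s$sample_datetime >= start_datetime &
                      s$sample_datetime < end_datetime])
      })
  }

  rescue_t <- truth$rescue
  if (nrow(rescue) > 0) {
    rescue_t <- rescue |>
      transmute(.data$op_id, .data$ingredient_code, .data$admin_datetime,
                within_15 = .data$latency_s < 900)
  }
  truth$rescue <- rescue_t

  first_epi_start <- rep(as.POSIXct(NA, tz = po_tz), n_ops)
  if (nrow(first_epi) > 0) {
    first_epi_start[match(first_epi$op_id, op_id)] <- op_t0[match(first_epi$op_id, op_id)] + first_epi$start_s
  }
  truth$operations <- tibble(
    op_id = op_id, stay_id = stay_id, patient_id = op_patient,
    year = as.numeric(format(op_t0, "%Y")),
    department = bundle$rooms$department[match(room, bundle$rooms$room_id)],
    outpatient = outpatient, urgent = urgent, fast_track = fast_track,
    icu_after = icu_after, death = death,
    early_hypotension = !is.na(first_epi_start) &
      first_epi_start < op_t0 + 1800,
    rescue_within_15 = op_id %in% rescue_t$op_id[rescue_t$within_15],
    asa = asa,
    mallampati = ifelse(malformed, "unknown", mallampati),
    anesthesia_start = op_t0, anesthesia_end = op_tend,
    n_episodes = n_epi
  )
  list(bundle = bundle, truth = truth)
}

#' Write a source bundle to a directory of delimited files
#' @param bundle A `source_bundle`.
#' @param dir Target directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "source_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tbl in names(bundle)) {
    po_write_csv(bundle[[tbl]], file.path(dir, paste0(tbl, ".csv")))
  }
  invisible(dir)
}

#' Read a source bundle written by [write_bundle()]
#' @param dir Bundle directory.
#' @return A `source_bundle`; lossless round trip.
#' @export
read_bundle <- function(dir) {
  proto <- empty_bundle()
  out <- proto
  for (tbl in names(proto)) {
    f <- file.path(dir, paste0(tbl, ".csv"))
    if (!file.exists(f)) {
      po_abort(paste0("missing bundle table file: ", f),
               "periomop_missing_file")
    }
    spec <- lapply(proto[[tbl]], function(col) {
      if (inherits(col, "POSIXct")) {
        readr::col_datetime(format = "%Y-%m-%d %H:%M:%S")
      } else if (is.numeric(col)) readr::col_double()
      else readr::col_character()
    })
    out[[tbl]] <- po_read_csv(f, col_types = do.call(readr::cols, spec))
  }
  out
}
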