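# Builds inst/extdata/concept_registry.csv, the packaged concept registry.
# Per-category composition (counts identified / mapped / locally added):
#   demographics    23 / 23 /   0   (SNOMED)
#   visits           6 /  5 /   1   (Visit; "operating room visit" is local)
#   units           67 / 67 /   0   (UCUM/SNOMED)
#   measurements    45 / 45 /   0   (LOINC/SNOMED)
#   operation_steps 46 / 46 /   0   (SNOMED)
#   drugs          162 /162 /   0   (RxNorm, ingredient level)
#   period          18 /  5 /  13
#   feature        155 /  0 / 155
# Names are synthetic (the real 522-concept list is not public); the codes
# actually consumed by the synthetic generator and ETL are named explicitly,
# fillers pad each category to its published size.

library(tibble)
library(dplyr)

row <- function(code, name, category, vocab, mapped) {
  tibble(source_code = code, source_name = name, category = category,
         target_vocabulary = vocab, mapped = mapped)
}

filler <- function(prefix, from, to, category, vocab, mapped, label) {
  idx <- seq(from, to)
  tibble(source_code = sprintf("%s_%03d", prefix, idx),
         source_name = sprintf("%s %03d (synthetic)", label, idx),
         category = category, target_vocabulary = vocab, mapped = mapped)
}

demographics <- bind_rows(
  row("DEMO_ASA",        "ASA physical status",               "demographics", "SNOMED", TRUE),
  row("DEMO_SEX",        "administrative sex",                "demographics", "SNOMED", TRUE),
  row("DEMO_HEIGHT",     "body height",                       "demographics", "SNOMED", TRUE),
  row("DEMO_WEIGHT",     "body weight",                       "demographics", "SNOMED", TRUE),
  row("DEMO_BMI",        "body mass index",                   "demographics", "SNOMED", TRUE),
  row("DEMO_AGE",        "age on day of procedure",           "demographics", "SNOMED", TRUE),
  row("DEMO_URGENT",     "urgent operation",                  "demographics", "SNOMED", TRUE),
  row("DEMO_MALLAMPATI", "Mallampati classification",         "demographics", "SNOMED", TRUE),
  filler("demo", 9, 23, "demographics", "SNOMED", TRUE, "patient characteristic")
)

visits <- bind_rows(
  row("VIS_INPATIENT",  "inpatient stay",            "visits", "Visit", TRUE),
  row("VIS_OUTPATIENT", "outpatient stay",           "visits", "Visit", TRUE),
  row("VIS_ICU",        "intensive care unit visit", "visits", "Visit", TRUE),
  row("VIS_WARD",       "standard care unit visit",  "visits", "Visit", TRUE),
  row("VIS_EMERGENCY",  "emergency unit visit",      "visits", "Visit", TRUE),
  row("VIS_OR",         "operating room visit",      "visits", NA,      FALSE)
)

units <- bind_rows(
  row("UNIT_MMHG",     "millimeter of mercury",        "units", "UCUM", TRUE),
  row("UNIT_BPM",      "beats per minute",             "units", "UCUM", TRUE),
  row("UNIT_PCT",      "percent",                      "units", "UCUM", TRUE),
  row("UNIT_ML",       "milliliter",                   "units", "UCUM", TRUE),
  row("UNIT_ML_KG",    "milliliter per kilogram",      "units", "UCUM", TRUE),
  row("UNIT_KG",       "kilogram",                     "units", "UCUM", TRUE),
  row("UNIT_CM",       "centimeter",                   "units", "UCUM", TRUE),
  row("UNIT_S",        "second",                       "units", "UCUM", TRUE),
  row("UNIT_MIN",      "minute",                       "units", "UCUM", TRUE),
  row("UNIT_MMHG_MIN", "millimeter of mercury minute", "units", "UCUM", TRUE),
  row("UNIT_COUNT",    "count",                        "units", "UCUM", TRUE),
  row("UNIT_YEAR",     "year",                         "units", "UCUM", TRUE),
  row("UNIT_KG_M2",    "kilogram per square meter",    "units", "UCUM", TRUE),
  filler("unit", 14, 67, "units", "UCUM/SNOMED", TRUE, "unit")
)

measurements <- bind_rows(
  row("MEAS_MAP",   "mean arterial pressure",    "measurements", "LOINC", TRUE),
  row("MEAS_SBP",   "systolic blood pressure",   "measurements", "LOINC", TRUE),
  row("MEAS_HR",    "heart rate",                "measurements", "LOINC", TRUE),
  row("MEAS_SPO2",  "oxygen saturation",         "measurements", "LOINC", TRUE),
  row("MEAS_TVEXP", "expiratory tidal volume",   "measurements", "LOINC", TRUE),
  row("MEAS_RR",    "respiratory rate",          "measurements", "LOINC", TRUE),
  row("MEAS_PPLAT", "plateau pressure",          "measurements", "LOINC", TRUE),
  filler("meas", 8, 45, "measurements", "LOINC/SNOMED", TRUE, "monitored parameter")
)

steps <- bind_rows(
  row("STEP_ANESTH_START", "start of anesthesia",       "operation_steps", "SNOMED", TRUE),
  row("STEP_INDUCTION",    "induction of anesthesia",   "operation_steps", "SNOMED", TRUE),
  row("STEP_INTUBATION",   "tracheal intubation",       "operation_steps", "SNOMED", TRUE),
  row("STEP_INCISION",     "surgical incision",         "operation_steps", "SNOMED", TRUE),
  row("STEP_CLOSURE",      "surgical closure",          "operation_steps", "SNOMED", TRUE),
  row("STEP_ANESTH_END",   "end of anesthesia",         "operation_steps", "SNOMED", TRUE),
  row("STEP_PACU_IN",      "admission to the PACU",     "operation_steps", "SNOMED", TRUE),
  row("STEP_PACU_OUT",     "discharge from the PACU",   "operation_steps", "SNOMED", TRUE),
  filler("step", 9, 46, "operation_steps", "SNOMED", TRUE, "operation step")
)

drugs <- bind_rows(
  row("DRUG_NOREPINEPHRINE", "norepinephrine", "drugs", "RxNorm", TRUE),
  row("DRUG_EPINEPHRINE",    "epinephrine",    "drugs", "RxNorm", TRUE),
  row("DRUG_EPHEDRINE",      "ephedrine",      "drugs", "RxNorm", TRUE),
  row("DRUG_PHENYLEPHRINE",  "phenylephrine",  "drugs", "RxNorm", TRUE),
  row("DRUG_DOBUTAMINE",     "dobutamine",     "drugs", "RxNorm", TRUE),
  row("DRUG_ATROPINE",       "atropine",       "drugs", "RxNorm", TRUE),
  row("DRUG_PROPOFOL",       "propofol",       "drugs", "RxNorm", TRUE),
  row("DRUG_SUFENTANIL",     "sufentanil",     "drugs", "RxNorm", TRUE),
  row("DRUG_ROCURONIUM",     "rocuronium",     "drugs", "RxNorm", TRUE),
  row("DRUG_CEFAZOLIN",      "cefazolin",      "drugs", "RxNorm", TRUE),
  filler("drug", 11, 162, "drugs", "RxNorm", TRUE, "drug ingredient")
)

periods <- bind_rows(
  row("PER_ANESTHESIA", "anesthesia period",          "period", "SNOMED", TRUE),
  row("PER_SURGERY",    "surgery period",             "period", "SNOMED", TRUE),
  row("PER_PACU",       "PACU period",                "period", "SNOMED", TRUE),
  row("PER_PREOP",      "preoperative period",        "period", "SNOMED", TRUE),
  row("PER_POSTOP",     "postoperative period",       "period", "SNOMED", TRUE),
  row("PER_HYPOTENSION",   "hypotension episode (MAP<65 mmHg)",    "period", NA, FALSE),
  row("PER_HYPERTENSION",  "hypertension episode (MAP>120 mmHg)",  "period", NA, FALSE),
  row("PER_BRADYCARDIA",   "bradycardia episode (HR<60 bpm)",      "period", NA, FALSE),
  row("PER_DESATURATION",  "desaturation episode (SpO2<90%)",      "period", NA, FALSE),
  row("PER_POST_INDUCTION_30", "30 minutes following induction",   "period", NA, FALSE),
  row("PER_PRE_INCISION_10",   "10 minutes preceding incision",    "period", NA, FALSE),
  filler("per", 12, 18, "period", NA, FALSE, "period of interest")
)

features <- bind_rows(
  row("FEAT_MEAN",          "mean over period",                   "feature", NA, FALSE),
  row("FEAT_MEDIAN",        "median over period",                 "feature", NA, FALSE),
  row("FEAT_MIN",           "minimum over period",                "feature", NA, FALSE),
  row("FEAT_MAX",           "maximum over period",                "feature", NA, FALSE),
  row("FEAT_RANGE",         "range over period",                  "feature", NA, FALSE),
  row("FEAT_EPISODE_COUNT", "number of threshold episodes",       "feature", NA, FALSE),
  row("FEAT_TIME_BEYOND",   "time spent beyond threshold",        "feature", NA, FALSE),
  row("FEAT_AUC_BEYOND",    "area under/over threshold",          "feature", NA, FALSE),
  row("FEAT_COUNT_MAP_LT65",  "number of episodes MAP<65 mmHg",     "feature", NA, FALSE),
  row("FEAT_TIME_MAP_LT65",   "time with MAP<65 mmHg",              "feature", NA, FALSE),
  row("FEAT_AUC_MAP_LT65",    "area under MAP<65 mmHg",             "feature", NA, FALSE),
  row("FEAT_COUNT_MAP_GT120", "number of episodes MAP>120 mmHg",    "feature", NA, FALSE),
  row("FEAT_TIME_MAP_GT120",  "time with MAP>120 mmHg",             "feature", NA, FALSE),
  row("FEAT_COUNT_HR_LT60",   "number of episodes HR<60 bpm",       "feature", NA, FALSE),
  row("FEAT_TIME_HR_LT60",    "time with HR<60 bpm",                "feature", NA, FALSE),
  row("FEAT_COUNT_SPO2_LT90", "number of episodes SpO2<90%",        "feature", NA, FALSE),
  row("FEAT_TIME_SPO2_LT90",  "time with SpO2<90%",                 "feature", NA, FALSE),
  filler("feat", 18, 155, "feature", NA, FALSE, "computed feature")
)

reg <- bind_rows(demographics, visits, units, measurements, steps, drugs,
                 periods, features)

stopifnot(nrow(reg) == 522, sum(reg$mapped) == 353, sum(!reg$mapped) == 169,
          !anyDuplicated(reg$source_code))

# Deterministic pseudo-standard target ids per vocabulary block; locally
# added concepts take the OHDSI site-local block starting at 2e9, in file
# order.
vocab_base <- c(SNOMED = 4500000, Visit = 9200, UCUM = 8500,
                "UCUM/SNOMED" = 8800, LOINC = 3000000,
                "LOINC/SNOMED" = 3300000, RxNorm = 1100000)
reg <- reg |>
  group_by(target_vocabulary) |>
  mutate(vocab_seq = row_number()) |>
  ungroup() |>
  mutate(
    status = ifelse(mapped, "mapped", "added_local"),
    target_concept_id = ifelse(mapped,
                               vocab_base[target_vocabulary] + vocab_seq,
                               NA_real_)
  )
reg$target_concept_id[!reg$mapped] <- 2e9 + seq_len(sum(!reg$mapped)) - 1
reg$target_vocabulary[!reg$mapped] <- "local"

out <- reg |>
  select(source_code, source_name, category, target_concept_id,
         target_vocabulary, status) |>
  mutate(target_concept_id = sprintf("%.0f", target_concept_id))

readr::write_csv(out, file.path("inst", "extdata", "concept_registry.csv"))
cat("wrote", nrow(out), "rows\n")
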