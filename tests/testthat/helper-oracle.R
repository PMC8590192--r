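# Independent brute-force episode oracle: per-sample labelling followed by
# run-length grouping and explicit run merging. Kept deliberately separate
# from the package's detector so the two can disagree.

oracle_detect <- function(times, values, rule, interval_s = 30) {
  empty <- data.frame(start = numeric(), end = numeric(),
                      duration_s = numeric(), n_samples = integer(),
                      extremum = numeric())
  keep <- !is.na(values) & values >= rule$bounds[1] & values <= rule$bounds[2]
  t <- as.numeric(times)[keep]
  v <- values[keep]
  if (length(t) == 0) return(empty)
  q <- if (rule$comparator == "<") v < rule$threshold else v > rule$threshold
  qi <- which(q)
  if (length(qi) == 0) return(empty)
  span <- interval_s + rule$gap_tolerance_s

  # raw runs: qualifying samples with nothing observed between them and a
  # time difference within span stay together
  brk <- c(FALSE, diff(qi) > 1 | diff(t[qi]) > span)
  runs <- lapply(split(qi, cumsum(brk)), function(m) {
    k <- max(m)
    end <- if (k < length(t) && (t[k + 1] - t[k]) <= span) t[k + 1]
           else t[k] + interval_s
    list(start = t[min(m)], end = end, members = m)
  })

  # merge runs whose separation is within the gap tolerance
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    prev <- merged[[length(merged)]]
    if (r$start - prev$end <= rule$gap_tolerance_s) {
      prev$end <- r$end
      prev$members <- c(prev$members, r$members)
      merged[[length(merged)]] <- prev
    } else {
      merged <- c(merged, list(r))
    }
  }

  out <- do.call(rbind, lapply(merged, function(r) {
    data.frame(start = r$start, end = r$end, duration_s = r$end - r$start,
               n_samples = length(r$members),
               extremum = if (rule$comparator == "<") min(v[r$members])
                          else max(v[r$members]))
  }))
  out[out$duration_s >= rule$min_duration_s, , drop = FALSE]
}

# random series generator for the property suites: uneven spacing (missing
# samples), NA values and artifacts around a threshold of 65
random_series <- function(n = NULL) {
  n <- n %||% sample(5:50, 1)
  steps <- sample(c(30, 30, 30, 60, 90, 120), n - 1, replace = TRUE)
  times <- cumsum(c(0, steps))
  values <- round(rnorm(n, 65, 8), 1)
  art <- runif(n) < 0.03
  values[art] <- sample(c(5, 400), sum(art), replace = TRUE)
  values[runif(n) < 0.05] <- NA
  list(times = times, values = values)
}

random_rule <- function() {
  threshold_rule(
    "MEAS_MAP",
    comparator = sample(c("<", ">"), 1),
    threshold = 65,
    unit = "UNIT_MMHG",
    min_duration_s = sample(c(0, 0, 60, 120), 1),
    gap_tolerance_s = sample(c(0, 0, 30, 60), 1),
    bounds = c(20, 250),
    period_code = "PER_HYPOTENSION"
  )
}

expect_episodes_equal <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  if (nrow(a) > 0) {
    expect_equal(as.numeric(a$start), as.numeric(b$start))
    expect_equal(as.numeric(a$end), as.numeric(b$end))
    expect_equal(a$n_samples, b$n_samples, ignore_attr = TRUE)
    expect_equal(a$extremum, b$extremum, ignore_attr = TRUE)
  }
}
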