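# Fixture builders shared across the test files. All fixtures are built in
# code; nothing is read from disk except CSVs the tests write themselves.

vitals <- c("rr", "hr", "spo2", "sysbp", "temp")

# A single well-formed observation row.
obs_row <- function(pid, t, rr = 16, hr = 80, spo2 = 97, sysbp = 120,
                    temp = 36.5) {
  data.frame(patient_id = pid, time_h = t, rr = rr, hr = hr, spo2 = spo2,
             sysbp = sysbp, temp = temp, stringsAsFactors = FALSE)
}

# A patient with one observation every `every` hours across `days` days;
# vitals vary deterministically with time so nothing is degenerate.
obs_series <- function(pid, days, every = 6) {
  t <- seq(0, days * 24 - 0.5, by = every)
  data.frame(patient_id = pid, time_h = t,
             rr = 16 + 0.3 * sin(t / 5), hr = 80 + cos(t / 7),
             spo2 = 97 + 0.5 * sin(t / 11), sysbp = 120 + 2 * sin(t / 13),
             temp = 36.5 + 0.1 * cos(t / 17), stringsAsFactors = FALSE)
}

# A small labelled cohort: patients with the given stays (days), all normal
# unless listed in `abnormal` (those get an event at the end of their stay).
toy_cohort <- function(stays, abnormal = character(0), every = 6) {
  ids <- names(stays)
  if (is.null(ids)) ids <- sprintf("T%02d", seq_along(stays))
  obs <- do.call(rbind, Map(obs_series, ids, stays, every))
  outc <- data.frame(
    patient_id = ids,
    outcome = ifelse(ids %in% abnormal, "abnormal", "normal"),
    event_time_h = ifelse(ids %in% abnormal, unlist(stays) * 24 - 1,
                          NA_real_),
    stringsAsFactors = FALSE)
  new_cohort(obs, outc)
}

# Small-scale generator settings for fast tests.
small_params <- function(...) {
  synthetic_params(n_normal = 20, n_abnormal = 4, ...)
}

# Random probability vector over n bins.
random_mass <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# Brute-force two-sample KS: evaluate |P - Q| at every pooled point.
ks_brute <- function(x, y) {
  pts <- c(x, y)
  P <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Q <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(P - Q))
}
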