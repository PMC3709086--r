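#' Parameters for the synthetic ward cohort generator
#'
#' The generator emulates the statistical structure of post-operative ward
#' vital signs: each vital sign relaxes exponentially from its admission-day
#' marginal (mean/SD) to its discharge-day marginal over the stay, with a
#' per-patient random offset carrying most of the variance; patients labelled
#' abnormal additionally ramp selected vitals towards extreme targets
#' (tachycardia, bradycardia with hypertension, or tachypnoea) during a
#' window before their adverse event.
#'
#' Defaults encode the study conditions: 154 normal and 17 abnormal patients;
#' admission means/SDs RR 16.7 (2.5) breaths/min, HR 80.6 (12.8) beats/min,
#' SpO2 97.0 (1.3) %, SysBP 115.7 (16.0) mmHg, Temp 36.6 (0.5) C and
#' discharge means/SDs 15.7 (1.0), 81.2 (11.7), 96.3 (1.5), 132.1 (16.6),
#' 36.4 (0.4); stay median 9 days with IQR 5 (quartiles near 7/12), abnormal
#' time-to-event median 5 days with IQR 4; recovery stabilising by about
#' day 4; charting every 1-2 h early in the stay and every 4 h later.
#'
#' @param n_normal,n_abnormal patient counts per outcome group.
#' @param admission_mean,admission_sd,discharge_mean,discharge_sd named
#'   5-vectors (\code{rr, hr, spo2, sysbp, temp}) of day-average marginal
#'   means and SDs in natural units.
#' @param recovery_tau_days exponential recovery time constant (days).
#' @param stay_median_days,stay_iqr_days median and interquartile range of
#'   the normal-group length of stay (days).
#' @param event_median_days,event_iqr_days median and IQR of the
#'   abnormal-group time to first event (days).
#' @param stay_min_days,stay_max_days hard stay bounds (days); draws are
#'   clipped into this range.
#' @param episode_targets named vector of deterioration extremes:
#'   \code{hr_high}, \code{hr_low}, \code{sysbp_high}, \code{rr_high}.
#' @param episode_window_h hours before the event during which the affected
#'   vitals ramp linearly towards their targets.
#' @param obs_interval_early_h charting intervals (hours) drawn uniformly
#'   during the early part of the stay.
#' @param obs_interval_late_h charting interval (hours) for the remainder.
#' @param early_fraction fraction of the stay charted at the early cadence.
#' @param between_patient_rho fraction of each vital's variance attributed to
#'   a stable per-patient offset (the rest is per-observation noise), so the
#'   admission/discharge SDs describe the spread of per-patient day averages.
#' @param mortality probability that an abnormal patient's event is a death
#'   rather than an ICU re-admission; the cohort-level count of deaths is
#'   \code{round(mortality * n_abnormal)}.
#' @param missing_rate probability that any single vital value is masked to
#'   \code{NA} (for exercising the completeness filter); default 0.
#' @return a list of class \code{synthetic_params}.
#' @seealso [simulate_cohort()], [simulate_patient()]
#' @export
synthetic_params <- function(n_normal = 154L,
                             n_abnormal = 17L,
                             admission_mean = c(rr = 16.7, hr = 80.6,
                                                spo2 = 97.0, sysbp = 115.7,
                                                temp = 36.6),
                             admission_sd = c(rr = 2.5, hr = 12.8,
                                              spo2 = 1.3, sysbp = 16.0,
                                              temp = 0.5),
                             discharge_mean = c(rr = 15.7, hr = 81.2,
                                                spo2 = 96.3, sysbp = 132.1,
                                                temp = 36.4),
                             discharge_sd = c(rr = 1.0, hr = 11.7,
                                              spo2 = 1.5, sysbp = 16.6,
                                              temp = 0.4),
                             recovery_tau_days = 1.5,
                             stay_median_days = 9,
                             stay_iqr_days = 5,
                             event_median_days = 5,
                             event_iqr_days = 4,
                             stay_min_days = 4L,
                             stay_max_days = 28L,
                             episode_targets = c(hr_high = 150, hr_low = 45,
                                                 sysbp_high = 190,
                                                 rr_high = 40),
                             episode_window_h = 24,
                             obs_interval_early_h = c(1, 2),
                             obs_interval_late_h = 4,
                             early_fraction = 0.4,
                             between_patient_rho = 0.8,
                             mortality = 6 / 17,
                             missing_rate = 0) {
  p <- list(n_normal = as.integer(n_normal),
            n_abnormal = as.integer(n_abnormal),
            admission_mean = admission_mean[VITALS],
            admission_sd = admission_sd[VITALS],
            discharge_mean = discharge_mean[VITALS],
            discharge_sd = discharge_sd[VITALS],
            recovery_tau_days = recovery_tau_days,
            stay_median_days = stay_median_days,
            stay_iqr_days = stay_iqr_days,
            event_median_days = event_median_days,
            event_iqr_days = event_iqr_days,
            stay_min_days = as.integer(stay_min_days),
            stay_max_days = as.integer(stay_max_days),
            episode_targets = episode_targets,
            episode_window_h = episode_window_h,
            obs_interval_early_h = obs_interval_early_h,
            obs_interval_late_h = obs_interval_late_h,
            early_fraction = early_fraction,
            between_patient_rho = between_patient_rho,
            mortality = mortality,
            missing_rate = missing_rate)
  stopifnot(p$n_normal >= 0, p$n_abnormal >= 0,
            all(p$admission_sd >= 0), all(p$discharge_sd >= 0),
            p$recovery_tau_days > 0,
            p$stay_min_days >= 1, p$stay_min_days <= p$stay_max_days,
            p$between_patient_rho >= 0, p$between_patient_rho <= 1,
            p$mortality >= 0, p$mortality <= 1,
            p$missing_rate >= 0, p$missing_rate < 1)
  class(p) <- "synthetic_params"
  p
}

# Log-normal sdlog such that the distribution with the given median has the
# given IQR: IQR = 2 * median * sinh(z75 * sdlog).
lnorm_sdlog <- function(median, iqr) {
  if (iqr <= 0) return(0)
  asinh(iqr / (2 * median)) / stats::qnorm(0.75)
}

#' Draw lengths of stay (or times to event)
#'
#' Stay lengths are drawn from a log-normal calibrated so its median and IQR
#' match the requested values, rounded to whole days and clipped into
#' \code{[stay_min_days, stay_max_days]}. With \code{type = "event"} the
#' abnormal-group time-to-event median/IQR are used instead.
#'
#' @param params a [synthetic_params()] object.
#' @param n number of draws.
#' @param type \code{"stay"} (normal group) or \code{"event"} (time to first
#'   adverse event for the abnormal group).
#' @return integer vector of days; uses the current RNG stream.
#' @export
sample_length_of_stay <- function(params, n = 1, type = c("stay", "event")) {
  type <- match.arg(type)
  med <- if (type == "stay") params$stay_median_days else
    params$event_median_days
  iqr <- if (type == "stay") params$stay_iqr_days else params$event_iqr_days
  sdlog <- lnorm_sdlog(med, iqr)
  draws <- if (sdlog == 0) rep(med, n) else
    stats::rlnorm(n, meanlog = log(med), sdlog = sdlog)
  as.integer(pmin(pmax(round_half_away(draws), params$stay_min_days),
                  params$stay_max_days))
}

# Exponential recovery weight at time t hours: 1 at admission, -> 0 at
# discharge, time constant recovery_tau_days.
recovery_weight <- function(time_h, tau_days) {
  exp(-time_h / (24 * tau_days))
}

# Charting times for a stay ending at end_h: 1-2 h cadence (uniform choice)
# for the early fraction of the stay, then the late cadence.
charting_times <- function(end_h, params) {
  t <- 0
  out <- numeric(0)
  switch_h <- params$early_fraction * end_h
  while (t < end_h) {
    out <- c(out, t)
    dt <- if (t < switch_h) {
      params$obs_interval_early_h[sample.int(
        length(params$obs_interval_early_h), 1)]
    } else {
      params$obs_interval_late_h
    }
    t <- t + dt
  }
  out
}

#' Simulate one patient's observation series
#'
#' Each vital v at time t has mean
#' \code{discharge_mean_v + (admission_mean_v - discharge_mean_v) * exp(-t / tau)}
#' and an SD interpolating the admission and discharge SDs on the same
#' schedule; the SD is split into a per-patient offset (fraction
#' \code{between_patient_rho} of the variance) plus per-observation Gaussian
#' noise. Abnormal patients are assigned 1-2 deterioration episode types from
#' \{HR-high, HR-low + SysBP-high, RR-high\}; inside \code{episode_window_h}
#' before the event the affected vitals' means ramp linearly towards the
#' episode targets. SpO2 is clipped to at most 100.
#'
#' @param params a [synthetic_params()] object.
#' @param outcome \code{"normal"} or \code{"abnormal"}.
#' @param patient_id identifier for the returned rows.
#' @return list with \code{observations} (data frame), \code{outcome},
#'   \code{event_time_h} (\code{NA} for normal patients) and
#'   \code{episodes} (character vector, empty for normal patients).
#'   Uses the current RNG stream.
#' @export
simulate_patient <- function(params, outcome, patient_id = "P001") {
  if (!outcome %in% c("normal", "abnormal")) {
    stop("unknown outcome label: ", outcome)
  }
  stay_days <- sample_length_of_stay(
    params, 1, type = if (outcome == "normal") "stay" else "event")
  event_time_h <- NA_real_
  episodes <- character(0)
  if (outcome == "abnormal") {
    # event lands in the second half of the final stay day
    event_time_h <- stats::runif(1, (stay_days - 1) * 24 + 12, stay_days * 24)
    n_ep <- sample.int(2, 1)
    episodes <- sample(c("hr_high", "hr_low_bp_high", "rr_high"), n_ep)
  }
  end_h <- if (outcome == "normal") stay_days * 24 else event_time_h
  times <- charting_times(end_h, params)
  n <- length(times)
  w <- recovery_weight(times, params$recovery_tau_days)

  u <- stats::rnorm(length(VITALS))  # stable per-patient offset, unit scale
  names(u) <- VITALS
  rho <- params$between_patient_rho
  obs <- data.frame(patient_id = rep(patient_id, n), time_h = times,
                    stringsAsFactors = FALSE)
  for (v in VITALS) {
    mu <- params$discharge_mean[v] +
      (params$admission_mean[v] - params$discharge_mean[v]) * w
    sdv <- params$discharge_sd[v] +
      (params$admission_sd[v] - params$discharge_sd[v]) * w
    ramp <- rep(0, n)
    tgt <- NULL
    if (outcome == "abnormal" && n > 0) {
      if ("hr_high" %in% episodes && v == "hr") {
        tgt <- params$episode_targets[["hr_high"]]
      }
      if ("hr_low_bp_high" %in% episodes) {
        if (v == "hr") tgt <- params$episode_targets[["hr_low"]]
        if (v == "sysbp") tgt <- params$episode_targets[["sysbp_high"]]
      }
      if ("rr_high" %in% episodes && v == "rr") {
        tgt <- params$episode_targets[["rr_high"]]
      }
      if (!is.null(tgt)) {
        ramp <- pmax(0, pmin(1, (times - (event_time_h -
          params$episode_window_h)) / params$episode_window_h))
        mu <- (1 - ramp) * mu + ramp * tgt
      }
    }
    # the episode overrides the patient's own baseline: the stable offset
    # fades with the ramp so the vital converges to the episode target,
    # while observation noise persists
    x <- mu + sdv * ((1 - ramp) * sqrt(rho) * u[v] +
                       sqrt(1 - rho) * stats::rnorm(n))
    x <- pmax(x, 0.1)
    if (v == "spo2") x <- pmin(x, 100)
    obs[[v]] <- x
  }
  if (params$missing_rate > 0 && n > 0) {
    for (v in VITALS) {
      mask <- stats::runif(n) < params$missing_rate
      obs[[v]][mask] <- NA_real_
    }
  }
  list(observations = obs, outcome = outcome,
       event_time_h = event_time_h, episodes = episodes)
}

#' Generate a synthetic ward cohort
#'
#' Draws \code{n_normal + n_abnormal} patients with [simulate_patient()],
#' labels them and assembles a [new_cohort()]. Among abnormal patients,
#' \code{round(mortality * n_abnormal)} are marked as deaths
#' (\code{event_type = "death"}) and the rest as ICU re-admissions.
#' Bit-for-bit reproducible for a fixed seed.
#'
#' @param params a [synthetic_params()] object.
#' @param seed integer seed.
#' @return a \code{vital_cohort}; the patient table carries an
#'   \code{event_type} column and the generator parameters are attached as
#'   attribute \code{"params"}.
#' @export
simulate_cohort <- function(params = synthetic_params(), seed = 1L) {
  set.seed(as.integer(seed))
  n_total <- params$n_normal + params$n_abnormal
  labels <- rep(c("normal", "abnormal"), c(params$n_normal, params$n_abnormal))
  ids <- sprintf("P%04d", seq_len(n_total))

  n_deaths <- round(params$mortality * params$n_abnormal)
  death_pick <- if (params$n_abnormal > 0) {
    sample.int(params$n_abnormal, n_deaths)
  } else integer(0)

  obs_list <- vector("list", n_total)
  outc <- data.frame(patient_id = ids, outcome = labels,
                     event_time_h = NA_real_,
                     event_type = NA_character_,
                     stringsAsFactors = FALSE)
  abn_i <- 0L
  for (i in seq_len(n_total)) {
    sim <- simulate_patient(params, labels[i], ids[i])
    obs_list[[i]] <- sim$observations
    outc$event_time_h[i] <- sim$event_time_h
    if (labels[i] == "abnormal") {
      abn_i <- abn_i + 1L
      outc$event_type[i] <- if (abn_i %in% death_pick) "death" else
        "icu_readmission"
    }
  }
  obs <- do.call(rbind, obs_list)
  out <- new_cohort(obs, outc)
  attr(out, "params") <- params
  out
}
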