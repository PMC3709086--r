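#' Ward vital-sign cohorts
#'
#' A cohort bundles timestamped vital-sign observations for a set of ward
#' patients with their outcome labels and a running report of the filtering
#' steps applied to them. Observations carry five variables: respiratory rate
#' (\code{rr}, breaths/min), heart rate (\code{hr}, beats/min), oxygen
#' saturation (\code{spo2}, percent), systolic blood pressure (\code{sysbp},
#' mmHg) and tympanic temperature (\code{temp}, degrees C). Time is hours
#' since ward admission; the admission day is day 1.
#'
#' Length of stay is the number of distinct calendar days touched by a
#' patient's observations; for patients labelled \code{"abnormal"} (ICU
#' re-admission or death on the ward) it is instead the number of days from
#' admission to the first adverse event. It is computed when the cohort is
#' constructed and is not recomputed by later filtering, so the completeness
#' and stay filters commute.
#'
#' @param observations data frame with columns \code{patient_id},
#'   \code{time_h} and the five vitals \code{rr, hr, spo2, sysbp, temp}.
#'   Vitals may be \code{NA} (removed later by [drop_incomplete()]);
#'   \code{time_h} must be present and non-negative.
#' @param outcomes data frame with one row per patient: \code{patient_id},
#'   \code{outcome} (\code{"normal"} or \code{"abnormal"}), \code{event_time_h}
#'   (hours since admission of the first ICU re-admission or death;
#'   \code{NA} for normal patients) and optionally \code{event_type}.
#'   If \code{NULL}, all patients are left unlabelled.
#' @param filter_report optional list of filter counts carried over from a
#'   previous stage.
#' @return An object of class \code{vital_cohort}: a list with elements
#'   \code{observations}, \code{patients} (per-patient table including
#'   \code{length_of_stay_days}) and \code{filter_report}.
#' @seealso [read_cohort()], [drop_incomplete()], [filter_by_stay()],
#'   [split_by_outcome()], [simulate_cohort()]
#' @export
new_cohort <- function(observations, outcomes = NULL, filter_report = NULL) {
  req <- c("patient_id", "time_h", VITALS)
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols) > 0) {
    stop("observations lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  obs <- observations[, req]
  obs$patient_id <- as.character(obs$patient_id)
  if (anyNA(obs$time_h)) stop("observation times must not be missing")
  if (any(obs$time_h < 0)) stop("observation times must be non-negative")
  ok <- !is.na(obs$spo2) & (obs$spo2 > 100 | obs$spo2 <= 0)
  if (any(ok)) stop("spo2 values must lie in (0, 100]")
  for (v in c("rr", "hr", "sysbp", "temp")) {
    if (any(!is.na(obs[[v]]) & obs[[v]] <= 0)) {
      stop("non-missing ", v, " values must be strictly positive")
    }
  }
  obs <- obs[order(obs$patient_id, obs$time_h), , drop = FALSE]
  rownames(obs) <- NULL

  ids <- unique(obs$patient_id)
  if (is.null(outcomes)) {
    outcomes <- data.frame(patient_id = ids,
                           outcome = rep(NA_character_, length(ids)),
                           event_time_h = rep(NA_real_, length(ids)),
                           stringsAsFactors = FALSE)
  }
  outcomes$patient_id <- as.character(outcomes$patient_id)
  if (anyDuplicated(outcomes$patient_id)) {
    stop("duplicated patient_id in outcome table")
  }
  if (!"event_time_h" %in% names(outcomes)) outcomes$event_time_h <- NA_real_
  pats <- merge(data.frame(patient_id = ids, stringsAsFactors = FALSE),
                outcomes, by = "patient_id", all.x = TRUE, sort = TRUE)

  bad <- !is.na(pats$outcome) & pats$outcome == "abnormal" &
    is.na(pats$event_time_h)
  if (any(bad)) {
    stop("abnormal patients must have event_time_h: ",
         paste(pats$patient_id[bad], collapse = ", "))
  }

  days_touched <- tapply(day_index(obs$time_h), obs$patient_id,
                         function(d) length(unique(d)))
  pats$length_of_stay_days <- as.integer(days_touched[pats$patient_id])
  abn <- !is.na(pats$outcome) & pats$outcome == "abnormal"
  pats$length_of_stay_days[abn] <- as.integer(day_index(pats$event_time_h[abn]))

  rep0 <- list(n_input_patients = length(ids),
               n_after_completeness = NA_integer_,
               n_after_stay_filter = NA_integer_,
               n_observations_dropped = 0L,
               n_normal = sum(pats$outcome == "normal", na.rm = TRUE),
               n_abnormal = sum(pats$outcome == "abnormal", na.rm = TRUE))
  if (!is.null(filter_report)) rep0[names(filter_report)] <- filter_report

  structure(list(observations = obs, patients = pats, filter_report = rep0),
            class = "vital_cohort")
}

#' @export
print.vital_cohort <- function(x, ...) {
  p <- x$patients
  cat("Vital-sign cohort:", nrow(p), "patients,",
      nrow(x$observations), "observations\n")
  if (any(!is.na(p$outcome))) {
    cat("  outcome: ", sum(p$outcome == "normal", na.rm = TRUE), " normal, ",
        sum(p$outcome == "abnormal", na.rm = TRUE), " abnormal\n", sep = "")
  }
  los <- p$length_of_stay_days
  cat("  length of stay (days): median ", stats::median(los),
      " [range ", min(los), "-", max(los), "]\n", sep = "")
  fr <- x$filter_report
  if (!is.na(fr$n_after_stay_filter) || fr$n_observations_dropped > 0) {
    cat("  filtering: ", fr$n_input_patients, " in",
        if (!is.na(fr$n_after_completeness))
          paste0(" -> ", fr$n_after_completeness, " complete"),
        if (!is.na(fr$n_after_stay_filter))
          paste0(" -> ", fr$n_after_stay_filter, " within stay bounds"),
        "; ", fr$n_observations_dropped, " observations dropped\n", sep = "")
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a \code{vital_cohort}.
#' @return integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

#' Read a cohort from CSV
#'
#' Expects one row per observation with columns
#' \code{patient_id,time_h,hr,rr,spo2,sysbp,temp,outcome,event_time_h}
#' (order free; extra columns ignored; empty string = missing;
#' \code{event_time_h} empty for normal patients). A \code{schema} mapping
#' renames non-standard headers, e.g.
#' \code{c(patient_id = "id", time_h = "hours")}.
#'
#' Cells that fail numeric parsing become \code{NA} and are counted in the
#' returned cohort's \code{filter_report$n_parse_failures}; rows are never
#' silently discarded. Duplicate \code{(patient_id, time_h)} rows trigger a
#' warning but both rows are kept, since repeated charting within the hour is
#' legitimate.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping canonical column names to the
#'   file's header names; only the names that differ need to be given.
#' @return a \code{vital_cohort}.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  canon <- c("patient_id", "time_h", VITALS, "outcome", "event_time_h")
  have <- canon
  names(have) <- canon
  if (!is.null(schema)) have[names(schema)] <- schema
  mandatory <- c("patient_id", "time_h", VITALS)
  miss <- mandatory[!have[mandatory] %in% names(raw)]
  if (length(miss) > 0) {
    stop("schema error: missing column(s) ",
         paste(have[miss], collapse = ", "))
  }

  n_parse <- 0L
  num <- function(col) {
    x <- raw[[have[col]]]
    if (is.null(x)) return(rep(NA_real_, nrow(raw)))
    x[x == ""] <- NA
    v <- suppressWarnings(as.numeric(x))
    n_parse <<- n_parse + sum(is.na(v) & !is.na(x))
    v
  }
  obs <- data.frame(patient_id = raw[[have["patient_id"]]],
                    time_h = num("time_h"), stringsAsFactors = FALSE)
  for (v in VITALS) obs[[v]] <- num(v)
  ev <- num("event_time_h")

  bad_time <- is.na(obs$time_h)
  if (any(bad_time)) {
    warning(sum(bad_time), " row(s) with unparseable time_h removed")
    obs <- obs[!bad_time, , drop = FALSE]
    ev <- ev[!bad_time]
    raw <- raw[!bad_time, , drop = FALSE]
  }
  if (anyDuplicated(obs[, c("patient_id", "time_h")])) {
    warning("duplicate (patient_id, time_h) rows present; keeping both")
  }

  outc <- if (have["outcome"] %in% names(raw)) raw[[have["outcome"]]] else
    rep(NA_character_, nrow(obs))
  outc[outc == ""] <- NA
  known <- is.na(outc) | outc %in% c("normal", "abnormal")
  if (!all(known)) {
    stop("unknown outcome label(s): ",
         paste(unique(outc[!known]), collapse = ", "))
  }
  pick_one <- function(x) if (all(is.na(x))) NA else x[!is.na(x)][1]
  outcomes <- data.frame(
    patient_id = unique(obs$patient_id),
    stringsAsFactors = FALSE)
  outcomes$outcome <- as.character(
    tapply(outc, obs$patient_id, pick_one)[outcomes$patient_id])
  outcomes$event_time_h <- as.numeric(
    tapply(ev, obs$patient_id, pick_one)[outcomes$patient_id])

  out <- new_cohort(obs, outcomes)
  out$filter_report$n_parse_failures <- n_parse
  out
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: one row per observation in the canonical
#' schema, with empty strings for missing values.
#'
#' @param cohort a \code{vital_cohort}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  obs <- cohort$observations
  p <- cohort$patients
  idx <- match(obs$patient_id, p$patient_id)
  out <- data.frame(patient_id = obs$patient_id, time_h = obs$time_h,
                    hr = obs$hr, rr = obs$rr, spo2 = obs$spo2,
                    sysbp = obs$sysbp, temp = obs$temp,
                    outcome = p$outcome[idx],
                    event_time_h = p$event_time_h[idx],
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Remove observations with missing vitals
#'
#' Keeps only observations for which all five vital signs are present; a
#' patient whose observations are all removed is excluded from the cohort.
#' The filter report's \code{n_observations_dropped} and
#' \code{n_after_completeness} counts are updated.
#'
#' @param cohort a \code{vital_cohort}.
#' @return the filtered \code{vital_cohort}.
#' @export
drop_incomplete <- function(cohort) {
  obs <- cohort$observations
  complete <- stats::complete.cases(obs[, VITALS])
  dropped <- sum(!complete)
  obs <- obs[complete, , drop = FALSE]
  keep <- cohort$patients$patient_id %in% unique(obs$patient_id)
  pats <- cohort$patients[keep, , drop = FALSE]
  fr <- cohort$filter_report
  fr$n_observations_dropped <- fr$n_observations_dropped + dropped
  fr$n_after_completeness <- nrow(pats)
  fr$n_normal <- sum(pats$outcome == "normal", na.rm = TRUE)
  fr$n_abnormal <- sum(pats$outcome == "abnormal", na.rm = TRUE)
  out <- cohort
  out$observations <- obs
  out$patients <- pats
  out$filter_report <- fr
  rownames(out$observations) <- NULL
  out
}

#' Filter patients by length of stay
#'
#' Retains patients whose length of stay (time to first event for abnormal
#' patients) lies within \code{[min_days, max_days]}, both bounds inclusive.
#' The defaults are the 10th and 90th percentile bounds used to define the
#' study population.
#'
#' @param cohort a \code{vital_cohort}.
#' @param min_days,max_days inclusive stay bounds in days.
#' @return the filtered \code{vital_cohort}.
#' @export
filter_by_stay <- function(cohort, min_days = 4, max_days = 29) {
  stopifnot(min_days <= max_days)
  p <- cohort$patients
  keep <- p$length_of_stay_days >= min_days & p$length_of_stay_days <= max_days
  pats <- p[keep, , drop = FALSE]
  obs <- cohort$observations[
    cohort$observations$patient_id %in% pats$patient_id, , drop = FALSE]
  fr <- cohort$filter_report
  fr$n_after_stay_filter <- nrow(pats)
  fr$n_normal <- sum(pats$outcome == "normal", na.rm = TRUE)
  fr$n_abnormal <- sum(pats$outcome == "abnormal", na.rm = TRUE)
  out <- cohort
  out$observations <- obs
  out$patients <- pats
  out$filter_report <- fr
  rownames(out$observations) <- NULL
  out
}

#' Split a cohort by outcome label
#'
#' @param cohort a \code{vital_cohort} in which every patient is labelled.
#' @return a list with elements \code{normal} and \code{abnormal}, two
#'   \code{vital_cohort}s whose union is the input.
#' @export
split_by_outcome <- function(cohort) {
  p <- cohort$patients
  if (anyNA(p$outcome)) {
    stop("unlabelled patient(s): ",
         paste(p$patient_id[is.na(p$outcome)], collapse = ", "))
  }
  take <- function(lbl) {
    pats <- p[p$outcome == lbl, , drop = FALSE]
    obs <- cohort$observations[
      cohort$observations$patient_id %in% pats$patient_id, , drop = FALSE]
    out <- cohort
    out$observations <- obs
    out$patients <- pats
    out$filter_report$n_normal <- sum(pats$outcome == "normal")
    out$filter_report$n_abnormal <- sum(pats$outcome == "abnormal")
    rownames(out$observations) <- NULL
    out
  }
  list(normal = take("normal"), abnormal = take("abnormal"))
}

#' Observations for one patient
#' @param cohort a \code{vital_cohort}.
#' @param patient_id patient identifier.
#' @return data frame of that patient's observations, time-ordered.
#' @export
patient_observations <- function(cohort, patient_id) {
  out <- cohort$observations[cohort$observations$patient_id == patient_id, ,
                             drop = FALSE]
  if (nrow(out) == 0) stop("no such patient: ", patient_id)
  rownames(out) <- NULL
  out
}

#' Write the filter report as JSON
#' @param cohort a \code{vital_cohort}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_filter_report <- function(cohort, path) {
  jsonlite::write_json(cohort$filter_report, path,
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
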