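#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the input (a cohort CSV
#' or synthetic-generator parameters), the stay-filter bounds, histogram bin
#' widths, Sammon options, bandwidth neighbour count, threshold multiplier
#' and a single global seed from which each stage's seed is derived, so any
#' stage can be rerun in isolation.
#'
#' @param input path to an observation CSV, or \code{NULL} to simulate.
#' @param synthetic a [synthetic_params()] object (used when \code{input} is
#'   \code{NULL}).
#' @param min_stay_days,max_stay_days stay-filter bounds.
#' @param bin_widths histogram widths per vital for the KL/Bhattacharyya
#'   maps.
#' @param sammon list of options for [sammon_map()] (\code{max_iter},
#'   \code{tol}, \code{magic}, \code{init}); set to \code{NULL} to skip the
#'   embedding stage.
#' @param bandwidth_k neighbour count for [estimate_bandwidth()].
#' @param threshold_multiplier SDs above the mean for the alarm threshold.
#' @param seed global integer seed.
#' @param out_dir optional directory; when given, stage artifacts (cohort
#'   CSV, filter report JSON, distance maps, embedding coordinates, scores)
#'   are written there.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL,
                            synthetic = synthetic_params(),
                            min_stay_days = 4,
                            max_stay_days = 29,
                            bin_widths = default_bin_widths(),
                            sammon = list(max_iter = 200, tol = 1e-6,
                                          magic = 0.3, init = "random"),
                            bandwidth_k = 10L,
                            threshold_multiplier = 3,
                            seed = 1L,
                            out_dir = NULL) {
  structure(list(input = input, synthetic = synthetic,
                 min_stay_days = min_stay_days,
                 max_stay_days = max_stay_days,
                 bin_widths = bin_widths, sammon = sammon,
                 bandwidth_k = as.integer(bandwidth_k),
                 threshold_multiplier = threshold_multiplier,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the end-to-end analysis
#'
#' Stages, in order: ingest (read or simulate a cohort), completeness filter,
#' stay filter, outcome split, distance maps (three metrics on the normal
#' group's G1-G5 subgroups), Sammon embedding of the normal subgroup
#' vectors, model-of-normality fit, group trajectories and the per-patient
#' threshold exceedance table. Identical configuration and seed give an
#' identical bundle.
#'
#' @param config a [pipeline_config()].
#' @return an object of class \code{drift_report}: list with
#'   \code{config_fingerprint}, \code{cohort}, \code{filter_report},
#'   \code{distance_maps}, \code{embedding} (+ \code{embedding_labels}),
#'   \code{model}, \code{trajectory} and \code{exceedance}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 2)
  fp <- config_fingerprint(config[setdiff(names(config), "out_dir")])

  cohort <- if (is.null(config$input)) {
    simulate_cohort(config$synthetic, seed = seeds[1])
  } else {
    read_cohort(config$input)
  }
  cohort <- drop_incomplete(cohort)
  cohort <- filter_by_stay(cohort, config$min_stay_days, config$max_stay_days)
  groups <- split_by_outcome(cohort)

  sg <- subgroup_set(groups$normal)
  maps <- distance_maps(sg, widths = config$bin_widths)

  norm <- fit_normalization(cohort)
  embedding <- NULL
  emb_labels <- NULL
  if (!is.null(config$sammon)) {
    sm <- subgroup_matrix(sg, norm)
    embedding <- do.call(sammon_map,
                         c(list(X = sm$X, seed = seeds[2]), config$sammon))
    emb_labels <- data.frame(patient_id = sm$patient_id,
                             subgroup = sm$subgroup,
                             stringsAsFactors = FALSE)
  }

  model <- fit_normality(cohort, k = config$bandwidth_k,
                         multiplier = config$threshold_multiplier)
  trajectory <- group_trajectory(cohort, model)
  exceedance <- threshold_exceedance(model, cohort)

  bundle <- structure(
    list(config_fingerprint = fp, cohort = cohort,
         filter_report = cohort$filter_report,
         distance_maps = maps, embedding = embedding,
         embedding_labels = emb_labels, model = model,
         trajectory = trajectory, exceedance = exceedance),
    class = "drift_report")

  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

# Serialize the bundle's tabular artifacts as plain text files.
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tag <- function(name) file.path(out_dir, name)
  write_cohort(bundle$cohort, tag("cohort.csv"))
  fr <- bundle$filter_report
  fr$config_fingerprint <- bundle$config_fingerprint
  jsonlite::write_json(fr, tag("filter_report.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  long <- do.call(rbind, lapply(names(bundle$distance_maps), function(m) {
    mat <- bundle$distance_maps[[m]]
    data.frame(metric = m,
               vital = rep(rownames(mat), ncol(mat)),
               comparison = rep(colnames(mat), each = nrow(mat)),
               distance = as.vector(mat))
  }))
  utils::write.csv(format(long, digits = 10), tag("distances.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$embedding)) {
    coords <- data.frame(bundle$embedding_labels,
                         y1 = bundle$embedding$points[, 1],
                         y2 = bundle$embedding$points[, 2])
    utils::write.csv(format(coords, digits = 10), tag("sammon.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(format(as.data.frame(bundle$trajectory), digits = 10),
                   tag("trajectory.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$exceedance, tag("exceedance.csv"),
                   row.names = FALSE, quote = FALSE)
  th <- bundle$model$threshold
  jsonlite::write_json(
    list(n_train = bundle$model$n_train, sigma = bundle$model$sigma,
         mu_z = th$mu_z, sd_z = th$sd_z, k_threshold = th$k_threshold,
         config_fingerprint = bundle$config_fingerprint),
    tag("model.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.drift_report <- function(x, ...) {
  cat("Vital-sign drift analysis (config ", x$config_fingerprint, ")\n",
      sep = "")
  print(x$cohort)
  cat("\nSysBP distances vs G5 (KS / KL_s / Bhat):\n")
  m <- sapply(x$distance_maps, function(d) d["sysbp", ])
  print(round(m, 3))
  if (!is.null(x$embedding)) {
    cat("\n")
    print(x$embedding)
  }
  cat("\n")
  print(x$model)
  det <- x$exceedance[x$exceedance$outcome == "abnormal", ]
  if (nrow(det) > 0) {
    cat(sprintf("\nPre-event threshold crossings: %d of %d abnormal (%.1f%%)\n",
                sum(det$exceeds), nrow(det), 100 * mean(det$exceeds)))
  }
  invisible(x)
}
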