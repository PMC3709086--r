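#' Pre-discharge training set for the model of normality
#'
#' All observations made on each normal patient's last ward day (the
#' discharge day, their most physiologically stable period), z-score
#' normalized. These vectors are the kernel centres of the model.
#'
#' @param normal_cohort a \code{vital_cohort} containing normal patients.
#' @param params a [fit_normalization()] object (fitted on the full cohort,
#'   normal and abnormal together).
#' @return N x 5 matrix of normalized vectors.
#' @export
training_set <- function(normal_cohort, params) {
  obs <- normal_cohort$observations
  if (nrow(obs) == 0) stop("empty cohort")
  rows <- unlist(lapply(split(seq_len(nrow(obs)), obs$patient_id),
                        function(ix) {
    d <- day_index(obs$time_h[ix])
    ix[d == max(d)]
  }), use.names = FALSE)
  normalize_vitals(obs[sort(rows), , drop = FALSE], params)
}

#' Nearest-neighbour kernel bandwidth
#'
#' For each training point, the mean Euclidean distance to its k nearest
#' other points (ties at the k-th distance broken by index order); the
#' kernel width sigma is the grand mean of these per-point averages. With
#' \code{mode = "squared"} the per-point averages use squared distances and
#' sigma is the square root of their grand mean.
#'
#' @param X N x D numeric matrix.
#' @param k neighbour count; reduced to N - 1 with a warning when N <= k.
#' @param mode \code{"distance"} (default) or \code{"squared"}.
#' @return an object of class \code{bandwidth_estimate}: list with
#'   \code{delta} (per-point averages), \code{k}, \code{mode} and
#'   \code{sigma}.
#' @export
estimate_bandwidth <- function(X, k = 10L, mode = c("distance", "squared")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 2) stop("need at least 2 points")
  if (N <= k) {
    k <- N - 1L
    warning("k reduced to ", k, " (only ", N, " points)")
  }
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  delta <- apply(d, 1, function(r) {
    nn <- sort(r, method = "radix")[seq_len(k)]
    if (mode == "squared") mean(nn^2) else mean(nn)
  })
  sigma <- if (mode == "squared") sqrt(mean(delta)) else mean(delta)
  if (sigma <= 0) stop("all points identical: bandwidth is zero")
  structure(list(delta = unname(delta), k = as.integer(k), mode = mode,
                 sigma = sigma),
            class = "bandwidth_estimate")
}

#' @export
print.bandwidth_estimate <- function(x, ...) {
  cat("Nearest-neighbour bandwidth: sigma =", format(x$sigma, digits = 6),
      "(k =", x$k, ", mode =", x$mode, ")\n")
  invisible(x)
}

# log p(x) under an isotropic Gaussian KDE, vectorized over query rows;
# computed with log-sum-exp so extreme queries never underflow to -Inf.
kde_log_density <- function(X_train, sigma, Xq) {
  X_train <- as.matrix(X_train)
  Xq <- matrix(Xq, ncol = ncol(X_train))
  N <- nrow(X_train)
  D <- ncol(X_train)
  const <- -log(N) - (D / 2) * log(2 * pi) - D * log(sigma)
  out <- numeric(nrow(Xq))
  xt2 <- rowSums(X_train^2)
  chunk <- 2000L
  for (s in seq(1, nrow(Xq), by = chunk)) {
    ix <- s:min(s + chunk - 1L, nrow(Xq))
    Q <- Xq[ix, , drop = FALSE]
    d2 <- outer(rowSums(Q^2), xt2, "+") - 2 * Q %*% t(X_train)
    d2[d2 < 0] <- 0
    lw <- -d2 / (2 * sigma^2)
    # row-wise log-sum-exp without an R-level loop
    rmax <- lw[cbind(seq_len(nrow(lw)), max.col(lw, ties.method = "first"))]
    out[ix] <- rmax + log(rowSums(exp(lw - rmax))) + const
  }
  out
}

#' Low-level model-of-normality constructor
#'
#' Wraps a set of kernel centres and a kernel width into a
#' \code{normality_model} without refitting anything; used for models built
#' directly from a matrix (any dimension), e.g. in validation studies.
#' [fit_normality()] is the user-facing fit from a cohort.
#'
#' @param X N x D matrix of kernel centres (model-space units).
#' @param sigma isotropic kernel width, > 0.
#' @param normalization optional [fit_normalization()] object used to map
#'   natural-unit queries into model space.
#' @return an object of class \code{normality_model}.
#' @export
new_normality_model <- function(X, sigma, normalization = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 1, sigma > 0)
  structure(list(X = X, sigma = sigma, dims = ncol(X),
                 n_train = nrow(X), normalization = normalization,
                 bandwidth = NULL, threshold = NULL, call = NULL),
            class = "normality_model")
}

# Map query input (cohort / data frame / matrix / vector, natural or
# model-space units) to a model-space matrix.
query_matrix <- function(model, x, normalized = FALSE) {
  if (inherits(x, "vital_cohort")) x <- x$observations
  if (is.data.frame(x)) x <- as.matrix(x[, VITALS])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!normalized) {
    if (is.null(model$normalization)) {
      stop("model has no normalization parameters; pass normalized = TRUE")
    }
    if (!is.null(colnames(x))) x <- x[, VITALS, drop = FALSE]
    x <- sweep(sweep(x, 2, model$normalization$mu), 2,
               model$normalization$sigma, "/")
  }
  if (ncol(x) != model$dims) {
    stop("query has ", ncol(x), " columns; model expects ", model$dims)
  }
  x
}

#' Kernel density estimate of the likelihood
#'
#' Evaluates the model-of-normality density
#' \deqn{p(x) = \frac{1}{N (2\pi)^{D/2} \sigma^D}
#'   \sum_{i=1}^{N} e^{-\|x - x_i\|^2 / 2\sigma^2}}
#' at one or more query points.
#'
#' @param model a \code{normality_model}.
#' @param x query: vector, matrix, data frame or \code{vital_cohort}.
#' @param normalized set \code{TRUE} if \code{x} is already in model
#'   (normalized) space; otherwise it is normalized with the model's
#'   parameters first.
#' @return numeric vector of densities (positive).
#' @export
kde_likelihood <- function(model, x, normalized = FALSE) {
  exp(kde_log_density(model$X, model$sigma,
                      query_matrix(model, x, normalized)))
}

#' Novelty score
#'
#' \code{z(x) = -log p(x)} under the model of normality, evaluated in the
#' log domain (log-sum-exp) so it stays finite for any finite query. Low
#' scores indicate vital signs compatible with stable pre-discharge
#' physiology; high scores indicate departure from normality.
#'
#' @inheritParams kde_likelihood
#' @return numeric vector of novelty scores, in nats.
#' @export
novelty_score <- function(model, x, normalized = FALSE) {
  -kde_log_density(model$X, model$sigma, query_matrix(model, x, normalized))
}

#' Per-day novelty scores for one patient
#'
#' Averages the per-observation novelty scores within each stay day. For
#' abnormal patients only observations up to the first adverse event are
#' scored.
#'
#' @param model a \code{normality_model}.
#' @param observations one patient's observation data frame.
#' @param event_time_h event time in hours, or \code{NA} for none.
#' @return data frame with \code{day}, \code{z_mean}, \code{n_obs}.
#' @export
daily_novelty <- function(model, observations, event_time_h = NA) {
  if (!is.na(event_time_h)) {
    observations <- observations[observations$time_h <= event_time_h, ,
                                 drop = FALSE]
  }
  if (nrow(observations) == 0) {
    return(data.frame(day = integer(0), z_mean = numeric(0),
                      n_obs = integer(0)))
  }
  z <- novelty_score(model, observations)
  day <- day_index(observations$time_h)
  agg <- tapply(z, day, mean)
  data.frame(day = as.integer(names(agg)), z_mean = as.numeric(agg),
             n_obs = as.integer(table(day)), row.names = NULL)
}

#' Novelty alarm threshold
#'
#' \code{k = mu + multiplier * sd} of the novelty scores of the normal
#' reference group: by default the per-observation scores of every normal
#' patient's observations (\code{unit = "patient"} uses per-patient mean
#' scores instead). The SD is the sample (n - 1) convention.
#'
#' @param model a \code{normality_model}.
#' @param normal_cohort the normal-group \code{vital_cohort}.
#' @param multiplier number of SDs above the mean; default 3.
#' @param unit \code{"observation"} or \code{"patient"}.
#' @return an object of class \code{novelty_threshold}: list with
#'   \code{mu_z}, \code{sd_z}, \code{multiplier}, \code{unit},
#'   \code{k_threshold}.
#' @export
novelty_threshold <- function(model, normal_cohort, multiplier = 3,
                              unit = c("observation", "patient")) {
  unit <- match.arg(unit)
  if (nrow(normal_cohort$observations) == 0) stop("empty cohort")
  z <- novelty_score(model, normal_cohort)
  if (unit == "patient") {
    z <- as.numeric(tapply(z, normal_cohort$observations$patient_id, mean))
  }
  mu <- mean(z)
  sd_z <- if (length(z) > 1) stats::sd(z) else 0
  structure(list(mu_z = mu, sd_z = sd_z, multiplier = multiplier,
                 unit = unit, k_threshold = mu + multiplier * sd_z),
            class = "novelty_threshold")
}

#' @export
print.novelty_threshold <- function(x, ...) {
  cat(sprintf(
    "Novelty threshold k = %.4g (mu = %.4g, sd = %.4g, mu + %g sd, per %s)\n",
    x$k_threshold, x$mu_z, x$sd_z, x$multiplier, x$unit))
  invisible(x)
}

#' Fit the kernel-density model of normality
#'
#' The central fit of the package. From a labelled, filtered cohort it
#' (1) fits z-score normalization over all observations of all patients,
#' (2) collects the normal patients' discharge-day observations as kernel
#' centres, (3) sets the isotropic kernel width by the k-nearest-neighbour
#' rule ([estimate_bandwidth()]), and (4) derives the alarm threshold
#' \code{k = mu + multiplier * sd} from the normal group's novelty scores.
#'
#' @param cohort a labelled \code{vital_cohort} (normal and abnormal
#'   patients together, after completeness and stay filtering).
#' @param k neighbour count for the bandwidth rule.
#' @param multiplier threshold multiplier (SDs above the mean).
#' @param bandwidth_mode passed to [estimate_bandwidth()].
#' @param threshold_unit passed to [novelty_threshold()].
#' @return an object of class \code{normality_model} with elements
#'   \code{X} (training vectors, normalized), \code{sigma}, \code{dims},
#'   \code{n_train}, \code{normalization}, \code{bandwidth},
#'   \code{threshold} and \code{call}.
#' @seealso [novelty_score()], [group_trajectory()],
#'   [threshold_exceedance()]
#' @examples
#' coh <- simulate_cohort(synthetic_params(n_normal = 12, n_abnormal = 2),
#'                        seed = 7)
#' fit <- fit_normality(coh)
#' fit
#' head(predict(fit, coh))
#' @export
fit_normality <- function(cohort, k = 10L, multiplier = 3,
                          bandwidth_mode = c("distance", "squared"),
                          threshold_unit = c("observation", "patient")) {
  bandwidth_mode <- match.arg(bandwidth_mode)
  threshold_unit <- match.arg(threshold_unit)
  groups <- split_by_outcome(cohort)
  if (n_patients(groups$normal) == 0) stop("no normal patients to train on")
  norm <- fit_normalization(cohort)
  X <- training_set(groups$normal, norm)
  bw <- estimate_bandwidth(X, k = k, mode = bandwidth_mode)
  model <- new_normality_model(X, bw$sigma, normalization = norm)
  model$bandwidth <- bw
  model$threshold <- novelty_threshold(model, groups$normal,
                                       multiplier = multiplier,
                                       unit = threshold_unit)
  model$call <- match.call()
  model
}

#' @export
print.normality_model <- function(x, ...) {
  cat("Kernel-density model of normality\n")
  cat("  training vectors:", x$n_train, "in", x$dims, "dimensions\n")
  cat("  kernel width sigma:", format(x$sigma, digits = 6),
      if (!is.null(x$bandwidth))
        paste0("(", x$bandwidth$k, "-NN rule, mode ", x$bandwidth$mode, ")"),
      "\n")
  if (!is.null(x$threshold)) print(x$threshold)
  invisible(x)
}

#' @export
summary.normality_model <- function(object, ...) {
  out <- list(n_train = object$n_train, dims = object$dims,
              sigma = object$sigma,
              k = if (!is.null(object$bandwidth)) object$bandwidth$k,
              threshold = object$threshold)
  class(out) <- "summary.normality_model"
  out
}

#' @export
print.summary.normality_model <- function(x, ...) {
  cat("Model of normality: N =", x$n_train, ", D =", x$dims,
      ", sigma =", format(x$sigma, digits = 6), "\n")
  if (!is.null(x$threshold)) print(x$threshold)
  invisible(x)
}

#' Predict novelty from a fitted model of normality
#'
#' @param object a \code{normality_model}.
#' @param newdata a \code{vital_cohort}, observation data frame, matrix or
#'   single vector (natural units unless \code{normalized = TRUE}).
#' @param type \code{"novelty"} (scores, the default), \code{"likelihood"}
#'   (densities) or \code{"exceeds"} (logical, score above the fitted
#'   threshold).
#' @param normalized passed to [novelty_score()].
#' @param ... unused.
#' @return numeric (or logical) vector, one element per observation row.
#' @export
predict.normality_model <- function(object, newdata,
                                    type = c("novelty", "likelihood",
                                             "exceeds"),
                                    normalized = FALSE, ...) {
  type <- match.arg(type)
  z <- novelty_score(object, newdata, normalized = normalized)
  switch(type,
         novelty = z,
         likelihood = exp(-z),
         exceeds = {
           if (is.null(object$threshold)) stop("model has no threshold")
           z > object$threshold$k_threshold
         })
}

#' Group novelty trajectories
#'
#' Per-day novelty summaries for the normal and abnormal groups: for each
#' patient the per-day mean score (abnormal patients scored only up to their
#' first event), then per group and day the mean across patients and its
#' standard error (SD over patients / sqrt(number of patients contributing
#' that day)). Each group's day axis is truncated at the 75th percentile of
#' its length of stay (time to event for the abnormal group).
#'
#' @param cohort a labelled \code{vital_cohort}.
#' @param model a fitted \code{normality_model}.
#' @return an object of class \code{novelty_trajectory}: a data frame with
#'   \code{group}, \code{day}, \code{mean_z}, \code{se}, \code{n_patients};
#'   per-patient daily scores are attached as attribute
#'   \code{"patient_daily"}.
#' @export
group_trajectory <- function(cohort, model) {
  groups <- split_by_outcome(cohort)
  per_patient <- list()
  rows <- list()
  for (g in names(groups)) {
    co <- groups[[g]]
    if (n_patients(co) == 0) next
    daily <- lapply(co$patients$patient_id, function(pid) {
      ev <- co$patients$event_time_h[co$patients$patient_id == pid]
      d <- daily_novelty(model, patient_observations(co, pid), ev)
      d$patient_id <- pid
      d
    })
    daily <- do.call(rbind, daily)
    daily$group <- g
    per_patient[[g]] <- daily
    cut_day <- floor(stats::quantile(co$patients$length_of_stay_days, 0.75,
                                     names = FALSE))
    daily <- daily[daily$day <= cut_day, , drop = FALSE]
    mean_z <- tapply(daily$z_mean, daily$day, mean)
    n_pat <- tapply(daily$z_mean, daily$day, length)
    sd_z <- tapply(daily$z_mean, daily$day, stats::sd)
    se <- ifelse(n_pat > 1, sd_z / sqrt(n_pat), 0)
    rows[[g]] <- data.frame(group = g, day = as.integer(names(mean_z)),
                            mean_z = as.numeric(mean_z),
                            se = as.numeric(se),
                            n_patients = as.integer(n_pat),
                            row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "patient_daily") <- do.call(rbind, per_patient)
  class(out) <- c("novelty_trajectory", "data.frame")
  out
}

#' Plot group novelty trajectories
#'
#' Group mean novelty score against ward day with one-SE error bars,
#' normal group in blue, abnormal in red.
#'
#' @param x a \code{novelty_trajectory}.
#' @param ... further arguments to [graphics::plot()].
#' @return invisibly, \code{x}.
#' @export
plot.novelty_trajectory <- function(x, ...) {
  cols <- c(normal = "navy", abnormal = "firebrick")
  ylim <- range(x$mean_z - x$se, x$mean_z + x$se)
  graphics::plot(NA, xlim = range(x$day), ylim = ylim,
                 xlab = "day of ward stay", ylab = "mean novelty score z",
                 main = "Group novelty trajectories", ...)
  for (g in unique(x$group)) {
    d <- x[x$group == g, ]
    graphics::lines(d$day, d$mean_z, col = cols[[g]], lwd = 2)
    graphics::points(d$day, d$mean_z, col = cols[[g]], pch = 16)
    graphics::arrows(d$day, d$mean_z - d$se, d$day, d$mean_z + d$se,
                     angle = 90, code = 3, length = 0.03, col = cols[[g]])
  }
  graphics::legend("topright", legend = unique(x$group),
                   col = cols[unique(x$group)], lwd = 2)
  invisible(x)
}

#' Per-patient threshold exceedance
#'
#' For every patient, whether any pre-event daily mean novelty score exceeds
#' the model's alarm threshold, and on which day it first does.
#'
#' @param model a fitted \code{normality_model} with a threshold.
#' @param cohort a labelled \code{vital_cohort}.
#' @return data frame with \code{patient_id}, \code{outcome},
#'   \code{max_daily_z}, \code{first_exceed_day} (\code{NA} if never) and
#'   \code{exceeds}.
#' @export
threshold_exceedance <- function(model, cohort) {
  if (is.null(model$threshold)) stop("model has no threshold")
  k <- model$threshold$k_threshold
  p <- cohort$patients
  res <- lapply(seq_len(nrow(p)), function(i) {
    d <- daily_novelty(model, patient_observations(cohort, p$patient_id[i]),
                       p$event_time_h[i])
    over <- d$day[d$z_mean > k]
    data.frame(patient_id = p$patient_id[i], outcome = p$outcome[i],
               max_daily_z = max(d$z_mean),
               first_exceed_day = if (length(over)) min(over) else NA_integer_,
               exceeds = length(over) > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
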