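#' Per-day average vital-sign vector
#'
#' The arithmetic mean, per variable, of all of a patient's observations on
#' one calendar day of the stay (admission day = day 1), in natural units.
#'
#' @param observations data frame of one patient's observations (as returned
#'   by [patient_observations()]).
#' @param day day index.
#' @return named 5-vector, or \code{NULL} if the day has no observations.
#' @export
daily_average <- function(observations, day) {
  sel <- day_index(observations$time_h) == day
  if (!any(sel)) return(NULL)
  colMeans(observations[sel, VITALS, drop = FALSE])
}

#' Subgroup day indices at stay quantiles
#'
#' Maps a length of stay L to the five day indices at 0, 25, 50, 75 and
#' 100 percent of the stay: \code{d_q = 1 + round(q * (L - 1))} with halves
#' rounded away from zero, so G1 is the admission day and G5 the last day.
#'
#' @param length_of_stay_days integer L, at least 4.
#' @return integer vector of 5 day indices named G1..G5.
#' @export
subgroup_days <- function(length_of_stay_days) {
  L <- length_of_stay_days
  if (L < 4) stop("length of stay must be at least 4 days, got ", L)
  q <- c(0, 0.25, 0.5, 0.75, 1)
  d <- as.integer(1 + round_half_away(q * (L - 1)))
  names(d) <- paste0("G", 1:5)
  d
}

#' Build the G1-G5 daily-average subgroups
#'
#' For each patient, one 5-vector per subgroup: the average of all
#' observations on the day at 0/25/50/75/100 percent of that patient's stay.
#' A patient contributes to a subgroup only if the designated day has at
#' least one observation.
#'
#' @param cohort a \code{vital_cohort} (typically the normal group of a
#'   stay-filtered cohort, so every length of stay is at least 4 days).
#' @return an object of class \code{subgroup_set}: a list of five matrices
#'   \code{G1..G5} (patients x 5 vitals, patient ids as row names).
#' @export
subgroup_set <- function(cohort) {
  groups <- lapply(1:5, function(i) list())
  for (pid in cohort$patients$patient_id) {
    obs <- cohort$observations[cohort$observations$patient_id == pid, ,
                               drop = FALSE]
    L <- cohort$patients$length_of_stay_days[
      cohort$patients$patient_id == pid]
    days <- subgroup_days(L)
    for (g in 1:5) {
      v <- daily_average(obs, days[g])
      if (!is.null(v)) groups[[g]][[pid]] <- v
    }
  }
  out <- lapply(groups, function(g) {
    if (length(g) == 0) {
      matrix(numeric(0), 0, length(VITALS),
             dimnames = list(NULL, VITALS))
    } else {
      do.call(rbind, g)
    }
  })
  names(out) <- paste0("G", 1:5)
  structure(out, class = "subgroup_set")
}

#' @export
print.subgroup_set <- function(x, ...) {
  cat("Daily-average subgroups (patients per subgroup):\n")
  print(vapply(unclass(x), nrow, integer(1)))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' The supremum of the absolute difference between the two empirical CDFs,
#' evaluated directly on the samples (no binning).
#'
#' @param sample_p,sample_q non-empty numeric samples.
#' @return distance in \[0, 1\].
#' @export
ks_distance <- function(sample_p, sample_q) {
  if (length(sample_p) == 0 || length(sample_q) == 0) {
    stop("KS distance needs non-empty samples")
  }
  pts <- sort(unique(c(sample_p, sample_q)))
  P <- stats::ecdf(sample_p)
  Q <- stats::ecdf(sample_q)
  max(abs(P(pts) - Q(pts)))
}

#' Shared histogram bin edges for a pooled pair of samples
#'
#' Fixed-width bins aligned to multiples of \code{width}, spanning the pooled
#' range of both samples, so two samples can be compared on identical bins.
#'
#' @param x,y numeric samples.
#' @param width bin width in the variable's natural units.
#' @return strictly increasing numeric vector of edges.
#' @export
shared_bin_edges <- function(x, y = NULL, width) {
  stopifnot(width > 0)
  pooled <- c(x, y)
  lo <- floor(min(pooled) / width) * width
  hi <- ceiling(max(pooled) / width) * width
  if (hi <= lo) hi <- lo + width
  seq(lo, hi, by = width)
}

#' Discretize a sample onto histogram bins
#'
#' @param x numeric sample.
#' @param edges strictly increasing bin edges (e.g. from
#'   [shared_bin_edges()]); values outside the edges are an error.
#' @return an object of class \code{discrete_distribution}: list with
#'   \code{edges} and \code{mass} (non-negative, summing to 1).
#' @export
discretize <- function(x, edges) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  if (min(x) < edges[1] || max(x) > edges[length(edges)]) {
    stop("sample values fall outside the bin edges")
  }
  counts <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  structure(list(edges = edges, mass = counts / sum(counts)),
            class = "discrete_distribution")
}

# Extract mass vectors from a pair of distributions, enforcing shared
# binning; plain probability vectors are accepted for direct use.
pair_mass <- function(p, q) {
  get1 <- function(d) {
    if (inherits(d, "discrete_distribution")) d else
      list(edges = NULL, mass = as.numeric(d))
  }
  p <- get1(p); q <- get1(q)
  if (!is.null(p$edges) && !is.null(q$edges) &&
      !isTRUE(all.equal(p$edges, q$edges))) {
    stop("distributions must share the same bin edges")
  }
  if (length(p$mass) != length(q$mass)) {
    stop("distributions must have the same number of bins")
  }
  if (abs(sum(p$mass) - 1) > 1e-9 || abs(sum(q$mass) - 1) > 1e-9) {
    stop("masses must each sum to 1")
  }
  list(p = p$mass, q = q$mass)
}

#' Symmetric Kullback-Leibler distance between discrete distributions
#'
#' \code{sum((p - q) * log(p / q))} over shared bins, in nats. The sum is
#' undefined when one distribution has mass where the other has none; by
#' default both distributions receive additive smoothing \code{eps} and are
#' renormalised, keeping the distance finite. With \code{strict = TRUE} such
#' pairs return \code{Inf} (a divergent flag) instead.
#'
#' @param p,q \code{discrete_distribution}s on identical edges (or plain
#'   probability vectors of equal length).
#' @param eps additive smoothing mass per bin.
#' @param strict if \code{TRUE}, no smoothing: divergent pairs give
#'   \code{Inf}.
#' @return non-negative distance in nats (or \code{Inf}).
#' @export
kl_symmetric <- function(p, q, eps = 1e-10, strict = FALSE) {
  m <- pair_mass(p, q)
  p <- m$p; q <- m$q
  if (strict) {
    if (any((p > 0) != (q > 0))) return(Inf)
    on <- p > 0
    return(sum((p[on] - q[on]) * log(p[on] / q[on])))
  }
  p <- (p + eps) / sum(p + eps)
  q <- (q + eps) / sum(q + eps)
  sum((p - q) * log(p / q))
}

#' Bhattacharyya distance between discrete distributions
#'
#' \code{-log(BC)} with overlap coefficient \code{BC = sum(sqrt(p * q))}
#' over shared bins, in nats; 0 iff the distributions agree on every bin,
#' \code{Inf} (divergent flag) when the supports are disjoint.
#'
#' @inheritParams kl_symmetric
#' @return non-negative distance in nats (or \code{Inf}).
#' @export
bhattacharyya <- function(p, q) {
  m <- pair_mass(p, q)
  bc <- sum(sqrt(m$p * m$q))
  if (bc <= 0) return(Inf)
  -log(min(bc, 1))
}

# Default histogram widths per vital, natural units.
default_bin_widths <- function() {
  c(rr = 1, hr = 5, spo2 = 1, sysbp = 5, temp = 0.2)
}

#' Distance map between subgroup distributions
#'
#' Compares the distribution of each vital sign in subgroups G1..G4 against
#' the discharge-day subgroup G5, giving a 5 vitals x 4 comparisons matrix.
#' The KS distance operates on the raw subgroup samples; the symmetric KL and
#' Bhattacharyya distances operate on histograms built on bin edges shared
#' within each comparison.
#'
#' @param subgroups a [subgroup_set()].
#' @param metric \code{"ks"}, \code{"kl"} or \code{"bhat"}.
#' @param widths named vector of histogram bin widths per vital (natural
#'   units); defaults to RR 1 breaths/min, HR 5 beats/min, SpO2 1 \%,
#'   SysBP 5 mmHg, Temp 0.2 C.
#' @param ... passed on to [kl_symmetric()] (e.g. \code{eps},
#'   \code{strict}).
#' @return a \code{distance_map}: 5 x 4 numeric matrix (rows = vitals,
#'   columns = G1..G4 vs G5) with the metric recorded as an attribute.
#' @export
distance_map <- function(subgroups, metric = c("ks", "kl", "bhat"),
                         widths = default_bin_widths(), ...) {
  metric <- match.arg(metric)
  stopifnot(inherits(subgroups, "subgroup_set"))
  if (any(vapply(unclass(subgroups), nrow, integer(1)) < 2)) {
    stop("every subgroup needs at least 2 contributing patients")
  }
  out <- matrix(NA_real_, length(VITALS), 4,
                dimnames = list(VITALS, paste0("G", 1:4)))
  g5 <- subgroups$G5
  for (v in VITALS) {
    for (g in 1:4) {
      a <- subgroups[[g]][, v]
      b <- g5[, v]
      out[v, g] <- switch(metric,
        ks = ks_distance(a, b),
        kl = {
          e <- shared_bin_edges(a, b, widths[[v]])
          kl_symmetric(discretize(a, e), discretize(b, e), ...)
        },
        bhat = {
          e <- shared_bin_edges(a, b, widths[[v]])
          bhattacharyya(discretize(a, e), discretize(b, e))
        })
    }
  }
  structure(out, metric = metric, class = c("distance_map", "matrix"))
}

#' @export
print.distance_map <- function(x, digits = 3, ...) {
  cat("Distribution distances (", attr(x, "metric"),
      "), G_i vs G5:\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Heat-map display of a distance map
#'
#' @param x a \code{distance_map}.
#' @param ... further arguments to [graphics::image()].
#' @return invisibly, \code{x}.
#' @export
plot.distance_map <- function(x, ...) {
  m <- unclass(x)
  graphics::image(1:4, 1:5, t(m[rev(seq_len(nrow(m))), ]),
                  col = grDevices::hcl.colors(24, "Blue-Red"),
                  axes = FALSE, xlab = "subgroup vs G5", ylab = "",
                  main = paste(attr(x, "metric"), "distance"), ...)
  graphics::axis(1, at = 1:4, labels = colnames(m))
  graphics::axis(2, at = 1:5, labels = rev(rownames(m)), las = 1)
  graphics::box()
  invisible(x)
}

#' All three distance maps
#'
#' @inheritParams distance_map
#' @return named list of three \code{distance_map}s (\code{ks}, \code{kl},
#'   \code{bhat}).
#' @export
distance_maps <- function(subgroups, widths = default_bin_widths(), ...) {
  list(ks = distance_map(subgroups, "ks", widths),
       kl = distance_map(subgroups, "kl", widths, ...),
       bhat = distance_map(subgroups, "bhat", widths))
}
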