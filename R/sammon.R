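#' Z-score normalization parameters for a cohort
#'
#' Per-vital mean and (sample) standard deviation over every observation of
#' every patient in the cohort, normal and abnormal together, so that each
#' vital contributes on a comparable dynamic range downstream.
#'
#' @param cohort a \code{vital_cohort} with at least 2 observations.
#' @return an object of class \code{vital_normalization}: list with named
#'   5-vectors \code{mu} and \code{sigma}.
#' @export
fit_normalization <- function(cohort) {
  X <- as.matrix(cohort$observations[, VITALS])
  if (nrow(X) < 2) stop("need at least 2 observations")
  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)
  zero <- sigma <= 0 | !is.finite(sigma)
  if (any(zero)) {
    stop("zero variance in: ", paste(VITALS[zero], collapse = ", "))
  }
  structure(list(mu = mu, sigma = sigma), class = "vital_normalization")
}

#' @export
print.vital_normalization <- function(x, ...) {
  cat("Vital-sign z-score normalization:\n")
  print(rbind(mu = x$mu, sigma = x$sigma))
  invisible(x)
}

#' Apply / invert the z-score transformation
#'
#' \code{normalize_vitals} maps natural units to \code{(x - mu) / sigma};
#' \code{denormalize_vitals} inverts it exactly.
#'
#' @param x named 5-vector, or matrix/data frame with the vital columns.
#' @param params a [fit_normalization()] object.
#' @return object of the same shape in normalized (resp. natural) units.
#' @export
normalize_vitals <- function(x, params) {
  if (is.null(dim(x))) {
    (x[VITALS] - params$mu) / params$sigma
  } else {
    X <- as.matrix(as.data.frame(x)[, VITALS])
    sweep(sweep(X, 2, params$mu), 2, params$sigma, "/")
  }
}

#' @rdname normalize_vitals
#' @export
denormalize_vitals <- function(x, params) {
  if (is.null(dim(x))) {
    x[VITALS] * params$sigma + params$mu
  } else {
    X <- as.matrix(as.data.frame(x)[, VITALS])
    sweep(sweep(X, 2, params$sigma, "*"), 2, params$mu, "+")
  }
}

#' Sammon stress of a configuration
#'
#' The normalized weighted sum of squared discrepancies between input-space
#' pairwise distances d*_ij and map-space distances d_ij:
#' \deqn{E = \frac{1}{\sum_{i<j} d^*_{ij}} \sum_{i<j}
#'   \frac{(d^*_{ij} - d_{ij})^2}{d^*_{ij}}}
#' Pairs of duplicate input points (d*_ij = 0) are skipped in both sums,
#' with a warning, since their term is undefined.
#'
#' @param X n x D matrix of input points (normalized units).
#' @param Y n x 2 matrix of map coordinates.
#' @return non-negative stress; 0 for a perfect embedding.
#' @export
sammon_stress <- function(X, Y) {
  dstar <- as.matrix(stats::dist(X))
  d <- as.matrix(stats::dist(Y))
  up <- upper.tri(dstar)
  ds <- dstar[up]
  dd <- d[up]
  if (any(ds == 0)) {
    warning(sum(ds == 0), " duplicate input pair(s) skipped")
    dd <- dd[ds > 0]
    ds <- ds[ds > 0]
  }
  if (length(ds) == 0) stop("all pairwise input distances are zero")
  sum((ds - dd)^2 / ds) / sum(ds)
}

#' Sammon nonlinear projection to 2-D
#'
#' Embeds n input vectors in the plane by minimising the Sammon stress with
#' the classic diagonal-Newton update (descent step scaled by a "magic
#' factor" of 0.3), backtracking by step halving whenever a proposed update
#' would increase the stress. Image points start at uniform-random locations
#' in \[-1, 1\]^2 (or at the first two principal components with
#' \code{init = "pca"}).
#'
#' @param X n x D numeric matrix (n >= 3), typically z-score normalized
#'   daily-average vectors.
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum number of accepted iterations.
#' @param tol convergence tolerance on the relative stress change.
#' @param magic descent step scale factor.
#' @param init \code{"random"} or \code{"pca"}.
#' @return an object of class \code{sammon_map}: list with \code{points}
#'   (n x 2), \code{stress}, \code{stress_trace} (non-increasing),
#'   \code{n_iterations} and \code{converged}.
#' @export
sammon_map <- function(X, seed = 1L, max_iter = 500L, tol = 1e-7,
                       magic = 0.3, init = c("random", "pca")) {
  init <- match.arg(init)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 points")
  dstar <- as.matrix(stats::dist(X))
  up <- upper.tri(dstar)
  dup <- dstar == 0
  diag(dup) <- FALSE
  if (any(dup[up])) {
    warning(sum(dup[up]), " duplicate input pair(s) skipped in the stress")
  }
  if (all(dstar[up][!dup[up]] == 0) || !any(dstar[up] > 0)) {
    stop("all pairwise input distances are zero")
  }
  csum <- sum(dstar[up][dstar[up] > 0])

  set.seed(as.integer(seed))
  Y <- if (init == "pca") {
    sc <- scale(X, scale = FALSE)
    pc <- svd(sc, nu = 0, nv = 2)
    sc %*% pc$v
  } else {
    matrix(stats::runif(2 * n, -1, 1), n, 2)
  }

  stress_of <- function(Y) {
    d <- as.matrix(stats::dist(Y))
    ds <- dstar[up]; dd <- d[up]
    keep <- ds > 0
    sum((ds[keep] - dd[keep])^2 / ds[keep]) / csum
  }

  E <- stress_of(Y)
  trace <- E
  converged <- FALSE
  it <- 0L
  eps <- 1e-12
  while (it < max_iter) {
    d <- as.matrix(stats::dist(Y))
    d[d < eps] <- eps
    s <- dstar - d
    A <- 1 / (dstar * d)
    A[dup | !is.finite(A)] <- 0
    diag(A) <- 0
    B <- s * A                       # (d* - d) / (d* d)
    G <- A * (1 + s / d) / d         # weight for the squared-coord term
    rB <- rowSums(B)
    rG <- rowSums(G)
    grad <- (-2 / csum) * (rB * Y - B %*% Y)
    Y2 <- Y^2
    hess <- (-2 / csum) *
      (rB - (rG * Y2 - 2 * Y * (G %*% Y) + G %*% Y2))
    step <- magic
    moved <- FALSE
    for (h in 1:20) {
      Ynew <- Y - step * grad / pmax(abs(hess), eps)
      Enew <- stress_of(Ynew)
      if (Enew <= E) {
        moved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!moved) {
      # cannot decrease the stress further at any step size
      converged <- TRUE
      break
    }
    rel <- (E - Enew) / max(E, eps)
    Y <- Ynew
    E <- Enew
    trace <- c(trace, E)
    it <- it + 1L
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(points = Y, stress = E, stress_trace = trace,
                 n_iterations = it, converged = converged),
            class = "sammon_map")
}

#' @export
print.sammon_map <- function(x, ...) {
  cat("Sammon 2-D embedding of", nrow(x$points), "points\n")
  cat("  stress:", format(x$stress, digits = 6),
      "after", x$n_iterations, "iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Scatter display of a Sammon embedding
#'
#' @param x a \code{sammon_map}.
#' @param groups optional factor colouring the points (e.g. subgroup label).
#' @param ... further arguments to [graphics::plot()].
#' @return invisibly, \code{x}.
#' @export
plot.sammon_map <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(x$points, col = col, pch = 16, xlab = "y1", ylab = "y2",
                 main = sprintf("Sammon map (stress %.4g)", x$stress), ...)
  if (!is.null(groups)) {
    lv <- levels(factor(groups))
    graphics::legend("topright", legend = lv, col = seq_along(lv), pch = 16)
  }
  invisible(x)
}

#' Stack subgroup vectors for embedding
#'
#' Collects the per-patient daily-average subgroup vectors (G1..G5) into one
#' matrix in normalized units, with subgroup and patient labels, the input
#' the Sammon projection is applied to.
#'
#' @param subgroups a [subgroup_set()].
#' @param params a [fit_normalization()] object.
#' @return list with \code{X} (n x 5 normalized matrix), \code{subgroup}
#'   and \code{patient_id} label vectors.
#' @export
subgroup_matrix <- function(subgroups, params) {
  Xs <- lapply(names(subgroups), function(g) {
    m <- subgroups[[g]]
    if (nrow(m) == 0) return(NULL)
    list(X = normalize_vitals(m, params),
         subgroup = rep(g, nrow(m)), patient_id = rownames(m))
  })
  Xs <- Filter(Negate(is.null), Xs)
  list(X = do.call(rbind, lapply(Xs, `[[`, "X")),
       subgroup = unlist(lapply(Xs, `[[`, "subgroup")),
       patient_id = unlist(lapply(Xs, `[[`, "patient_id")))
}
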