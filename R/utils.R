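# Internal helpers shared across the package.

# The five vital signs, in canonical column order.
VITALS <- c("rr", "hr", "spo2", "sysbp", "temp")

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; day-percentile arithmetic here
#' needs the "half away from zero" convention so that, e.g., 1.5 -> 2.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector (may contain -Inf).
#' @return \code{log(sum(exp(x)))} computed without overflow/underflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive per-stage seeds from one global seed, so stages can be rerun in
# isolation. Deterministic and independent of the caller's RNG state.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Small FNV-1a style fingerprint of an R object (via its deparsed form),
# used to tag pipeline outputs with the configuration that produced them.
config_fingerprint <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Day index of an observation time in hours since admission; admission day
# is day 1, each subsequent calendar day adds one.
day_index <- function(time_h) {
  floor(time_h / 24) + 1L
}
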