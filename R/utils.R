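#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so library functions never disturb user-level streams.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# upper-triangle values of a square matrix, by column (stable order)
upper_tri_values <- function(m) m[upper.tri(m)]

#' Exponential moving average
#'
#' First-order recursive smoother `y[n] = a*x[n] + (1-a)*y[n-1]` with
#' `a = 1 - exp(-1/(tau*fs))`, initialized at the first sample.
#'
#' @param x numeric vector.
#' @param tau time constant in seconds (> 0).
#' @param fs sampling rate in Hz.
#' @return Smoothed numeric vector of the same length.
#' @keywords internal
ema <- function(x, tau, fs) {
  stopifnot(tau > 0, fs > 0)
  a <- 1 - exp(-1 / (tau * fs))
  as.numeric(stats::filter(a * x, 1 - a, method = "recursive", init = x[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
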