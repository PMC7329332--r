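#' Zero-phase band-stop filter
#'
#' Forward-backward (zero-phase) Butterworth band-stop filtering, the tool
#' used to selectively abolish slow-wave frequency content before
#' cross-correlation. Works on a [calcium_trace()] (filters the signal) or a
#' [roi_timeseries()] (filters every ROI row at `fs = 1/dt`).
#'
#' @param x a `calcium_trace` or `roi_ts` object.
#' @param f_low,f_high stop-band edges in Hz, `0 < f_low < f_high < fs/2`.
#' @param order Butterworth design order per pass (default 2; the
#'   forward-backward pass doubles the effective order to 4).
#' @return Object of the same class, filtered.
#' @export
bandstop_filter <- function(x, f_low, f_high, order = 2) {
  UseMethod("bandstop_filter")
}

bandstop_core <- function(sig, fs, f_low, f_high, order) {
  if (!(f_low > 0 && f_low < f_high && f_high < fs / 2)) {
    stop(sprintf("stop band [%g, %g] Hz must lie inside (0, fs/2 = %g) Hz",
                 f_low, f_high, fs / 2))
  }
  bf <- signal::butter(order, c(f_low, f_high) / (fs / 2), type = "stop")
  signal::filtfilt(bf, sig)
}

#' @export
bandstop_filter.calcium_trace <- function(x, f_low, f_high, order = 2) {
  out <- calcium_trace(bandstop_core(x$signal, x$fs, f_low, f_high, order),
                       x$fs, x$site_position)
  attr(out, "ground_truth") <- attr(x, "ground_truth")
  out
}

#' @export
bandstop_filter.roi_ts <- function(x, f_low, f_high, order = 2) {
  fs <- 1 / x$dt
  data <- t(apply(x$data, 1, bandstop_core, fs = fs, f_low = f_low,
                  f_high = f_high, order = order))
  roi_timeseries(data, x$dt, x$roi_labels, x$centroids, x$nuisance)
}

#' Peak of the normalized cross-correlation between two traces
#'
#' Both signals are mean-subtracted and scaled to unit variance; the global
#' maximum of the cross-correlation within `+/- max_lag` is returned together
#' with its lag. A positive lag means `b` lags `a` (the wave arrives at site
#' b later).
#'
#' @param a,b [calcium_trace()] objects with equal sampling rates; unequal
#'   lengths are truncated to the common length with a message.
#' @param max_lag maximum lag to search, in seconds.
#' @return List with `peak_r` and `lag` (seconds).
#' @export
xcorr_peak <- function(a, b, max_lag = 1) {
  if (a$fs != b$fs) stop("sampling rates differ")
  n <- min(length(a$signal), length(b$signal))
  if (length(a$signal) != length(b$signal)) {
    message(sprintf("truncating to common length %d", n))
  }
  xa <- a$signal[seq_len(n)]
  xb <- b$signal[seq_len(n)]
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
    stop("zero-variance input")
  }
  lag_n <- round(max_lag * a$fs)
  cc <- stats::ccf(xa, xb, lag.max = lag_n, plot = FALSE, demean = TRUE)
  vals <- as.numeric(cc$acf)
  lags <- as.numeric(cc$lag)
  i <- which.max(vals)
  # ccf reports cor(a[t+k], b[t]); peak at k = -d when b lags a by d
  list(peak_r = vals[i], lag = -lags[i] / a$fs)
}

#' Propagation speed of a travelling wave
#'
#' @param lag positive delay in seconds (site b behind site a).
#' @param separation inter-site distance in mm.
#' @return Speed in mm/s (`separation / lag`).
#' @export
propagation_speed <- function(lag, separation) {
  if (lag <= 0) stop("no resolvable propagation direction (lag <= 0)")
  separation / lag
}
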