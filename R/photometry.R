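#' Halve the sampling rate by averaging adjacent sample pairs
#'
#' Mirrors the acquisition pipeline's 2 kHz to 1 kHz reduction: output sample
#' k is the mean of input samples 2k-1 and 2k. A trailing odd sample is
#' dropped with a message.
#'
#' @param trace a [calcium_trace()].
#' @return A [calcium_trace()] at half the sampling rate.
#' @export
downsample_mean2 <- function(trace) {
  x <- trace$signal
  if (length(x) %% 2 == 1) {
    message("odd-length signal: dropping the trailing sample")
    x <- x[-length(x)]
  }
  y <- (x[seq(1, length(x), by = 2)] + x[seq(2, length(x), by = 2)]) / 2
  out <- calcium_trace(y, trace$fs / 2, trace$site_position)
  attr(out, "ground_truth") <- attr(trace, "ground_truth")
  out
}

#' Baseline-correct a fluorescence trace with shifted quantile windows
#'
#' Estimates the slow baseline as the 20th percentile of the signal within
#' shifted windows of `window_samples` points (half-window steps), cubic-
#' spline interpolates the per-window anchors across window centers, and
#' subtracts the result. Low-quantile anchoring keeps transient events out of
#' the baseline, so slow drifts are removed while event peaks are preserved.
#'
#' @param trace a [calcium_trace()].
#' @param window_samples window width in samples (default 2500).
#' @param anchor_quantile quantile used as the per-window baseline anchor.
#' @return A baseline-corrected [calcium_trace()]; the removed baseline is
#'   attached as attribute `baseline`.
#' @export
correct_baseline <- function(trace, window_samples = 2500,
                             anchor_quantile = 0.2) {
  x <- trace$signal
  n <- length(x)
  if (window_samples >= n) {
    stop("window_samples must be smaller than the signal length")
  }
  step <- max(1, floor(window_samples / 2))
  starts <- unique(c(seq(1, n - window_samples + 1, by = step),
                     n - window_samples + 1))
  centers <- starts + (window_samples - 1) / 2
  anchors <- vapply(starts, function(s) {
    stats::quantile(x[s:(s + window_samples - 1)], anchor_quantile,
                    names = FALSE)
  }, numeric(1))
  baseline <- if (length(starts) < 4) {
    stats::approx(centers, anchors, xout = seq_len(n), rule = 2)$y
  } else {
    stats::spline(centers, anchors, xout = seq_len(n), method = "natural")$y
  }
  out <- calcium_trace(x - baseline, trace$fs, trace$site_position)
  attr(out, "ground_truth") <- attr(trace, "ground_truth")
  attr(out, "baseline") <- baseline
  out
}

#' Convert a trace to dF/F
#'
#' `dF/F = (signal - f0) / f0`. Reported dF/F values leave f0 unspecified;
#' by default f0 is the 10th percentile of the (baseline-corrected) signal,
#' and any explicit positive value can be supplied instead.
#'
#' @param trace a [calcium_trace()].
#' @param f0 either a positive number or `NULL` to use
#'   `quantile(signal, f0_quantile)`.
#' @param f0_quantile quantile used when `f0` is `NULL`.
#' @return A [calcium_trace()] in dF/F units.
#' @export
compute_dff <- function(trace, f0 = NULL, f0_quantile = 0.1) {
  if (is.null(f0)) {
    f0 <- stats::quantile(trace$signal, f0_quantile, names = FALSE)
  }
  if (f0 <= 0) stop("f0 must be positive")
  out <- calcium_trace((trace$signal - f0) / f0, trace$fs,
                       trace$site_position)
  attr(out, "ground_truth") <- attr(trace, "ground_truth")
  out
}

#' Detection parameters for slow calcium waves
#'
#' @param onset_fraction threshold as a fraction of the envelope's robust
#'   amplitude scale (99th percentile minus median); onset when the envelope
#'   exceeds it (default 0.70).
#' @param termination_fraction termination when the envelope drops below
#'   this fraction of the threshold value (default 0.50).
#' @param merge_gap events separated by less than this many seconds are one
#'   wave (default 0.5).
#' @param min_duration events shorter than this many seconds are discarded
#'   (default 0.3).
#' @param cum_intensity_cutoff events whose signal peak does not reach this
#'   quantile of the amplitude histogram are discarded (default 0.90).
#' @param ema_fast_tau,ema_slow_tau time constants (s) of the fast and slow
#'   exponential moving averages whose difference forms the detection
#'   envelope.
#' @return A `detection_params` list.
#' @export
detection_params <- function(onset_fraction = 0.70,
                             termination_fraction = 0.50,
                             merge_gap = 0.5, min_duration = 0.3,
                             cum_intensity_cutoff = 0.90,
                             ema_fast_tau = 0.1, ema_slow_tau = 2) {
  stopifnot(termination_fraction > 0,
            termination_fraction < onset_fraction,
            onset_fraction <= 1,
            merge_gap > 0, min_duration > 0,
            cum_intensity_cutoff > 0, cum_intensity_cutoff < 1,
            ema_fast_tau > 0, ema_slow_tau > ema_fast_tau)
  structure(list(onset_fraction = onset_fraction,
                 termination_fraction = termination_fraction,
                 merge_gap = merge_gap, min_duration = min_duration,
                 cum_intensity_cutoff = cum_intensity_cutoff,
                 ema_fast_tau = ema_fast_tau, ema_slow_tau = ema_slow_tau),
            class = "detection_params")
}

#' Detect slow calcium waves (down-up transitions) with EMA filters
#'
#' The detection envelope is the difference between a fast and a slow
#' exponential moving average of the (baseline-corrected) signal. The
#' dynamic threshold is `onset_fraction` times a robust amplitude scale
#' (99th percentile minus median of the envelope); an event starts where the
#' envelope crosses the threshold and ends where it drops below
#' `termination_fraction` of the threshold value. Post-processing applies, in
#' this exact order: (1) merge events separated by less than `merge_gap`;
#' (2) discard events shorter than `min_duration`; (3) discard events whose
#' signal peak does not reach the `cum_intensity_cutoff` quantile of the
#' signal's amplitude histogram.
#'
#' @param trace a baseline-corrected [calcium_trace()].
#' @param params a [detection_params()] list.
#' @return A [sw_events()] list (empty for constant signals).
#' @export
detect_slow_waves <- function(trace, params = detection_params()) {
  x <- trace$signal
  fs <- trace$fs
  env <- ema(x, params$ema_fast_tau, fs) - ema(x, params$ema_slow_tau, fs)
  env <- env - stats::median(env)
  scale_amp <- stats::quantile(env, 0.99, names = FALSE)
  if (!is.finite(scale_amp) || scale_amp <= 0) {
    return(sw_events(numeric(0), numeric(0), numeric(0), fs))
  }
  thr <- params$onset_fraction * scale_amp
  term <- params$termination_fraction * thr

  # candidate segments: maximal runs above the termination level that
  # contain at least one threshold crossing; onset at the first
  # above-threshold sample, offset at the segment end
  above_term <- env >= term
  r <- rle(above_term)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- which(r$values)
  onset_i <- integer(0)
  offset_i <- integer(0)
  for (s in seg) {
    i0 <- starts[s]
    i1 <- ends[s]
    hit <- which(env[i0:i1] >= thr)
    if (length(hit)) {
      onset_i <- c(onset_i, i0 + hit[1] - 1)
      offset_i <- c(offset_i, i1)
    }
  }
  if (!length(onset_i)) {
    return(sw_events(numeric(0), numeric(0), numeric(0), fs))
  }
  onsets <- (onset_i - 1) / fs
  offsets <- offset_i / fs

  # rule 1: merge waves separated by less than merge_gap
  if (length(onsets) > 1) {
    keep_on <- onsets[1]
    keep_off <- offsets[1]
    for (k in 2:length(onsets)) {
      if (onsets[k] - keep_off[length(keep_off)] < params$merge_gap) {
        keep_off[length(keep_off)] <- offsets[k]
      } else {
        keep_on <- c(keep_on, onsets[k])
        keep_off <- c(keep_off, offsets[k])
      }
    }
    onsets <- keep_on
    offsets <- keep_off
  }
  # rule 2: discard waves shorter than min_duration
  ok <- (offsets - onsets) >= params$min_duration
  onsets <- onsets[ok]
  offsets <- offsets[ok]
  # rule 3: discard waves not reaching the amplitude-histogram cutoff
  if (length(onsets)) {
    cutoff <- stats::quantile(x, params$cum_intensity_cutoff, names = FALSE)
    peaks <- vapply(seq_along(onsets), function(k) {
      max(x[(floor(onsets[k] * fs) + 1):min(length(x),
                                            ceiling(offsets[k] * fs))])
    }, numeric(1))
    ok <- peaks >= cutoff
    onsets <- onsets[ok]
    offsets <- offsets[ok]
    peaks <- peaks[ok]
  } else {
    peaks <- numeric(0)
  }
  sw_events(onsets, offsets, peaks, fs)
}

#' Count transitions in tiled analysis windows
#'
#' Windows of `window_length` seconds tile the recording with `gap` seconds
#' between them (window k covers `[k*(window_length+gap),
#' k*(window_length+gap) + window_length)`, half-open). An event is counted
#' in the window containing its onset.
#'
#' @param events a [sw_events()] list.
#' @param window_length window length in seconds (default 180, i.e. 3 min).
#' @param gap gap between windows in seconds (default 60).
#' @param total_duration recording length in seconds.
#' @return Integer vector of counts with attribute `window_starts` (s).
#' @export
count_transitions <- function(events, window_length = 180, gap = 60,
                              total_duration) {
  stopifnot(window_length + gap <= total_duration)
  n_win <- floor((total_duration - window_length) / (window_length + gap)) + 1
  starts <- (seq_len(n_win) - 1) * (window_length + gap)
  counts <- vapply(starts, function(s) {
    sum(events$onsets >= s & events$onsets < s + window_length)
  }, numeric(1))
  structure(as.integer(counts), window_starts = starts)
}

#' Event-triggered average waveform
#'
#' Averages onset-aligned snippets `[-pre_window, +post_window]` around each
#' event; events too close to the trace edges are skipped with a message.
#'
#' @param trace a [calcium_trace()].
#' @param events a [sw_events()] list.
#' @param pre_window,post_window margins in seconds.
#' @return List with `t` (seconds relative to onset), `mean` (the average
#'   waveform) and `n_events` used.
#' @export
event_triggered_average <- function(trace, events, pre_window = 1,
                                    post_window = 3) {
  x <- trace$signal
  fs <- trace$fs
  pre_n <- round(pre_window * fs)
  post_n <- round(post_window * fs)
  idx <- round(events$onsets * fs) + 1
  usable <- idx - pre_n >= 1 & idx + post_n <= length(x)
  if (sum(!usable) > 0) {
    message(sprintf("skipping %d event(s) too close to the trace edges",
                    sum(!usable)))
  }
  idx <- idx[usable]
  if (!length(idx)) stop("no usable events for the triggered average")
  snips <- vapply(idx, function(i) x[(i - pre_n):(i + post_n)],
                  numeric(pre_n + post_n + 1))
  list(t = (seq(-pre_n, post_n)) / fs,
       mean = rowMeans(snips),
       n_events = length(idx))
}
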