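#' Event train of down-up transitions
#'
#' A sorted, non-overlapping set of events (onset + duration) inside
#' `[0, total_duration]`. This is the ground-truth substrate for both the
#' synthetic calcium traces and the slow-wave BOLD generator.
#'
#' @param onsets event onset times in seconds, strictly increasing.
#' @param durations event durations in seconds, all > 0.
#' @param total_duration recording length in seconds.
#' @return An object of class `event_train` with fields `onsets`, `durations`,
#'   `total_duration`.
#' @export
event_train <- function(onsets, durations, total_duration) {
  stopifnot(length(onsets) == length(durations), total_duration > 0)
  if (length(onsets)) {
    stopifnot(all(durations > 0), all(onsets >= 0),
              all(onsets + durations <= total_duration + 1e-9))
    if (is.unsorted(onsets, strictly = TRUE)) {
      stop("event onsets must be strictly increasing")
    }
    if (any(diff(onsets) < durations[-length(onsets)] - 1e-9)) {
      stop("events must not overlap")
    }
  }
  structure(list(onsets = as.numeric(onsets),
                 durations = as.numeric(durations),
                 total_duration = total_duration),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events over %.1f s (rate %.3f /s)\n",
              length(x$onsets), x$total_duration,
              length(x$onsets) / x$total_duration))
  invisible(x)
}

#' ROI-by-time BOLD-like time-series set
#'
#' @param data ROI-by-time numeric matrix (signal units arbitrary).
#' @param dt sampling interval in seconds (the BOLD TR), > 0.
#' @param roi_labels character labels, one per ROI.
#' @param centroids numeric n_roi-by-3 matrix of ROI centroids in mm.
#' @param nuisance named list of nuisance regressors (each of length
#'   `ncol(data)`), e.g. breathing or ventricle/white-matter means.
#' @return An object of class `roi_ts`.
#' @export
roi_timeseries <- function(data, dt, roi_labels = NULL, centroids = NULL,
                           nuisance = list()) {
  data <- as.matrix(data)
  stopifnot(dt > 0, is.numeric(data))
  n_roi <- nrow(data)
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%03d", seq_len(n_roi))
  stopifnot(length(roi_labels) == n_roi)
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    stopifnot(nrow(centroids) == n_roi, ncol(centroids) == 3)
  }
  stopifnot(is.list(nuisance))
  for (nm in names(nuisance)) {
    if (length(nuisance[[nm]]) != ncol(data)) {
      stop(sprintf("nuisance regressor '%s' has %d samples, data has %d",
                   nm, length(nuisance[[nm]]), ncol(data)))
    }
  }
  rownames(data) <- roi_labels
  structure(list(data = data, dt = dt, roi_labels = roi_labels,
                 centroids = centroids, nuisance = nuisance),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d ROIs x %d timepoints, dt = %g s (%.1f min)\n",
              nrow(x$data), ncol(x$data), x$dt,
              ncol(x$data) * x$dt / 60))
  if (length(x$nuisance)) {
    cat("  nuisance:", paste(names(x$nuisance), collapse = ", "), "\n")
  }
  invisible(x)
}

# time (s) of each BOLD sample, first sample at t = 0
roi_ts_times <- function(ts) (seq_len(ncol(ts$data)) - 1) * ts$dt

#' Restrict an ROI time-series set to a time window
#'
#' Keeps samples with time in the half-open interval `[start, end)`;
#' nuisance regressors are sliced alongside.
#'
#' @param ts a [roi_timeseries()] object.
#' @param start,end window bounds in seconds.
#' @return A `roi_ts` object covering the window.
#' @export
roi_ts_window <- function(ts, start, end) {
  t <- roi_ts_times(ts)
  keep <- t >= start - 1e-9 & t < end - 1e-9
  if (!any(keep)) stop("window contains no samples")
  roi_timeseries(ts$data[, keep, drop = FALSE], ts$dt, ts$roi_labels,
                 ts$centroids, lapply(ts$nuisance, function(v) v[keep]))
}

#' Fiber-photometry calcium trace
#'
#' @param signal numeric fluorescence signal (a.u. or dF/F); must be finite.
#' @param fs sampling rate in Hz, > 0.
#' @param site_position optional 3-vector, recording-site position in mm.
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(signal, fs, site_position = NULL) {
  stopifnot(fs > 0, is.numeric(signal))
  if (!all(is.finite(signal))) stop("calcium signal must be finite everywhere")
  structure(list(signal = as.numeric(signal), fs = fs,
                 site_position = site_position),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %d samples at %g Hz (%.1f s)\n",
              length(x$signal), x$fs, length(x$signal) / x$fs))
  invisible(x)
}

#' Detected slow-wave (down-up transition) events
#'
#' @param onsets,offsets event bounds in seconds; onsets strictly increasing,
#'   `offsets[k] > onsets[k]` and `offsets[k] <= onsets[k+1]`.
#' @param peak_amplitudes per-event peak of the source signal.
#' @param source_fs sampling rate of the trace the events came from (Hz).
#' @return An object of class `sw_events`.
#' @export
sw_events <- function(onsets, offsets, peak_amplitudes, source_fs) {
  stopifnot(length(onsets) == length(offsets),
            length(onsets) == length(peak_amplitudes))
  if (length(onsets)) {
    if (is.unsorted(onsets, strictly = TRUE)) {
      stop("event onsets must be strictly increasing")
    }
    stopifnot(all(offsets > onsets))
    if (length(onsets) > 1 &&
        any(offsets[-length(offsets)] > onsets[-1] + 1e-9)) {
      stop("events must not overlap")
    }
  }
  structure(list(onsets = as.numeric(onsets), offsets = as.numeric(offsets),
                 peak_amplitudes = as.numeric(peak_amplitudes),
                 source_fs = source_fs),
            class = "sw_events")
}

#' @export
print.sw_events <- function(x, ...) {
  cat(sprintf("<sw_events> %d events", length(x$onsets)))
  if (length(x$onsets)) {
    cat(sprintf(", mean duration %.2f s", mean(x$offsets - x$onsets)))
  }
  cat("\n")
  invisible(x)
}
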