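#' Write / read an ROI time-series set as TSV + JSON sidecar
#'
#' The TSV holds timepoints in rows and ROIs in columns (header = ROI
#' labels); the sidecar JSON carries `dt`, `centroids` and the nuisance
#' regressors. The round trip is lossless for values and metadata.
#'
#' @param ts a [roi_timeseries()].
#' @param path TSV file path.
#' @param sidecar_path JSON sidecar path; default replaces the extension
#'   with `.json`.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path,
                                 sidecar_path = sub("\\.[^.]+$", ".json",
                                                    path)) {
  df <- as.data.frame(t(ts$data))
  names(df) <- ts$roi_labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  side <- list(dt = ts$dt, roi_labels = ts$roi_labels,
               centroids = ts$centroids, nuisance = ts$nuisance)
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_timeseries
#' @export
read_roi_timeseries <- function(path,
                                sidecar_path = sub("\\.[^.]+$", ".json",
                                                   path)) {
  df <- utils::read.delim(path, check.names = FALSE)
  bad <- names(df)[vapply(df, function(col) any(is.na(col)) ||
                            !is.numeric(col), logical(1))]
  if (length(bad)) {
    stop("non-numeric or NA-containing column(s): ",
         paste(bad, collapse = ", "))
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(side$dt)) stop("sidecar is missing dt")
  if (!identical(as.character(side$roi_labels), names(df))) {
    off <- c(setdiff(side$roi_labels, names(df)),
             setdiff(names(df), side$roi_labels))
    stop("TSV header and sidecar ROI labels disagree: ",
         paste(off, collapse = ", "))
  }
  cent <- if (!is.null(side$centroids)) as.matrix(side$centroids) else NULL
  nuis <- lapply(side$nuisance %||% list(), as.numeric)
  roi_timeseries(t(as.matrix(df)), side$dt, names(df), cent, nuis)
}

#' Write / read a calcium trace as CSV (`time_s`, `signal`)
#'
#' @param trace a [calcium_trace()].
#' @param path CSV path.
#' @return `path` invisibly; `read_calcium_trace` returns the trace, with
#'   `fs` recovered from the time column.
#' @export
write_calcium_trace <- function(trace, path) {
  t <- (seq_along(trace$signal) - 1) / trace$fs
  utils::write.csv(data.frame(time_s = t, signal = trace$signal), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_calcium_trace
#' @export
read_calcium_trace <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "signal") %in% names(df)))
  dt <- stats::median(diff(df$time_s))
  calcium_trace(df$signal, fs = 1 / dt)
}

#' Write / read detected slow-wave events as JSON
#'
#' @param events a [sw_events()] list.
#' @param path JSON path.
#' @return `path` invisibly; `read_sw_events` returns the event list.
#' @export
write_sw_events <- function(events, path) {
  jsonlite::write_json(list(onsets = events$onsets,
                            offsets = events$offsets,
                            peaks = events$peak_amplitudes,
                            source_fs = events$source_fs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sw_events
#' @export
read_sw_events <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sw_events(as.numeric(x$onsets), as.numeric(x$offsets),
            as.numeric(x$peaks), x$source_fs)
}

#' Write a connectivity result (matrix TSV + JSON summary)
#'
#' @param result an `fc_result`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fc_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- as.data.frame(result$r)
  names(m) <- result$roi_labels %||% names(m)
  utils::write.table(m, file.path(dir, "r_matrix.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fdr_cutoff = result$fdr_cutoff,
         n_sig_pairs = result$n_sig_pairs,
         n_timepoints = result$n_timepoints,
         covariables = result$covariables),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
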