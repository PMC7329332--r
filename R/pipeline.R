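#' Run the full state-connectivity pipeline on one recording
#'
#' Orchestrates the analysis chain on a BOLD time-series set (and optional
#' simultaneous calcium trace): slow-wave detection, partial-correlation
#' connectivity with FDR thresholding, fALFF, distance dependence, graph
#' metrics, dynamic connectivity dissimilarity, and the transition/
#' connectivity linkage statistics. Every stage's configuration and seed is
#' echoed into the report so a rerun with the same config is numerically
#' identical.
#'
#' @param ts a [roi_timeseries()].
#' @param trace optional simultaneous [calcium_trace()] (baseline-corrected
#'   internally before detection).
#' @param config named list of stage settings; unknown keys are rejected.
#'   Recognized keys (all optional): `covariables` (character names into
#'   `ts$nuisance`), `q`, `fdr_method`, `detection` (a
#'   [detection_params()]), `graph_restarts`, `graph_seed`,
#'   `dynamics_window`, `dynamics_step`, `link_window`, `link_gap`,
#'   `n_perm`, `perm_seed`, `baseline_window`.
#' @param out_dir optional directory; when given, the report is written to
#'   `report.json` there, together with the connectivity result.
#' @return The report (a nested list), invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(ts, trace = NULL, config = list(), out_dir = NULL) {
  known <- c("covariables", "q", "fdr_method", "detection",
             "graph_restarts", "graph_seed", "dynamics_window",
             "dynamics_step", "link_window", "link_gap", "n_perm",
             "perm_seed", "baseline_window")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- list(covariables = config$covariables %||% names(ts$nuisance),
              q = config$q %||% 0.05,
              fdr_method = config$fdr_method %||% "storey",
              detection = config$detection %||% detection_params(),
              graph_restarts = config$graph_restarts %||% 100,
              graph_seed = config$graph_seed %||% 7,
              dynamics_window = config$dynamics_window %||% 300,
              dynamics_step = config$dynamics_step %||% 60,
              link_window = config$link_window %||% 180,
              link_gap = config$link_gap %||% 60,
              n_perm = config$n_perm %||% 10000,
              perm_seed = config$perm_seed %||% 7,
              baseline_window = config$baseline_window %||% 2500)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    val
  }

  report <- list(config = cfg[setdiff(names(cfg), "detection")],
                 detection_params = unclass(cfg$detection),
                 version = as.character(utils::packageVersion("statefc")))

  events <- NULL
  if (!is.null(trace)) {
    events <- stage("detect", {
      corrected <- correct_baseline(trace,
                                    min(cfg$baseline_window,
                                        length(trace$signal) - 1))
      detect_slow_waves(corrected, cfg$detection)
    })
    report$detect <- list(n_events = length(events$onsets),
                          mean_duration = if (length(events$onsets))
                            mean(events$offsets - events$onsets) else NA)
  }

  fc <- stage("fc", partial_corr_matrix(ts, cfg$covariables, q = cfg$q,
                                        method = cfg$fdr_method))
  report$fc <- list(fdr_cutoff = fc$fdr_cutoff,
                    n_sig_pairs = fc$n_sig_pairs,
                    n_timepoints = fc$n_timepoints)
  report$falff <- stage("falff", {
    f <- falff(ts)
    list(mean = f$fitted_mean, sd = f$fitted_sd)
  })

  report$graph <- stage("graph", {
    g <- build_adjacency(fc)
    if (max(g$weights) > 0) {
      graph_metrics(g, cfg$graph_restarts, seed = cfg$graph_seed)
    } else {
      list(note = "edgeless graph: metrics skipped")
    }
  })

  total <- ncol(ts$data) * ts$dt
  if (total >= 2 * cfg$dynamics_window) {
    report$dynamics <- stage("dynamics", {
      dyn <- dynamic_similarity(ts, cfg$covariables, cfg$dynamics_window,
                                cfg$dynamics_step, q = cfg$q,
                                method = cfg$fdr_method)
      list(window_starts = dyn$window_starts, values = dyn$values)
    })
  }

  if (!is.null(events) && length(events$onsets) >= 5) {
    report$link <- stage("link", {
      wp <- window_pair_series(events, ts, cfg$link_window, cfg$link_gap,
                               cfg$covariables, q = cfg$q,
                               method = cfg$fdr_method)
      pt <- permutation_corr_test(wp$transitions, wp$n_sig_pairs,
                                  n_perm = cfg$n_perm, seed = cfg$perm_seed)
      list(per_window = wp, pearson_r = pt$observed_r,
           permutation_p = pt$p_empirical)
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fc_result(fc, file.path(out_dir, "fc"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(report))
  }
  report
}
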