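#' Paired transition-count / significant-pair series over tiled windows
#'
#' For every analysis window (3 min with 1-min gaps by default, tiled as in
#' [count_transitions()]): counts the down-up transitions whose onset falls
#' inside the window, and computes the significant-pair count from a
#' window-restricted partial-correlation matrix with its own FDR cutoff.
#' At TR = 1.5 s a 3-min window holds 120 BOLD samples, above the minimum of
#' 100 points required for windowed connectivity.
#'
#' @param events a [sw_events()] list (detected or ground-truth transitions).
#' @param ts the simultaneous BOLD [roi_timeseries()].
#' @param window_length,gap window tiling in seconds (defaults 180 / 60).
#' @param covariables,q,method as in [partial_corr_matrix()]; windows
#'   default to Benjamini-Hochberg q-values, whose cutoff is more stable
#'   than Storey's pi0 estimate at the ~120 samples a 3-min window holds.
#' @param calcium_duration optional duration (s) of the calcium recording;
#'   if it differs from the BOLD duration by more than one window the two
#'   clocks are considered misaligned and an error is raised.
#' @return A data.frame with `window_start`, `transitions`, `n_sig_pairs`.
#' @export
window_pair_series <- function(events, ts, window_length = 180, gap = 60,
                               covariables = NULL, q = 0.05,
                               method = "bh",
                               calcium_duration = NULL) {
  total <- ncol(ts$data) * ts$dt
  if (!is.null(calcium_duration) &&
      abs(calcium_duration - total) > window_length) {
    stop(sprintf(
      "misaligned recordings: calcium covers %.1f s, BOLD covers %.1f s",
      calcium_duration, total))
  }
  if (window_length / ts$dt < 100) {
    stop("BOLD window holds fewer than 100 timepoints")
  }
  counts <- count_transitions(events, window_length, gap, total)
  starts <- attr(counts, "window_starts")
  n_sig <- vapply(starts, function(s) {
    res <- partial_corr_matrix(roi_ts_window(ts, s, s + window_length),
                               covariables, q = q, method = method)
    res$n_sig_pairs
  }, numeric(1))
  data.frame(window_start = starts, transitions = as.integer(counts),
             n_sig_pairs = as.integer(n_sig))
}

#' Permutation test for a correlation
#'
#' Observed Pearson correlation compared against a null built by shuffling
#' `y` against `x` (`n_perm` surrogates; one side shuffled, which is
#' equivalent to shuffling both under exchangeability). The empirical
#' two-sided p-value uses the add-one correction
#' `p = (1 + #(|null| >= |observed|)) / (n_perm + 1)`.
#'
#' @param x,y numeric vectors of equal length >= 5, non-constant.
#' @param n_perm number of surrogates (default 10000).
#' @param seed integer seed; the test is seed-deterministic.
#' @return An object of class `perm_test`: `observed_r`, `null_rs`,
#'   `p_empirical`, `n_perm`, `seed`.
#' @export
permutation_corr_test <- function(x, y, n_perm = 10000, seed = 1) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  obs <- stats::cor(x, y)
  n <- length(x)
  xs <- as.numeric(scale(x))
  ys <- as.numeric(scale(y))
  nulls <- with_seed(seed, {
    perms <- replicate(n_perm, sample.int(n))
    colSums(xs * matrix(ys[perms], n, n_perm)) / (n - 1)
  })
  p <- (1 + sum(abs(nulls) >= abs(obs) - 1e-12)) / (n_perm + 1)
  structure(list(observed_r = obs, null_rs = nulls, p_empirical = p,
                 n_perm = n_perm, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> r = %.3f, empirical p = %.4g (%d surrogates)\n",
              x$observed_r, x$p_empirical, x$n_perm))
  invisible(x)
}

#' Repeated-measures correlation
#'
#' Common within-subject association across subjects, estimated by the
#' analysis-of-covariance formulation: `y` is fitted on subject indicator
#' variables plus a shared slope for `x`;
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))` with
#' `df = N - k - 1` (N observations, k subjects) and the p-value from the
#' corresponding t distribution. Subjects with constant `x` are excluded
#' with a message; a single remaining subject degenerates to the ordinary
#' Pearson correlation (df adjusted accordingly).
#'
#' @param subject_ids subject identifier per observation.
#' @param x,y numeric vectors, same length as `subject_ids`.
#' @return An object of class `rmcorr_result`: `r_rm`, `df`, `p`,
#'   `slope`, `n_subjects`.
#' @export
rmcorr <- function(subject_ids, x, y) {
  stopifnot(length(subject_ids) == length(x), length(x) == length(y))
  subj <- factor(subject_ids)
  drop <- vapply(levels(subj), function(s) {
    i <- subj == s
    sum(i) < 2 || stats::sd(x[i]) == 0
  }, logical(1))
  if (any(drop)) {
    message("excluding subject(s) with constant x: ",
            paste(levels(subj)[drop], collapse = ", "))
    keep <- !(subj %in% levels(subj)[drop])
    subj <- droplevels(subj[keep])
    x <- x[keep]
    y <- y[keep]
  }
  k <- nlevels(subj)
  if (k == 0) stop("all subjects excluded")
  # within-subject centering is equivalent to the subject-intercept ANCOVA
  xc <- x - stats::ave(x, subj)
  yc <- y - stats::ave(y, subj)
  sxx <- sum(xc^2)
  syy <- sum(yc^2)
  sxy <- sum(xc * yc)
  slope <- sxy / sxx
  r_rm <- sign(slope) * sqrt((sxy^2 / sxx) / syy)
  df <- if (k == 1) length(x) - 2 else length(x) - k - 1
  tval <- r_rm * sqrt(df / max(1 - r_rm^2, 1e-15))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(r_rm = r_rm, df = df, p = p, slope = slope,
                 n_subjects = k),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("<rmcorr> r(%d) = %.3f, p = %.3g (%d subjects)\n",
              x$df, x$r_rm, x$p, x$n_subjects))
  invisible(x)
}

#' Paired t comparison between conditions
#'
#' Classical paired t-test on the per-subject differences (df = n - 1), the
#' statistic used for all slow-wave vs persistent condition contrasts. When
#' every difference is exactly zero, `t = 0, p = 1` by convention; a
#' non-zero constant shift (zero variance of differences) is an error.
#'
#' @param a,b per-subject values under the two conditions (equal length
#'   >= 3, finite).
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_comparison <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3,
            all(is.finite(a)), all(is.finite(b)))
  d <- a - b
  n <- length(d)
  if (all(d == 0)) {
    return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
  }
  if (stats::sd(d) <= 1e-12 * max(abs(d))) {
    stop("zero variance of differences: paired t undefined")
  }
  tval <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tval, df = n - 1, p = 2 * stats::pt(-abs(tval), n - 1),
       mean_diff = mean(d))
}
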