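#' Eigenvalue-Frobenius matrix dissimilarity
#'
#' Sorts the eigenvalues of each symmetric matrix in descending order and
#' returns the Euclidean (Frobenius) norm of the difference between the two
#' spectra. Zero means identical spectra (hence highly similar connectivity
#' structure); larger values mean more dissimilar matrices. The measure is
#' invariant under any relabeling of the ROIs (isospectral matrices compare
#' as identical).
#'
#' @param a,b symmetric numeric matrices of equal dimension.
#' @param tol symmetry tolerance.
#' @return Non-negative scalar dissimilarity.
#' @export
eig_frobenius_similarity <- function(a, b, tol = 1e-8) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("dimension mismatch")
  if (!isSymmetric(a, tol = tol) || !isSymmetric(b, tol = tol)) {
    stop("matrices must be symmetric")
  }
  ev_a <- sort(eigen(a, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  ev_b <- sort(eigen(b, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  sqrt(sum((ev_a - ev_b)^2))
}

#' Sliding-window dynamic connectivity dissimilarity
#'
#' Computes a partial-correlation matrix in every sliding window (length
#' `window_length`, step `step`) and compares each to the first window's
#' matrix with [eig_frobenius_similarity()] -- the dynamic connectivity
#' analysis comparing the initial recording period with a moving window.
#' Stable network configurations give a flat, low trajectory; ongoing
#' reorganization (as during slow-wave activity) gives larger values.
#'
#' @param ts a [roi_timeseries()] covering at least `2 * window_length`.
#' @param covariables as in [partial_corr_matrix()].
#' @param window_length window length in seconds (default 300, i.e. 5 min).
#' @param step step between window starts in seconds (default 60).
#' @param use_thresholded if `TRUE`, compare FDR-thresholded adjacency
#'   matrices instead of the raw partial-correlation matrices.
#' @param q,method FDR settings for the per-window matrices.
#' @return An object of class `similarity_series`: `window_starts` (s),
#'   `values` (dissimilarity to the first window; first value 0),
#'   `window_length`, `step`.
#' @export
dynamic_similarity <- function(ts, covariables = NULL, window_length = 300,
                               step = 60, use_thresholded = FALSE,
                               q = 0.05, method = "storey") {
  total <- ncol(ts$data) * ts$dt
  if (total < 2 * window_length) {
    stop("recording must cover at least two window lengths")
  }
  if (window_length / ts$dt < 100) {
    stop("window holds fewer than 100 timepoints")
  }
  starts <- seq(0, total - window_length, by = step)
  mats <- lapply(starts, function(s) {
    res <- partial_corr_matrix(roi_ts_window(ts, s, s + window_length),
                               covariables, q = q, method = method)
    if (use_thresholded) build_adjacency(res)$weights else res$r
  })
  vals <- vapply(mats, eig_frobenius_similarity, numeric(1), b = mats[[1]])
  structure(list(window_starts = starts, values = vals,
                 window_length = window_length, step = step),
            class = "similarity_series")
}

#' @export
print.similarity_series <- function(x, ...) {
  cat(sprintf(
    "<similarity_series> %d windows (%g s / step %g s), mean dissimilarity %.3f\n",
    length(x$values), x$window_length, x$step, mean(x$values)))
  invisible(x)
}
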