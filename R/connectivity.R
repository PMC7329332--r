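#' Partial-correlation functional connectivity matrix
#'
#' Residualizes every ROI series against the covariable design (with
#' intercept) by least squares and computes the Pearson correlation of the
#' residuals -- the partial correlation controlling for the covariables. A
#' per-matrix FDR cutoff on the positive correlations is computed alongside
#' (one-sided p-values from the t-transform of r; Storey q-values by
#' default), giving the significance mask and the significant-pair count.
#'
#' Following the thresholding rule used for graph construction, significance
#' is one-sided: only positive correlations at or above the cutoff are
#' counted; negative correlations remain in the matrix but are never
#' significant.
#'
#' @param ts a [roi_timeseries()].
#' @param covariables covariable set: a character vector naming regressors in
#'   `ts$nuisance`, a numeric matrix/vector (time along rows), a named list
#'   of numeric vectors, or `NULL` for plain correlation. The cortex-wide
#'   component regressor (or its time-reversed control) is passed here.
#' @param q FDR level (default 0.05).
#' @param method `"storey"` (default) or `"bh"` q-value procedure.
#' @return An object of class `fc_result`: `r` (symmetric, unit diagonal),
#'   `covariables` (names used), `fdr_cutoff` (smallest significant r; `Inf`
#'   if none), `sig_mask` (logical, `r >= fdr_cutoff` on the positive side),
#'   `n_sig_pairs` (upper-triangle count), `n_timepoints`, `centroids`,
#'   `roi_labels`.
#' @export
partial_corr_matrix <- function(ts, covariables = NULL, q = 0.05,
                                method = c("storey", "bh")) {
  method <- match.arg(method)
  X <- t(ts$data)
  n <- nrow(X)
  C <- build_covariable_design(ts, covariables)
  stopifnot(ncol(X) >= 2)
  if (n < ncol(C$design) + 10) {
    stop("too few timepoints for the covariable design")
  }
  qrC <- qr(C$design)
  if (qrC$rank < ncol(C$design)) {
    bad <- colnames(C$design)[qrC$pivot[(qrC$rank + 1):ncol(C$design)]]
    stop("rank-deficient covariable design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  R <- qr.resid(qrC, X)
  r <- stats::cor(R)
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  cut <- fdr_cutoff(r, n_timepoints = n - (ncol(C$design) - 1), q = q,
                    method = method)
  sig <- r >= cut & r > 0
  diag(sig) <- FALSE
  structure(list(r = r, covariables = C$names, fdr_cutoff = cut,
                 sig_mask = sig,
                 n_sig_pairs = sum(sig[upper.tri(sig)]),
                 n_timepoints = n,
                 centroids = ts$centroids, roi_labels = ts$roi_labels),
            class = "fc_result")
}

#' @export
print.fc_result <- function(x, ...) {
  cat(sprintf(
    "<fc_result> %d ROIs, %d timepoints; FDR cutoff r = %s; %d significant pairs\n",
    nrow(x$r), x$n_timepoints,
    if (is.finite(x$fdr_cutoff)) sprintf("%.3f", x$fdr_cutoff) else "Inf",
    x$n_sig_pairs))
  if (length(x$covariables)) {
    cat("  covariables:", paste(x$covariables, collapse = ", "), "\n")
  }
  invisible(x)
}

# normalize the many accepted covariable forms into an intercept-led design
build_covariable_design <- function(ts, covariables) {
  n <- ncol(ts$data)
  if (is.null(covariables) || (is.character(covariables) &&
                               !length(covariables))) {
    return(list(design = matrix(1, n, 1,
                                dimnames = list(NULL, "(intercept)")),
                names = character(0)))
  }
  if (is.character(covariables)) {
    missing <- setdiff(covariables, names(ts$nuisance))
    if (length(missing)) {
      stop("unknown nuisance regressor(s): ", paste(missing, collapse = ", "))
    }
    mat <- do.call(cbind, ts$nuisance[covariables])
    nms <- covariables
  } else if (is.list(covariables)) {
    mat <- do.call(cbind, covariables)
    nms <- names(covariables) %||% paste0("cov", seq_along(covariables))
  } else {
    mat <- as.matrix(covariables)
    nms <- colnames(mat) %||% paste0("cov", seq_len(ncol(mat)))
  }
  if (nrow(mat) != n) {
    stop(sprintf("covariables have %d samples, data has %d", nrow(mat), n))
  }
  colnames(mat) <- nms
  list(design = cbind("(intercept)" = 1, mat), names = nms)
}

#' Time-reverse a regressor
#'
#' The control condition for the cortex-wide-component covariable: the same
#' values in reversed temporal order, preserving amplitude and spectrum while
#' destroying the temporal alignment.
#'
#' @param regressor numeric vector.
#' @return The reversed vector.
#' @export
reverse_regressor <- function(regressor) rev(regressor)

#' Per-matrix FDR cutoff on positive correlations
#'
#' Upper-triangle correlations are converted to one-sided p-values through
#' the t-transform `t = r * sqrt((n-2)/(1-r^2))`; q-values are computed by
#' Storey's procedure (default) or Benjamini-Hochberg, and the cutoff is the
#' smallest r among pairs with `q < q`-level. Correlations at or above the
#' cutoff are the significant connections. Returns `Inf` when nothing is
#' significant.
#'
#' @param result_r symmetric correlation matrix.
#' @param n_timepoints effective sample size for the t-transform (> 3).
#' @param q FDR level.
#' @param method `"storey"` or `"bh"`.
#' @return The r-value cutoff (scalar, possibly `Inf`).
#' @export
fdr_cutoff <- function(result_r, n_timepoints, q = 0.05,
                       method = c("storey", "bh")) {
  method <- match.arg(method)
  stopifnot(n_timepoints > 3)
  rv <- upper_tri_values(result_r)
  rv <- pmin(pmax(rv, -1), 1)
  tt <- rv * sqrt((n_timepoints - 2) / pmax(1 - rv^2, 1e-15))
  p <- stats::pt(tt, df = n_timepoints - 2, lower.tail = FALSE)
  qv <- if (method == "storey") storey_qvalues(p) else stats::p.adjust(p, "BH")
  sig <- qv < q & rv > 0
  if (!any(sig)) return(Inf)
  min(rv[sig])
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05..0.90 (step
#' 0.05) with a smoothing-spline fit evaluated at the largest lambda, clipped
#' to (0, 1], then converts p-values to monotone q-values.
#'
#' @param p vector of p-values.
#' @return Vector of q-values, same order as `p`.
#' @export
storey_qvalues <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  lambda <- seq(0.05, 0.9, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- if (all(pi0_l == 0)) {
    0
  } else {
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  }
  pi0 <- min(max(pi0, 1 / m), 1)
  o <- order(p)
  q <- numeric(m)
  q[o] <- pi0 * m * p[o] / seq_len(m)
  q[o] <- rev(cummin(rev(q[o])))
  pmin(q, 1)
}

#' Empirical CDF of the connectivity r-values
#'
#' Cumulative distribution of the upper-triangle correlations evaluated on a
#' grid; evaluating each subject's CDF at the cohort-mean FDR cutoff supports
#' the between-state comparison "at the mean of the cutoff".
#'
#' @param result an `fc_result` from [partial_corr_matrix()].
#' @param grid ascending r-values at which to evaluate the CDF.
#' @return Numeric vector of CDF values on `grid`.
#' @export
rvalue_cdf <- function(result, grid) {
  if (is.unsorted(grid)) stop("grid must be sorted ascending")
  stats::ecdf(upper_tri_values(result$r))(grid)
}

#' Fractional amplitude of low-frequency fluctuations (fALFF)
#'
#' Per ROI, the amplitude spectrum is `|FFT|` of the demeaned series (DC
#' excluded, rectangular window); fALFF is the sum of amplitudes inside
#' `band` divided by the sum inside `full_band`. A normal distribution
#' (mean/sd) is fitted across ROIs, mirroring the per-animal fALFF curves.
#'
#' @param ts a [roi_timeseries()].
#' @param band low-frequency band of interest in Hz (default 0.01-0.1).
#' @param full_band reference band in Hz (default 0-0.25); its upper edge
#'   must not exceed the Nyquist frequency.
#' @return An object of class `falff_profile`: `falff_per_roi` (values in
#'   `[0, 1]`), `band`, `full_band`, `fitted_mean`, `fitted_sd`.
#' @export
falff <- function(ts, band = c(0.01, 0.1), full_band = c(0, 0.25)) {
  n <- ncol(ts$data)
  nyquist <- 1 / (2 * ts$dt)
  if (full_band[2] > nyquist + 1e-12) {
    stop(sprintf("full band upper edge %g Hz exceeds Nyquist %g Hz",
                 full_band[2], nyquist))
  }
  df <- 1 / (n * ts$dt)
  if (band[1] < 2 * df) {
    stop("recording too short to resolve the lower band edge")
  }
  nf <- floor(n / 2)
  freqs <- (seq_len(nf)) * df  # DC bin excluded
  in_band <- freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12
  in_full <- freqs >= full_band[1] - 1e-12 & freqs <= full_band[2] + 1e-12
  amp <- abs(stats::mvfft(t(ts$data - rowMeans(ts$data))))[1 + seq_len(nf), ,
                                                           drop = FALSE]
  vals <- colSums(amp[in_band, , drop = FALSE]) /
    colSums(amp[in_full, , drop = FALSE])
  structure(list(falff_per_roi = as.numeric(vals), band = band,
                 full_band = full_band,
                 fitted_mean = mean(vals), fitted_sd = stats::sd(vals)),
            class = "falff_profile")
}

#' Distance dependence of significant connectivity
#'
#' Ordinary least-squares regression of the significant pairs' correlations
#' against the pairwise Euclidean distance between ROI centroids. A steeper
#' (more negative) slope means connectivity is more strongly governed by
#' distance, the signature of propagating slow-wave activity.
#'
#' @param result an `fc_result` from [partial_corr_matrix()].
#' @param centroids n-by-3 mm matrix; defaults to the centroids stored in
#'   `result`.
#' @return List with `slope` (r-units per mm), `pearson_r`, `intercept`,
#'   `n_pairs`.
#' @export
distance_dependence <- function(result, centroids = NULL) {
  centroids <- centroids %||% result$centroids
  if (is.null(centroids)) stop("no centroids available")
  D <- as.matrix(stats::dist(centroids))
  ut <- upper.tri(result$r)
  sel <- result$sig_mask & ut
  if (sum(sel) < 3) stop("fewer than 3 significant pairs")
  rr <- result$r[sel]
  dd <- D[sel]
  fit <- stats::lm(rr ~ dd)
  pearson_r <- if (stats::sd(rr) == 0) 0 else stats::cor(rr, dd)
  list(slope = unname(stats::coef(fit)[2]),
       pearson_r = pearson_r,
       intercept = unname(stats::coef(fit)[1]),
       n_pairs = sum(sel))
}
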