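#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peaking near `peak` seconds,
#' undershoot near `undershoot` seconds), normalized to unit peak. The BOLD
#' generator convolves down-up transition boxcars with this kernel.
#'
#' @param t time in seconds (vector).
#' @param peak,undershoot response and undershoot peak times (s).
#' @param ratio undershoot-to-peak amplitude ratio.
#' @return Kernel values at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot + 1, rate = 1)
  h[t < 0] <- 0
  h / max(h)
}

# n_series columns of unit-sd Gaussian noise band-limited to `band` (Hz) by
# zero-phase FFT masking; n samples at interval dt
bandlimited_noise <- function(n, dt, band = c(0.01, 0.1), n_series = 1) {
  f <- (seq_len(n) - 1) / (n * dt)
  f <- pmin(f, 1 / dt - f)  # two-sided spectrum folded to [0, Nyquist]
  mask <- f >= band[1] & f <= band[2]
  if (!any(mask)) stop("band contains no frequency bins at this length")
  w <- matrix(stats::rnorm(n * n_series), n, n_series)
  fw <- stats::mvfft(w)
  fw[!mask, ] <- 0
  x <- Re(stats::mvfft(fw, inverse = TRUE)) / n
  scale(x, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

# default ROI centroid geometry: a 3-D grid spanning ~12 x 8 x 4 mm
# (rat cortex scale) so Euclidean-distance analyses are meaningful
default_centroids <- function(n_rois) {
  nx <- ceiling(n_rois^(1 / 3) * 1.5)
  ny <- ceiling(sqrt(n_rois / nx))
  nz <- ceiling(n_rois / (nx * ny))
  g <- expand.grid(x = seq(0, 12, length.out = nx),
                   y = seq(0, 8, length.out = max(ny, 2)),
                   z = seq(0, 4, length.out = max(nz, 2)))
  as.matrix(g[seq_len(n_rois), , drop = FALSE])
}

# amplitude-modulated ~0.1 Hz breathing-like regressor, standardized
breathing_regressor <- function(t) {
  b <- sin(2 * pi * 0.1 * t) * (1 + 0.3 * sin(2 * pi * 0.01 * t))
  as.numeric(scale(b))
}

#' Generate a state-dependent synthetic BOLD dataset with ground truth
#'
#' Two regimes are emulated:
#' \describe{
#'   \item{persistent}{each ROI is `sqrt(c1)` times its module's band-limited
#'     (0.01-0.1 Hz) latent, plus (for a random subset of ROIs) a weaker
#'     `sqrt(c2)` loading on a second module's latent emulating distributed
#'     long-range membership, plus independent band-limited noise and white
#'     measurement noise. Within-module correlation is approximately `c1`
#'     before measurement noise.}
#'   \item{slow_wave}{a cortex-wide event train of down-up transitions is
#'     convolved with the HRF; each ROI receives it scaled by its coupling and
#'     delayed by (distance from the origin ROI)/`wave_speed`. A fraction of
#'     ROIs couple only weakly. Noise is part spatially correlated
#'     (exponential decay with inter-ROI distance) and part independent white
#'     noise, so pairwise correlation decays with distance.}
#' }
#' Both regimes add shared breathing and ventricle/white-matter-like nuisance
#' regressors (with small coupling into every ROI) that are also returned in
#' `nuisance`, giving the connectivity covariables something real to remove.
#'
#' @param state `"persistent"` or `"slow_wave"`.
#' @param n_rois number of ROIs (default 96, the cortical parcellation size).
#' @param dt BOLD sampling interval in seconds (TR, default 1.5).
#' @param total_duration recording length in seconds (default 30 min).
#' @param module_map integer module label per ROI; default interleaves 8
#'   modules across the centroid grid (functional networks are spatially
#'   distributed, not contiguous blocks).
#' @param centroids n-by-3 mm matrix; default grid spans ~12 x 8 x 4 mm.
#' @param within_module_corr persistent: target within-module correlation
#'   `c1` before measurement noise, in `[0, 1)`.
#' @param secondary_corr,secondary_frac persistent: secondary-module loading
#'   `c2` and the fraction of ROIs carrying one.
#' @param event_rate slow-wave: mean down-up transition rate (events/s).
#' @param rate_drift_depth,rate_drift_period slow-wave: slow sinusoidal
#'   drift of the transition rate (relative depth, period in seconds,
#'   seed-drawn phase), emulating the ongoing changes in down-up transition
#'   frequency that reorganize connectivity over minutes; depth 0 gives a
#'   homogeneous train.
#' @param event_train optional pre-built [event_train()] overriding
#'   `event_rate` (used to couple BOLD and calcium generators).
#' @param min_gap,duration_range passed to [gen_event_train()].
#' @param wave_speed propagation speed of the slow wave in mm/s.
#' @param weak_frac slow-wave: fraction of ROIs only weakly coupled to the
#'   wave; strong couplings are drawn from `U(0.85, 1.15)`, weak from
#'   `U(0, 0.25)`.
#' @param hrf list with `peak`, `undershoot`, `ratio` for
#'   [hrf_double_gamma()].
#' @param noise_sd measurement-noise standard deviation in signal units
#'   (signal components have unit scale); default 0.45 (persistent) or 1.05
#'   (slow-wave, relative to the unit-sd wave component).
#' @param spatial_share,spatial_scale slow-wave noise structure: share of
#'   noise variance that is spatially correlated and its exponential
#'   correlation length (mm).
#' @param nuisance_coupling amplitude with which the breathing and
#'   ventricle/white-matter regressors leak into every ROI.
#' @param band frequency band (Hz) of the persistent-state latents.
#' @param seed integer seed; output is fully reproducible.
#' @return List with `ts` (a [roi_timeseries()]) and `gt` (a `ground_truth`
#'   list: `module_of_roi`, `event_train`, `roi_coupling`, `roi_delay`,
#'   `wave_speed`, `cwc_regressor` -- the standardized undelayed
#'   HRF-convolved event train, the synthetic stand-in for the cortex-wide
#'   component time course -- and `seed`).
#' @export
gen_bold_state_dataset <- function(state = c("persistent", "slow_wave"),
                                   n_rois = 96, dt = 1.5,
                                   total_duration = 1800,
                                   module_map = NULL, centroids = NULL,
                                   within_module_corr = 0.6,
                                   secondary_corr = 0.15,
                                   secondary_frac = 0.2,
                                   event_rate = 0.15, event_train = NULL,
                                   rate_drift_depth = 0.5,
                                   rate_drift_period = 600,
                                   min_gap = 1, duration_range = c(0.3, 2),
                                   wave_speed = 51.2, weak_frac = 0.3,
                                   hrf = list(peak = 6, undershoot = 16,
                                              ratio = 1 / 6),
                                   noise_sd = NULL,
                                   spatial_share = 0.35, spatial_scale = 4,
                                   nuisance_coupling = 0.05,
                                   band = c(0.01, 0.1), seed = 1) {
  state <- match.arg(state)
  n <- round(total_duration / dt)
  if (n < 120) {
    stop("recording too short: fewer than 120 samples (the minimum window)")
  }
  if (is.null(centroids)) centroids <- default_centroids(n_rois)
  centroids <- as.matrix(centroids)
  stopifnot(nrow(centroids) == n_rois)
  if (is.null(module_map)) module_map <- rep_len(seq_len(8), n_rois)
  stopifnot(length(module_map) == n_rois)
  if (is.null(noise_sd)) {
    noise_sd <- if (state == "persistent") 0.45 else 1.05
  }
  t_bold <- (seq_len(n) - 1) * dt

  out <- with_seed(seed, {
    breath <- breathing_regressor(t_bold)
    vwm <- as.numeric(bandlimited_noise(n, dt, c(0.005, 0.05), 1))
    if (state == "persistent") {
      c1 <- within_module_corr
      c2 <- secondary_corr
      stopifnot(c1 >= 0, c1 < 1, c1 + c2 < 1)
      mods <- sort(unique(module_map))
      latents <- bandlimited_noise(n, dt, band, length(mods))
      colnames(latents) <- as.character(mods)
      has_sec <- stats::runif(n_rois) < secondary_frac & c2 > 0
      sec_mod <- vapply(seq_len(n_rois), function(i) {
        sample(setdiff(mods, module_map[i]), 1)
      }, numeric(1))
      indep <- bandlimited_noise(n, dt, band, n_rois)
      data <- matrix(0, n_rois, n)
      for (i in seq_len(n_rois)) {
        load2 <- if (has_sec[i]) c2 else 0
        data[i, ] <- sqrt(c1) * latents[, as.character(module_map[i])] +
          sqrt(load2) * latents[, as.character(sec_mod[i])] +
          sqrt(1 - c1 - load2) * indep[, i]
      }
      data <- data + noise_sd * matrix(stats::rnorm(n_rois * n), n_rois, n)
      coupling <- ifelse(has_sec, sqrt(c1 + c2), sqrt(c1))
      train <- event_train(numeric(0), numeric(0), total_duration)
      delays <- rep(0, n_rois)
      cwc <- NULL
    } else {
      train <- event_train %||% {
        if (rate_drift_depth > 0) {
          phase <- stats::runif(1, 0, 2 * pi)
          profile <- function(t) {
            1 + rate_drift_depth * sin(2 * pi * t / rate_drift_period + phase)
          }
          gen_event_train(event_rate * (1 + rate_drift_depth),
                          total_duration, min_gap, duration_range,
                          seed = seed + 1, rate_profile = profile)
        } else {
          gen_event_train(event_rate, total_duration, min_gap,
                          duration_range, seed = seed + 1)
        }
      }
      # fine time grid so sub-TR propagation delays are represented exactly
      up <- max(1, round(dt / 0.1))
      dtf <- dt / up
      nf <- n * up
      e <- numeric(nf)
      for (k in seq_along(train$onsets)) {
        i0 <- floor(train$onsets[k] / dtf) + 1
        i1 <- min(nf, ceiling((train$onsets[k] + train$durations[k]) / dtf))
        e[i0:i1] <- 1
      }
      h <- hrf_double_gamma(seq(0, 32, by = dtf), hrf$peak, hrf$undershoot,
                            hrf$ratio)
      L <- stats::nextn(nf + length(h), 2)
      E <- stats::fft(c(e, numeric(L - nf)))
      H <- stats::fft(c(h, numeric(L - length(h))))
      origin <- which.min(rowSums(centroids))
      delays <- sqrt(colSums((t(centroids) - centroids[origin, ])^2)) /
        wave_speed
      conv0 <- Re(stats::fft(E * H, inverse = TRUE))[seq_len(nf)] / L
      # fixed reference amplitude (the convolved train's typical sd at the
      # default 0.15 events/s), so the wave strength grows with event rate
      wave_sd <- 7.3
      n_weak <- round(weak_frac * n_rois)
      weak <- sample.int(n_rois, n_weak)
      coupling <- stats::runif(n_rois, 0.85, 1.15)
      coupling[weak] <- stats::runif(n_weak, 0, 0.25)
      k_idx <- 0:(L - 1)
      data <- matrix(0, n_rois, n)
      for (i in seq_len(n_rois)) {
        ph <- exp(-2i * pi * k_idx * (delays[i] / dtf) / L)
        ci <- Re(stats::fft(E * H * ph, inverse = TRUE))[seq_len(nf)] / L
        data[i, ] <- coupling[i] * ci[seq(1, nf, by = up)] / wave_sd
      }
      # noise: spatially correlated field + independent white component
      D <- as.matrix(stats::dist(centroids))
      Rchol <- chol(exp(-D / spatial_scale) + diag(1e-8, n_rois))
      field <- t(Rchol) %*% matrix(stats::rnorm(n_rois * n), n_rois, n)
      white <- matrix(stats::rnorm(n_rois * n), n_rois, n)
      data <- data + noise_sd * (sqrt(spatial_share) * field +
                                   sqrt(1 - spatial_share) * white)
      cwc <- conv0[seq(1, nf, by = up)] / wave_sd
      if (stats::sd(cwc) > 0) cwc <- as.numeric(scale(cwc))
    }
    data <- data + nuisance_coupling * (rep(1, n_rois) %o% breath) +
      nuisance_coupling * (rep(1, n_rois) %o% vwm)
    ts <- roi_timeseries(data, dt, centroids = centroids,
                         nuisance = list(breathing = breath, vwm = vwm))
    gt <- structure(list(module_of_roi = module_map, event_train = train,
                         roi_coupling = coupling, roi_delay = delays,
                         wave_speed = wave_speed, cwc_regressor = cwc,
                         state = state, seed = seed),
                    class = "ground_truth")
    list(ts = ts, gt = gt)
  })
  out
}

#' Generate a synthetic cohort of state-dependent BOLD datasets
#'
#' Draws independent per-subject seeds from the master seed and (optionally)
#' jitters the main scale parameters across subjects, emulating inter-animal
#' variability in anesthesia depth and signal quality.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param state `"persistent"` or `"slow_wave"`.
#' @param shared_params named list of arguments passed on to
#'   [gen_bold_state_dataset()] for every subject.
#' @param jitter relative (lognormal) per-subject jitter applied to
#'   `noise_sd` and `event_rate`; 0 disables.
#' @param seed master seed; the same master seed reproduces the cohort
#'   bit for bit.
#' @return List of `n_subjects` elements, each `list(ts, gt)`.
#' @export
gen_cohort <- function(n_subjects, state, shared_params = list(),
                       jitter = 0.15, seed = 1) {
  stopifnot(n_subjects >= 2)
  setup <- with_seed(seed, {
    list(seeds = sample.int(2^30, n_subjects),
         jit_noise = exp(stats::rnorm(n_subjects, 0, jitter)),
         jit_rate = exp(stats::rnorm(n_subjects, 0, jitter)))
  })
  lapply(seq_len(n_subjects), function(s) {
    pars <- shared_params
    pars$state <- state
    pars$seed <- setup$seeds[s]
    if (jitter > 0) {
      base_noise <- pars$noise_sd %||%
        (if (state == "persistent") 0.45 else 1.05)
      pars$noise_sd <- base_noise * setup$jit_noise[s]
      if (state == "slow_wave" && is.null(pars$event_train)) {
        pars$event_rate <- (pars$event_rate %||% 0.15) * setup$jit_rate[s]
      }
    }
    do.call(gen_bold_state_dataset, pars)
  })
}

#' Generate a coupled BOLD + calcium recording from one event train
#'
#' One down-up transition train with a slowly modulated rate drives both a
#' slow-wave BOLD dataset and a photometry calcium trace, emulating the
#' co-registered fMRI/photometry experiments used to link transition counts
#' to connectivity.
#'
#' @param total_duration recording length (s).
#' @param dt BOLD sampling interval (s).
#' @param fs calcium sampling rate (Hz).
#' @param rate mean transition rate (events/s).
#' @param rate_mod_depth,rate_mod_period sinusoidal rate modulation: local
#'   rate is `rate * (1 + depth * sin(2*pi*t/period + phase))` with a
#'   seed-drawn phase, creating genuine within-subject variation in
#'   transition counts across analysis windows.
#' @param calcium_noise_sd white-noise level of the calcium trace.
#' @param seed integer seed.
#' @param ... further arguments for [gen_bold_state_dataset()].
#' @return List with `ts` (BOLD), `trace` (calcium), `gt` (ground truth).
#' @export
gen_coupled_recording <- function(total_duration = 1800, dt = 1.5, fs = 200,
                                  rate = 0.05, rate_mod_depth = 0.9,
                                  rate_mod_period = 1800,
                                  calcium_noise_sd = 0.1, seed = 1, ...) {
  phase <- with_seed(seed + 3, stats::runif(1, 0, 2 * pi))
  profile <- function(t) {
    1 + rate_mod_depth * sin(2 * pi * t / rate_mod_period + phase)
  }
  train <- gen_event_train(rate * (1 + rate_mod_depth), total_duration,
                           min_gap = 1, duration_range = c(0.3, 2),
                           seed = seed, rate_profile = profile)
  bold <- gen_bold_state_dataset("slow_wave", dt = dt,
                                 total_duration = total_duration,
                                 event_train = train, seed = seed + 1, ...)
  trace <- gen_calcium_trace(train, fs = fs, noise_sd = calcium_noise_sd,
                             seed = seed + 2)
  list(ts = bold$ts, trace = trace, gt = bold$gt)
}
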