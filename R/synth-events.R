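#' Generate a Poisson-like train of down-up transition events
#'
#' Draws candidate onsets from a (optionally rate-modulated) Poisson process
#' on `[0, total_duration]`, assigns each event a duration uniform in
#' `duration_range`, and greedily thins the train so that consecutive events
#' are separated by at least `min_gap` seconds of quiescence (measured from
#' the previous event's offset). Emulates the bimodal population dynamics of
#' slow-wave activity: long down periods interrupted by brief up states.
#'
#' @param rate mean event rate in events/s (> 0).
#' @param total_duration recording length in seconds.
#' @param min_gap minimum quiescent gap between an event's offset and the
#'   next onset, in seconds (>= 0).
#' @param duration_range length-2 interval (seconds) for uniform durations;
#'   must lie within (0, 10].
#' @param seed integer seed; the train is reproducible given the seed.
#' @param rate_profile optional function of time (seconds) returning a
#'   non-negative relative intensity; events are kept by thinning with
#'   probability `rate_profile(t)/max(rate_profile)`, so `rate` remains the
#'   peak rate. Used to emulate slow drifts in transition frequency.
#' @return An [event_train()].
#' @export
gen_event_train <- function(rate, total_duration, min_gap = 1,
                            duration_range = c(0.3, 2), seed = 1,
                            rate_profile = NULL) {
  stopifnot(rate > 0, total_duration > 0, min_gap >= 0,
            length(duration_range) == 2,
            duration_range[1] > 0, duration_range[2] <= 10,
            duration_range[1] <= duration_range[2])
  # an event "slot" needs at least min_gap + shortest duration of room
  if (rate > 1 / (min_gap + duration_range[1])) {
    stop(sprintf(
      "infeasible rate: %.3g events/s cannot respect min_gap = %.2g s with durations >= %.2g s",
      rate, min_gap, duration_range[1]))
  }
  with_seed(seed, {
    n_cand <- stats::rpois(1, rate * total_duration)
    if (n_cand == 0) {
      return(event_train(numeric(0), numeric(0), total_duration))
    }
    onsets <- sort(stats::runif(n_cand, 0, total_duration))
    durations <- stats::runif(n_cand, duration_range[1], duration_range[2])
    if (!is.null(rate_profile)) {
      rel <- rate_profile(onsets)
      stopifnot(all(rel >= 0))
      keep <- stats::runif(n_cand) < rel / max(rel)
      onsets <- onsets[keep]
      durations <- durations[keep]
    }
    keep_on <- numeric(0)
    keep_dur <- numeric(0)
    last_end <- -Inf
    for (k in seq_along(onsets)) {
      if (onsets[k] >= last_end + min_gap &&
          onsets[k] + durations[k] <= total_duration) {
        keep_on <- c(keep_on, onsets[k])
        keep_dur <- c(keep_dur, durations[k])
        last_end <- onsets[k] + durations[k]
      }
    }
    event_train(keep_on, keep_dur, total_duration)
  })
}

# unit-peak double-exponential calcium transient kernel evaluated at t >= 0;
# peak occurs at t* = rise*decay/(decay-rise) * log(decay/rise)
transient_kernel <- function(t, rise_tau, decay_tau) {
  stopifnot(decay_tau > rise_tau, rise_tau > 0)
  tstar <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-tstar / decay_tau) - exp(-tstar / rise_tau)
  h <- exp(-t / decay_tau) - exp(-t / rise_tau)
  h[t < 0] <- 0
  h / peak
}

#' Synthesize a fiber-photometry calcium trace from an event train
#'
#' Each event contributes a unit-peak double-exponential transient scaled by
#' `transient$amplitude`; a slow sinusoidal baseline drift and white Gaussian
#' noise are added on top. The generating train is attached as attribute
#' `ground_truth` so detector recovery can be scored exactly.
#'
#' @param train an [event_train()].
#' @param fs sampling rate in Hz (>= 50).
#' @param transient list with `rise_tau` (s), `decay_tau` (s), `amplitude`
#'   (a.u.); `decay_tau > rise_tau > 0`.
#' @param drift list with `amplitude` (a.u.) and `period` (s) of a slow
#'   sinusoidal baseline drift.
#' @param noise_sd standard deviation of additive white Gaussian noise (a.u.).
#' @param seed integer seed for the noise.
#' @return A [calcium_trace()] with attribute `ground_truth` (the train).
#' @export
gen_calcium_trace <- function(train, fs = 1000,
                              transient = list(rise_tau = 0.05,
                                               decay_tau = 0.4,
                                               amplitude = 1),
                              drift = list(amplitude = 0, period = 100),
                              noise_sd = 0, seed = 1) {
  stopifnot(inherits(train, "event_train"), fs >= 50,
            transient$decay_tau > transient$rise_tau,
            transient$rise_tau > 0)
  n <- round(train$total_duration * fs)
  t <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  support <- transient$rise_tau + 5 * transient$decay_tau
  if (length(train$onsets) > 1 && min(diff(train$onsets)) < support) {
    warning("events denser than the transient support; transients overlap")
  }
  kn <- min(n, ceiling(support * 2 * fs))
  kernel <- transient$amplitude *
    transient_kernel((seq_len(kn) - 1) / fs,
                     transient$rise_tau, transient$decay_tau)
  for (k in seq_along(train$onsets)) {
    i0 <- floor(train$onsets[k] * fs) + 1
    i1 <- min(n, i0 + kn - 1)
    sig[i0:i1] <- sig[i0:i1] + kernel[seq_len(i1 - i0 + 1)]
  }
  if (drift$amplitude != 0) {
    sig <- sig + drift$amplitude * sin(2 * pi * t / drift$period)
  }
  if (noise_sd > 0) {
    sig <- sig + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  out <- calcium_trace(sig, fs)
  attr(out, "ground_truth") <- train
  out
}

#' Synthesize dual-site calcium traces with a propagation delay
#'
#' The second site sees the same event train delayed by
#' `separation / wave_speed` (a travelling slow wave), with independent
#' noise. Events whose delayed copy would overrun the recording are dropped
#' from both trains so the two traces stay paired.
#'
#' @param train an [event_train()].
#' @param separation inter-site distance in mm.
#' @param wave_speed propagation speed in mm/s (> 0).
#' @param fs sampling rate in Hz.
#' @param transient,drift,noise_sd as in [gen_calcium_trace()].
#' @param shared_band optional length-2 Hz interval: the shared (noiseless)
#'   wave component of both sites is zero-phase band-passed to this band
#'   before the independent noise is added, producing a pair that shares
#'   content only inside the band (the substrate for band-stop
#'   cross-correlation experiments).
#' @param seed integer seed; site noise streams are independent.
#' @return List of two [calcium_trace()] objects (`a`, `b`) with attribute
#'   `lag` (the ground-truth delay in seconds, site b lagging site a).
#' @export
gen_dual_site_traces <- function(train, separation, wave_speed = 51.2,
                                 fs = 1000,
                                 transient = list(rise_tau = 0.05,
                                                  decay_tau = 0.4,
                                                  amplitude = 1),
                                 drift = list(amplitude = 0, period = 100),
                                 noise_sd = 0, shared_band = NULL,
                                 seed = 1) {
  stopifnot(wave_speed > 0, separation >= 0)
  lag <- separation / wave_speed
  ok <- train$onsets + lag + train$durations <= train$total_duration
  tr_a <- event_train(train$onsets[ok], train$durations[ok],
                      train$total_duration)
  tr_b <- event_train(train$onsets[ok] + lag, train$durations[ok],
                      train$total_duration)
  clean_a <- gen_calcium_trace(tr_a, fs, transient, drift, noise_sd = 0)
  clean_b <- gen_calcium_trace(tr_b, fs, transient, drift, noise_sd = 0)
  if (!is.null(shared_band)) {
    bp <- signal::butter(2, shared_band / (fs / 2), type = "pass")
    clean_a$signal <- signal::filtfilt(bp, clean_a$signal)
    clean_b$signal <- signal::filtfilt(bp, clean_b$signal)
  }
  noise <- function(offs) {
    if (noise_sd > 0) {
      with_seed(seed + offs, stats::rnorm(length(clean_a$signal),
                                          sd = noise_sd))
    } else 0
  }
  a <- calcium_trace(clean_a$signal + noise(0), fs)
  b <- calcium_trace(clean_b$signal + noise(1), fs)
  attr(a, "ground_truth") <- tr_a
  attr(b, "ground_truth") <- tr_b
  structure(list(a = a, b = b), lag = lag)
}
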