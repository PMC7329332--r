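test_that("downsampling averages adjacent sample pairs", {
  tr <- calcium_trace(c(1, 1, 2, 2), fs = 2000)
  down <- downsample_mean2(tr)
  expect_equal(down$signal, c(1, 2))
  expect_equal(down$fs, 1000)

  const <- downsample_mean2(calcium_trace(rep(3.5, 100), fs = 2000))
  expect_true(all(const$signal == 3.5))

  # mean preserved exactly (arithmetic identity)
  set.seed(1)
  x <- rnorm(1000)
  expect_equal(mean(downsample_mean2(calcium_trace(x, 2000))$signal),
               mean(x))

  expect_message(downsample_mean2(calcium_trace(rnorm(11), 2000)),
                 "trailing sample")
})

test_that("baseline correction removes slow drift but keeps transients", {
  fs <- 500
  t <- (0:(300 * fs - 1)) / fs
  # pure slow sinusoid (period 100 s) is attenuated at least 10x
  drift <- 2 * sin(2 * pi * t / 100)
  corr <- correct_baseline(calcium_trace(drift, fs), window_samples = 2500)
  expect_lt(max(abs(corr$signal)), 0.1 * 2)

  # flat signal + one transient: peak height preserved within 10%
  tr <- event_train(150, 1, 300)
  ct <- gen_calcium_trace(tr, fs = fs,
                          transient = list(rise_tau = 0.05, decay_tau = 0.4,
                                           amplitude = 1))
  corr2 <- correct_baseline(ct, window_samples = 2500)
  expect_equal(max(corr2$signal), 1, tolerance = 0.1)

  # zero in, zero out
  z <- correct_baseline(calcium_trace(numeric(10000), fs), 2500)
  expect_true(all(abs(z$signal) < 1e-12))

  expect_error(correct_baseline(calcium_trace(rnorm(100), fs), 2500),
               "smaller than the signal length")
})

test_that("dF/F conversion behaves as (signal - f0)/f0", {
  tr <- calcium_trace(rep(2, 100), fs = 100)
  expect_true(all(compute_dff(tr, f0 = 2)$signal == 0))

  x <- rep(1, 100)
  x[50] <- 2
  expect_equal(compute_dff(calcium_trace(x, 100), f0 = 1)$signal[50], 1)

  # percentile f0 matches the same value passed explicitly
  set.seed(2)
  y <- abs(rnorm(1000)) + 1
  tr2 <- calcium_trace(y, 100)
  f0 <- quantile(y, 0.1, names = FALSE)
  expect_equal(compute_dff(tr2)$signal, compute_dff(tr2, f0 = f0)$signal)

  expect_error(compute_dff(calcium_trace(rnorm(100), 100), f0 = -1),
               "positive")
})

test_that("detection applies merge, duration and intensity rules in order", {
  fs <- 1000
  params <- detection_params(ema_fast_tau = 0.02, ema_slow_tau = 2)
  burst <- function(t0, dur, x, fs) {
    i <- (round(t0 * fs) + 1):round((t0 + dur) * fs)
    x[i] <- 1
    x
  }
  # two 0.2 s bursts, 0.4 s apart: merged into one wave (< 500 ms rule);
  # min-duration-first would instead have discarded both sub-waves
  # (trace kept short so the percentile amplitude scale sees the bursts)
  x <- numeric(20 * fs)
  x <- burst(10, 0.2, x, fs)
  x <- burst(10.6, 0.2, x, fs)
  ev <- detect_slow_waves(calcium_trace(x, fs), params)
  expect_length(ev$onsets, 1)
  expect_gte(ev$offsets[1] - ev$onsets[1], 0.3)

  # each sub-burst alone is below the minimum duration: applying the
  # duration rule before merging would have returned zero events
  x1 <- burst(10, 0.2, numeric(20 * fs), fs)
  ev1 <- detect_slow_waves(calcium_trace(x1, fs), params)
  expect_length(ev1$onsets, 0)

  # a single 0.25 s burst is discarded (< 300 ms rule)
  y <- burst(10, 0.25, numeric(20 * fs), fs)
  expect_length(detect_slow_waves(calcium_trace(y, fs), params)$onsets, 0)

  # constant signal: empty list, no error
  expect_length(detect_slow_waves(calcium_trace(rep(1, 5000), fs))$onsets, 0)
})

test_that("detector recovers synthetic events at SNR 10", {
  for (s in 1:10) {
    ct <- fixture_trace_with_events(snr = 10, seed = s)
    truth <- attr(ct, "ground_truth")
    ev <- detect_slow_waves(correct_baseline(ct, 2500))
    matched <- sum(vapply(truth$onsets, function(o) {
      any(abs(ev$onsets - o) < 0.5)
    }, logical(1)))
    spurious <- sum(vapply(ev$onsets, function(o) {
      !any(abs(truth$onsets - o) < 0.5)
    }, logical(1)))
    expect_gte(matched / length(truth$onsets), 0.95)
    expect_lte(spurious, 1)
  }
})

test_that("raising the onset threshold never increases the event count", {
  for (s in 1:5) {
    ct <- fixture_trace_with_events(snr = 5, seed = 40 + s)
    corr <- correct_baseline(ct, 2500)
    counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(f) {
      length(detect_slow_waves(corr, detection_params(
        onset_fraction = f, termination_fraction = 0.5 * f))$onsets)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("dF/F and downsampling commute with event counting", {
  ct <- fixture_trace_with_events(snr = 10, seed = 77, fs = 1000)
  corr <- correct_baseline(ct, 2500)
  n_direct <- length(detect_slow_waves(corr)$onsets)
  n_down <- length(detect_slow_waves(downsample_mean2(corr))$onsets)
  shifted <- calcium_trace(corr$signal + 5, corr$fs)
  n_dff <- length(detect_slow_waves(compute_dff(shifted, f0 = 5))$onsets)
  expect_lte(abs(n_direct - n_down), 1)
  expect_lte(abs(n_direct - n_dff), 1)
})

test_that("transition counts tile the recording into 3-min windows", {
  ev <- sw_events(c(10, 200, 250, 500, 1700), c(11, 201, 251, 501, 1701),
                  rep(1, 5), 1000)
  counts <- count_transitions(ev, 180, 60, 1800)
  expect_length(counts, 7)
  expect_equal(attr(counts, "window_starts"), (0:6) * 240)
  # onsets at 10 (window 1), 200 (in the gap), 250 and 500 (windows 2-3),
  # 1700 (after the last full window)
  expect_equal(as.integer(counts), c(1L, 1L, 1L, 0L, 0L, 0L, 0L))

  # empty list: zeros
  none <- sw_events(numeric(0), numeric(0), numeric(0), 1000)
  expect_true(all(count_transitions(none, 180, 60, 1800) == 0))

  # boundary convention: onset exactly at a window start belongs to it,
  # onset exactly at a window end does not
  edge <- sw_events(c(180, 240), c(181, 241), c(1, 1), 1000)
  ce <- count_transitions(edge, 180, 60, 1800)
  expect_equal(as.integer(ce)[1:2], c(0L, 1L))
})

test_that("event-triggered averages reduce noise as 1/sqrt(n)", {
  fs <- 500
  ct <- fixture_trace_with_events(n_events = 20, snr = 5, seed = 3, fs = fs)
  truth <- attr(ct, "ground_truth")
  ev <- sw_events(truth$onsets, truth$onsets + truth$durations,
                  rep(1, length(truth$onsets)), fs)
  eta <- event_triggered_average(ct, ev, pre_window = 1, post_window = 2)
  expect_length(eta$mean, 3 * fs + 1)
  # pre-onset tail is nearly flat: residual noise ~ sigma/sqrt(n)
  pre <- eta$mean[1:(0.5 * fs)]
  expect_lt(sd(pre), 3 * (1 / 5) / sqrt(eta$n_events))

  # single noiseless event: average equals the snippet
  tr1 <- event_train(10, 1, 30)
  ct1 <- gen_calcium_trace(tr1, fs = fs)
  ev1 <- sw_events(10, 11, 1, fs)
  eta1 <- event_triggered_average(ct1, ev1, 1, 2)
  i0 <- round(9 * fs) + 1
  expect_equal(eta1$mean, ct1$signal[i0:(i0 + 3 * fs)])

  expect_error(event_triggered_average(ct1, sw_events(0.1, 0.2, 1, fs),
                                       1, 2),
               "no usable events")
})
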