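test_that("event trains respect rate, gaps and bounds", {
  expect_error(gen_event_train(0, 600), "rate > 0")
  expect_error(gen_event_train(2, 600, min_gap = 2), "infeasible rate")

  # vanishing rate: empty train is a valid outcome
  tr0 <- gen_event_train(1e-6, 600, seed = 4)
  expect_s3_class(tr0, "event_train")
  expect_length(tr0$onsets, 0)

  # count stays inside the Poisson 99% interval around rate * duration
  # (thinning at min_gap = 0 with sparse events removes almost nothing)
  tr <- gen_event_train(0.2, 600, min_gap = 0, seed = 7)
  expect_gte(length(tr$onsets), qpois(0.005, 120))
  expect_lte(length(tr$onsets), qpois(0.995, 120))

  for (s in 1:5) {
    tr <- gen_event_train(0.2, 600, min_gap = 2, seed = s)
    gaps <- tr$onsets[-1] - (tr$onsets + tr$durations)[-length(tr$onsets)]
    expect_true(all(gaps >= 2))
    expect_true(all(tr$onsets + tr$durations <= 600))
    expect_true(all(diff(tr$onsets) > 0))
  }

  # determinism
  expect_identical(gen_event_train(0.2, 600, seed = 3),
                   gen_event_train(0.2, 600, seed = 3))
})

test_that("calcium transients peak at the double-exponential maximum", {
  rise <- 0.05
  decay <- 0.4
  tstar <- rise * decay / (decay - rise) * log(decay / rise)
  tr <- event_train(10, 1, 60)
  ct <- gen_calcium_trace(tr, fs = 1000,
                          transient = list(rise_tau = rise, decay_tau = decay,
                                           amplitude = 2))
  peak_i <- which.max(ct$signal)
  expect_equal((peak_i - 1) / 1000, 10 + tstar, tolerance = 2 / 1000)
  expect_equal(max(ct$signal), 2, tolerance = 1e-3)

  # empty train, no drift, no noise: flat zero
  ct0 <- gen_calcium_trace(event_train(numeric(0), numeric(0), 30), fs = 500)
  expect_true(all(ct0$signal == 0))

  # ground truth carried along equals the train exactly
  expect_identical(attr(ct, "ground_truth"), tr)
})

test_that("dual-site traces delay the second site by separation/speed", {
  tr <- gen_event_train(0.1, 120, seed = 5)
  same <- gen_dual_site_traces(tr, separation = 0, fs = 500)
  expect_equal(same$a$signal, same$b$signal)

  pair <- gen_dual_site_traces(tr, separation = 2.048, wave_speed = 51.2,
                               fs = 500)
  expect_equal(attr(pair, "lag"), 0.040)
  gt_a <- attr(pair$a, "ground_truth")
  gt_b <- attr(pair$b, "ground_truth")
  expect_equal(gt_b$onsets - gt_a$onsets,
               rep(0.040, length(gt_a$onsets)))

  # self-consistency with the cross-correlation estimator on clean traces
  x <- xcorr_peak(pair$a, pair$b, max_lag = 0.5)
  expect_equal(x$lag, 0.040, tolerance = 1 / 500 + 1e-9)
})

test_that("persistent-state construction yields the designed correlations", {
  # c = 1, no noise: within-module r = 1, between-module r ~ 0
  d <- gen_bold_state_dataset("persistent", n_rois = 12, dt = 1.5,
                              total_duration = 900,
                              module_map = rep(1:2, each = 6),
                              within_module_corr = 1 - 1e-9,
                              secondary_corr = 0, noise_sd = 0,
                              nuisance_coupling = 0, seed = 2)
  r <- cor(t(d$ts$data))
  within <- r[1:6, 1:6][upper.tri(r[1:6, 1:6])]
  between <- r[1:6, 7:12]
  expect_true(all(within > 0.999))
  expect_lt(mean(abs(between)), 0.15)

  # c = 0.5: mean within-module empirical r ~ 0.5 across seeds
  mean_r <- sapply(1:10, function(s) {
    d <- gen_bold_state_dataset("persistent", n_rois = 12, dt = 1.5,
                                total_duration = 1200,
                                module_map = rep(1:2, each = 6),
                                within_module_corr = 0.5,
                                secondary_corr = 0, noise_sd = 0,
                                nuisance_coupling = 0, seed = 100 + s)
    r <- cor(t(d$ts$data))
    mean(r[1:6, 1:6][upper.tri(r[1:6, 1:6])])
  })
  expect_equal(mean(mean_r), 0.5, tolerance = 0.1)
})

test_that("persistent datasets separate within- from between-module r", {
  ok <- sapply(1:10, function(s) {
    d <- gen_bold_state_dataset("persistent", n_rois = 24, dt = 1.5,
                                total_duration = 900,
                                module_map = rep(1:4, 6),
                                within_module_corr = 0.3, noise_sd = 0.8,
                                seed = 200 + s)
    r <- cor(t(d$ts$data))
    same <- outer(d$gt$module_of_roi, d$gt$module_of_roi, "==")
    ut <- upper.tri(r)
    mean(r[ut & same]) > mean(abs(r[ut & !same]))
  })
  expect_true(all(ok))
})

test_that("slow-wave correlations decrease with inter-ROI distance", {
  rho <- sapply(1:10, function(s) {
    d <- gen_bold_state_dataset("slow_wave", n_rois = 48, dt = 1.5,
                                total_duration = 900, seed = 300 + s)
    r <- cor(t(d$ts$data))
    D <- as.matrix(dist(d$ts$centroids))
    ut <- upper.tri(r)
    cor(r[ut], D[ut], method = "spearman")
  })
  expect_true(all(rho < 0))
})

test_that("doubling the event rate increases significant-pair counts", {
  # sparse transition regime with purely independent noise isolates the
  # wave-driven connectivity: more down-up transitions means more shared
  # BOLD variance, hence more supra-cutoff pairs (at dense rates the
  # hemodynamic responses fuse and the effect saturates)
  more <- sapply(1:5, function(s) {
    counts <- sapply(c(0.025, 0.05), function(rate) {
      d <- gen_bold_state_dataset("slow_wave", n_rois = 48,
                                  total_duration = 900,
                                  event_rate = rate, rate_drift_depth = 0,
                                  spatial_share = 0, seed = 400 + s)
      partial_corr_matrix(d$ts, c("breathing", "vwm"))$n_sig_pairs
    })
    counts
  })
  expect_true(all(more[2, ] > more[1, ]))
})

test_that("cohorts are reproducible and per-subject independent", {
  a <- gen_cohort(3, "persistent", shared_params = list(n_rois = 10,
                                                        total_duration = 300),
                  seed = 9)
  b <- gen_cohort(3, "persistent", shared_params = list(n_rois = 10,
                                                        total_duration = 300),
                  seed = 9)
  expect_identical(a, b)
  expect_error(gen_cohort(1, "persistent"), "n_subjects")
  seeds <- vapply(a, function(d) d$gt$seed, numeric(1))
  expect_length(unique(seeds), 3)
  # distinct seeds give distinct data
  expect_false(identical(a[[1]]$ts$data, a[[2]]$ts$data))
})

test_that("short recordings are rejected", {
  expect_error(gen_bold_state_dataset("persistent", n_rois = 6, dt = 1.5,
                                      total_duration = 60),
               "fewer than 120")
})
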