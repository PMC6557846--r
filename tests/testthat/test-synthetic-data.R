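test_that("noiseless generation integrates the drift exactly", {
  # constant drift 1, no noise: z(t_i) = t_i up to one Euler step
  cfg <- synth_config(drift_coeffs = 1, noise_coeffs = 0, amplitude_scale = 1)
  x <- generate_trial(cfg, 1, 1)$samples[[1]]
  t_i <- (seq_along(x) - 1) / cfg$fs
  expect_equal(length(x), 750L)
  expect_lt(max(abs(x - t_i)), 1 / cfg$fs)
  # zero drift, zero noise: identically zero
  cfg0 <- synth_config(drift_coeffs = 0, noise_coeffs = 0, amplitude_scale = 1)
  expect_true(all(generate_trial(cfg0, 1, 1)$samples[[1]] == 0))
})

test_that("OU ground truth reaches the closed-form stationary variance", {
  # dz = -z dt + dW has stationary variance 1/2; long single trial,
  # discard the relaxation transient
  cfg <- synth_config(drift_coeffs = c(-1, 0), noise_coeffs = 1,
                      amplitude_scale = 1, epoch_duration = 2000,
                      event_latency = 1000, seed = 8)
  z <- generate_trial(cfg, 1, 1)$samples[[1]]
  z <- z[-(1:2500)]
  expect_equal(var(z), 0.5, tolerance = 0.1)
})

test_that("dataset generation is deterministic, complete, and gain-linear", {
  cfg <- synth_config(n_trials = 5, n_channels = 2, channel_gains = c(1, 2),
                      seed = 11)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_equal(nrow(d1), 10L)
  expect_true(all(lengths(d1$samples) == 750L))
  expect_identical(d1$samples, d2$samples)
  # channels share the latent path: gain 2 means exactly twice channel 1
  for (tr in 1:5) {
    a <- d1$samples[[which(d1$channel_id == "MEG001" & d1$trial_index == tr)]]
    b <- d1$samples[[which(d1$channel_id == "MEG002" & d1$trial_index == tr)]]
    expect_identical(b, 2 * a)
  }
  # every (channel, trial) pair unique
  expect_equal(anyDuplicated(d1[c("subject_id", "channel_id", "trial_index")]), 0L)
})

test_that("amplitude scale is an exact multiplicative factor", {
  cfg1 <- synth_config(n_trials = 2, seed = 5, amplitude_scale = 1)
  cfgk <- synth_config(n_trials = 2, seed = 5, amplitude_scale = 3.5)
  d1 <- generate_dataset(cfg1)
  dk <- generate_dataset(cfgk)
  expect_identical(dk$samples[[1]], 3.5 * d1$samples[[1]])
})

test_that("per-trial substreams are independent of iteration order", {
  cfg <- synth_config(n_trials = 6, seed = 21)
  d <- generate_dataset(cfg)
  # regenerating trial 4 alone reproduces the dataset's trial 4
  ep <- generate_trial(cfg, 1, 4)
  expect_identical(ep$samples[[1]],
                   d$samples[[which(d$trial_index == 4)]])
})

test_that("config validation rejects inconsistent geometry", {
  expect_error(synth_config(fs = 250, epoch_duration = 1.001), "integer sample")
  expect_error(synth_config(n_trials = 0), ">= 1")
  expect_error(synth_config(amplitude_scale = -1), "positive")
  expect_error(synth_config(n_channels = 2, channel_gains = c(1, 2, 3)),
               "channel_gains")
})

test_that("epoch cropping keeps the half-open window and realigns t0", {
  cfg <- synth_config(n_trials = 2, seed = 3)
  d <- generate_dataset(cfg) # window -2.5 .. 0.5, t0_index 626
  cropped <- crop_epochs(d, c(-1, 0))
  expect_equal(length(cropped$samples[[1]]), 250L)
  t0 <- attr(cropped, "t0_index")
  # event time falls just past the final retained sample
  expect_equal(t0, 251L)
  full <- d$samples[[1]]
  expect_identical(cropped$samples[[1]], full[376:625])
  expect_error(crop_epochs(d, c(5, 6)), "window")
})

test_that("inverse-Gaussian sampler matches its moments and refits", {
  w <- waiting_times(generate_ig_wt_sample(5.95, 21.96, 1e5, seed = 2))
  expect_true(all(w > 0))
  se_mean <- sqrt(5.95^3 / 21.96) / sqrt(1e5)
  expect_lt(abs(mean(w) - 5.95), 3 * se_mean)
  # degenerate limit: enormous shape concentrates at the mean
  wd <- waiting_times(generate_ig_wt_sample(2, 1e9, 1e4, seed = 3))
  expect_lt(sd(wd), 1e-3)
  expect_equal(mean(wd), 2, tolerance = 1e-4)
  # MLE refit recovers both parameters within 3 asymptotic SEs
  w2 <- generate_ig_wt_sample(7.01, 22.55, 1e5, seed = 4)
  fit <- fit_inverse_gaussian(w2)
  expect_lt(abs(fit$mu - 7.01), 3 * sqrt(7.01^3 / (22.55 * 1e5)))
  expect_lt(abs(fit$lambda - 22.55), 3 * 22.55 * sqrt(2 / 1e5))
})

test_that("dataset CSV + JSON sidecar round trip preserves the data", {
  cfg <- synth_config(n_trials = 3, n_channels = 2, seed = 13)
  d <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  expect_true(file.exists(file.path(dir, "dataset.json")))
  d2 <- read_dataset(dir)
  expect_equal(d2$samples, d$samples, tolerance = 1e-12)
  expect_equal(attr(d2, "fs"), 250)
  expect_equal(attr(d2, "t0_index"), attr(d, "t0_index"))
  expect_equal(d2$channel_id, d$channel_id)
})
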