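test_that("concatenation preserves values and records boundaries", {
  cs <- concatenate_trials(list(c(1, 2), c(3, 4)))
  expect_equal(cs$series, c(1, 2, 3, 4))
  expect_equal(cs$starts, c(1L, 3L))
  one <- concatenate_trials(list(c(5, 6, 7)))
  expect_equal(one$series, c(5, 6, 7))
  expect_equal(one$starts, 1L)
})

test_that("degenerate constant input cannot be binned", {
  expect_error(estimate_km_field(rep(3, 1000), fs = 250), "degenerate")
})

test_that("a deterministic ramp gives A1 = tau and A2 = tau^2 exactly", {
  x <- seq(0, 3, by = 1 / 250)
  f <- estimate_km_field(x, fs = 250)
  occ <- dplyr::filter(f$moments, n > 0)
  expect_equal(occ$A1, occ$tau, tolerance = 1e-12)
  expect_equal(occ$A2, occ$tau^2, tolerance = 1e-12)
  # so the extrapolated drift is 1 everywhere it is defined
  b <- f$bins[is.finite(f$bins$D1), ]
  expect_equal(b$D1, rep(1, nrow(b)), tolerance = 1e-8)
})

test_that("lag-zero extrapolation recovers linear rates", {
  taus <- (1:10) / 250
  expect_equal(extrapolate_moment(2 * taus, taus), 2, tolerance = 1e-10)
  # order-2 fit removes quadratic bias exactly
  expect_equal(extrapolate_moment(2 * taus + 3 * taus^2, taus), 2,
               tolerance = 1e-8)
  expect_true(is.na(extrapolate_moment(rep(NA_real_, 10), taus)))
})

test_that("extrapolation under observation noise is unbiased at the derived precision", {
  # Monte-Carlo of the derived example: noise sd 1e-3 on the 10 default lags
  # gives a rate error of scale ~5e-2 (the fit's standard error)
  taus <- (1:10) / 250
  errs <- withr::with_seed(31, {
    vapply(1:200, function(i) {
      extrapolate_moment(2 * taus + 3 * taus^2 + rnorm(10, sd = 1e-3), taus) - 2
    }, numeric(1))
  })
  expect_lt(abs(mean(errs)), 3 * 0.052 / sqrt(200)) # unbiased
  expect_lt(sqrt(mean(errs^2)), 0.08)               # precision scale
})

test_that("binned moments match an exhaustive brute-force oracle exactly", {
  set.seed(17)
  trials <- list(cumsum(rnorm(160)), cumsum(rnorm(160)))
  taus <- (1:4) / 100
  f <- estimate_km_field(trials, fs = 100, n_bins = 12, taus = taus,
                         min_count = 1)
  oracle <- brute_force_moments(trials, f$edges, lags = 1:4)
  for (j in 1:4) {
    got <- dplyr::filter(f$moments, tau == taus[j])
    expect_identical(got$n, as.numeric(oracle[[j]]$n))
    expect_equal(got$A1, oracle[[j]]$A1, tolerance = 1e-12)
    expect_equal(got$A2, oracle[[j]]$A2, tolerance = 1e-12)
  }
})

test_that("no moment pair straddles a trial boundary", {
  # two flat trials at wildly different levels: any straddling pair would
  # produce an increment of ~200 and blow up the second moment
  set.seed(4)
  t1 <- 100 + rnorm(200, sd = 0.1)
  t2 <- -100 + rnorm(200, sd = 0.1)
  f <- estimate_km_field(list(t1, t2), fs = 250, n_bins = 10, min_count = 1)
  occ <- dplyr::filter(f$moments, n > 0)
  expect_lt(max(occ$A2), 1) # pure within-trial noise, never ~200^2
  # identical estimates when passed as a concat_series
  f2 <- estimate_km_field(concatenate_trials(list(t1, t2)), fs = 250,
                          n_bins = 10, min_count = 1)
  expect_equal(f2$moments$A1, f$moments$A1)
})

test_that("exact polynomial fields are fitted exactly", {
  centers <- seq(-2, 2, length.out = 40)
  fake <- structure(list(
    bins = tibble::tibble(
      bin = seq_along(centers), center = centers,
      count = rep(100, 40),
      D1 = 3 * centers + 1,
      D2 = (centers^2 + 1)^2,
      valid = TRUE, valid_h = TRUE
    ),
    taus = (1:10) / 250, fs = 250, n_samples = 4000, n_trials = 1
  ), class = "km_field")
  m <- fit_langevin_model(fake, degree_g = 1, degree_h = 2)
  expect_equal(m$drift_coeffs, c(3, 1), tolerance = 1e-10)
  expect_equal(m$noise_coeffs, c(1, 0, 1), tolerance = 1e-10)
  expect_error(fit_langevin_model(fake, degree_g = 41), "insufficient")
})

test_that("OU reconstruction recovers slope and noise and tightens with n", {
  run_ou <- function(n_samples, seed) {
    cfg <- synth_config(drift_coeffs = c(-1, 0), noise_coeffs = 1,
                        amplitude_scale = 1, n_trials = 1,
                        epoch_duration = n_samples / 250,
                        event_latency = n_samples / 500, seed = seed)
    d <- generate_dataset(cfg)
    reconstruct(d, "concatenated", degree_g = 1, degree_h = 0)$model[[1]]
  }
  m_big <- run_ou(1e5, 42)
  expect_equal(m_big$drift_coeffs[1], -1, tolerance = 0.1)
  expect_equal(m_big$noise_coeffs[1], 1, tolerance = 0.1)
  # consistency: mean absolute slope error shrinks from 1e4 to 1e6 samples
  err_at <- function(n) {
    mean(vapply(1:3, function(s) abs(run_ou(n, 40 + s)$drift_coeffs[1] + 1),
                numeric(1)))
  }
  expect_lt(err_at(1e6), err_at(1e4))
})

test_that("pure Brownian input yields zero drift slope and the right noise", {
  cfg <- synth_config(drift_coeffs = 0, noise_coeffs = 2, amplitude_scale = 1,
                      n_trials = 1, epoch_duration = 400, event_latency = 200,
                      seed = 6)
  d <- generate_dataset(cfg)
  m <- reconstruct(d, "concatenated", degree_g = 1, degree_h = 0)$model[[1]]
  expect_lt(abs(m$drift_coeffs[1]), 0.15)
  expect_equal(m$noise_coeffs[1], 2, tolerance = 0.1)
})

test_that("rescaling the input transforms fitted coefficients covariantly", {
  cfg <- synth_config(n_trials = 10, amplitude_scale = 1, seed = 19)
  d <- generate_dataset(cfg)
  k <- 1e-9
  dk <- generate_dataset(synth_config(n_trials = 10, amplitude_scale = k,
                                      seed = 19))
  m1 <- reconstruct(d, "concatenated", degree_g = 1, degree_h = 0)$model[[1]]
  mk <- reconstruct(dk, "concatenated", degree_g = 1, degree_h = 0)$model[[1]]
  # x -> kx: slope invariant, constant drift and noise scale by k
  expect_equal(mk$drift_coeffs[1], m1$drift_coeffs[1], tolerance = 1e-6)
  expect_equal(mk$drift_coeffs[2], k * m1$drift_coeffs[2], tolerance = 1e-6)
  expect_equal(mk$noise_coeffs[1], k * m1$noise_coeffs[1], tolerance = 1e-6)
})

test_that("reconstruction modes keep their bookkeeping contracts", {
  cfg <- synth_config(n_trials = 4, amplitude_scale = 1, seed = 23)
  d <- generate_dataset(cfg)
  st <- reconstruct(d, "single_trial", degree_g = 1, degree_h = 0,
                    min_count = 5)
  expect_equal(nrow(st), 4L)
  expect_equal(st$trial_index, 1:4)
  # pooling identical copies of one epoch is invariant to duplication
  one <- d[d$trial_index == 1, ]
  one3 <- d[c(1, 1, 1), ]
  one3$trial_index <- 1:3
  mk_ds <- function(df) accubound:::new_trial_dataset(
    df, fs = attr(d, "fs"), t0_index = attr(d, "t0_index"),
    window = attr(d, "window")
  )
  p1 <- reconstruct(mk_ds(one), "pooled", degree_g = 1, degree_h = 0,
                    min_count = 5)$model[[1]]
  p3 <- reconstruct(mk_ds(one3), "pooled", degree_g = 1, degree_h = 0,
                    min_count = 5)$model[[1]]
  expect_equal(p3$drift_coeffs, p1$drift_coeffs, tolerance = 1e-10)
  expect_equal(p3$noise_coeffs, p1$noise_coeffs, tolerance = 1e-10)
  expect_error(reconstruct(d[0, ], "pooled"), "empty")
})
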