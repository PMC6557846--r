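#' Configuration for the synthetic MEG-like epoch generator
#'
#' Defines a ground-truth polynomial Langevin process and the recording
#' geometry of a trial-epoched dataset: the generator integrates
#' `dz/dt = P_G(z) + P_H(z) Gamma(t)` at the recording resolution
#' (Euler-Maruyama, one step per sample, Ito convention) and maps the latent
#' state to Tesla through `amplitude_scale` and a per-channel gain. All
#' channels of one (subject, trial) share a single latent path, so channels
#' differ only by gain (plus optional independent sensor noise) -- the
#' idealized picture of one neural source seen by many sensors.
#'
#' Defaults emulate the study conditions the package targets: 250 Hz
#' sampling, 3-s epochs of 750 samples with the movement event 2.5 s into
#' the epoch, 60 trials per subject, and `amplitude_scale = 1e-13` so
#' model-unit dynamics of order one map to ~100 fT signals (the inverse of
#' the `z = 1e13 x` evidence scaling). The default ground truth is the
#' printed leaky-stochastic-accumulator model (drift `-0.29 z + 1.43`,
#' constant noise amplitude `1.78`).
#'
#' @param drift_coeffs,noise_coeffs Ground-truth polynomial coefficients,
#'   highest-degree-first (model units).
#' @param n_subjects,n_trials,n_channels Dataset dimensions.
#' @param fs Sampling rate, Hz.
#' @param epoch_duration Epoch length, seconds; `epoch_duration * fs` must be
#'   a whole number of samples.
#' @param event_latency Event (button-press) time from epoch start, seconds.
#' @param amplitude_scale Tesla per model unit.
#' @param channel_gains Per-channel multiplicative gains (length
#'   `n_channels`, recycled from length 1).
#' @param z0 Initial latent state of every trial (model units).
#' @param sensor_noise_sd Standard deviation of independent white sensor
#'   noise per channel, in model units before `amplitude_scale`; 0 disables.
#' @param erf_peak Peak amplitude (model units) of an optional deterministic
#'   ramp-and-collapse event-related template added to the latent state:
#'   linear rise from 0 at epoch start to `erf_peak` at the event, linear
#'   decay back to 0 at epoch end. 0 (default) disables it; reconstruction
#'   tests use the pure Langevin process.
#' @param seed Master seed; every epoch is generated on its own substream,
#'   so regeneration of any single trial is independent of iteration order.
#'
#' @return A list of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_trials = 5, n_channels = 2, seed = 42)
#' dat <- generate_dataset(cfg)
#' dat
#' @export
synth_config <- function(drift_coeffs = c(-0.29, 1.43),
                         noise_coeffs = 1.78,
                         n_subjects = 1L,
                         n_trials = 60L,
                         n_channels = 1L,
                         fs = 250,
                         epoch_duration = 3,
                         event_latency = 2.5,
                         amplitude_scale = 1e-13,
                         channel_gains = 1,
                         z0 = 0,
                         sensor_noise_sd = 0,
                         erf_peak = 0,
                         seed = 1L) {
  assert_scalar_number(fs, "fs", positive = TRUE)
  assert_scalar_number(epoch_duration, "epoch_duration", positive = TRUE)
  assert_scalar_number(amplitude_scale, "amplitude_scale", positive = TRUE)
  assert_scalar_number(event_latency, "event_latency")
  n_samples <- epoch_duration * fs
  if (abs(n_samples - round(n_samples)) > 1e-8) {
    abort("`epoch_duration * fs` must be an integer sample count.")
  }
  if (n_subjects < 1 || n_trials < 1 || n_channels < 1) {
    abort("`n_subjects`, `n_trials` and `n_channels` must all be >= 1.")
  }
  if (event_latency < 0 || event_latency > epoch_duration) {
    abort("`event_latency` must lie within the epoch.")
  }
  if (length(channel_gains) == 1L) channel_gains <- rep(channel_gains, n_channels)
  if (length(channel_gains) != n_channels) {
    abort("`channel_gains` must have length 1 or `n_channels`.")
  }
  structure(
    list(
      drift_coeffs = as.numeric(drift_coeffs),
      noise_coeffs = as.numeric(noise_coeffs),
      n_subjects = as.integer(n_subjects),
      n_trials = as.integer(n_trials),
      n_channels = as.integer(n_channels),
      fs = fs,
      epoch_duration = epoch_duration,
      event_latency = event_latency,
      amplitude_scale = amplitude_scale,
      channel_gains = as.numeric(channel_gains),
      z0 = z0,
      sensor_noise_sd = sensor_noise_sd,
      erf_peak = erf_peak,
      seed = as.integer(seed),
      n_samples = as.integer(round(n_samples)),
      t0_index = as.integer(round(event_latency * fs)) + 1L
    ),
    class = "synth_config"
  )
}

# Deterministic ramp-and-collapse template over the epoch (model units).
erf_template <- function(config) {
  if (config$erf_peak == 0) {
    return(rep(0, config$n_samples))
  }
  i <- seq_len(config$n_samples)
  t0 <- config$t0_index
  up <- pmin(1, (i - 1) / max(t0 - 1, 1))
  down <- pmin(1, (config$n_samples - i) / max(config$n_samples - t0, 1))
  config$erf_peak * pmin(up, down)
}

# Latent Langevin path for one (subject, trial), shared by all channels.
latent_path <- function(config, subject, trial) {
  with_substream(
    substream_seed(config$seed, subject, trial),
    cpp_sim_path(config$drift_coeffs, config$noise_coeffs, config$z0,
                 1 / config$fs, config$n_samples - 1L, 0)
  )
}

#' Generate a single synthetic trial epoch
#'
#' Integrates the ground-truth Langevin process at one Euler-Maruyama step
#' per sample and maps the latent state to Tesla. Deterministic given
#' `(seed, subject, channel, trial)`.
#'
#' @param config A [synth_config()].
#' @param channel,trial,subject 1-based indices.
#' @return A one-row tibble with columns `subject_id`, `channel_id`,
#'   `trial_index` and a `samples` list-column (Tesla), plus `fs` and
#'   `t0_index` columns.
#' @examples
#' ep <- generate_trial(synth_config(drift_coeffs = 1, noise_coeffs = 0,
#'                                   amplitude_scale = 1), 1, 1)
#' head(ep$samples[[1]])
#' @export
generate_trial <- function(config, channel, trial, subject = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (channel < 1 || channel > config$n_channels) abort("`channel` out of range.")
  if (trial < 1 || trial > config$n_trials) abort("`trial` out of range.")
  z <- latent_path(config, subject, trial)[seq_len(config$n_samples)]
  z <- z + erf_template(config)
  sens <- if (config$sensor_noise_sd > 0) {
    with_substream(
      substream_seed(config$seed, subject, channel, trial, 7L),
      rnorm(config$n_samples, sd = config$sensor_noise_sd)
    )
  } else {
    0
  }
  x <- config$amplitude_scale * (config$channel_gains[channel] * z + sens)
  tibble(
    subject_id = sprintf("S%02d", subject),
    channel_id = sprintf("MEG%03d", channel),
    trial_index = as.integer(trial),
    samples = list(x),
    fs = config$fs,
    t0_index = config$t0_index
  )
}

new_trial_dataset <- function(df, fs, t0_index, window, units = "T",
                              config = NULL) {
  structure(
    df,
    fs = fs,
    t0_index = t0_index,
    window = window,
    units = units,
    config = config,
    class = c("trial_dataset", class(tibble()))
  )
}

#' Generate a full synthetic trial dataset
#'
#' @param config A [synth_config()].
#' @return A `trial_dataset`: a tibble with one row per epoch
#'   (`n_subjects * n_channels * n_trials` rows), a `samples` list-column in
#'   Tesla, and attributes `fs`, `t0_index`, `window` (epoch start/end in
#'   seconds relative to the event) and the generating `config`.
#' @examples
#' dat <- generate_dataset(synth_config(n_trials = 3, seed = 7))
#' nrow(dat)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rows <- vector("list", config$n_subjects * config$n_trials * config$n_channels)
  i <- 1L
  for (s in seq_len(config$n_subjects)) {
    for (tr in seq_len(config$n_trials)) {
      for (ch in seq_len(config$n_channels)) {
        rows[[i]] <- generate_trial(config, ch, tr, subject = s)
        i <- i + 1L
      }
    }
  }
  df <- list_rbind(rows)
  df <- arrange(df, .data$subject_id, .data$channel_id, .data$trial_index)
  new_trial_dataset(
    df,
    fs = config$fs,
    t0_index = config$t0_index,
    window = c(-config$event_latency,
               config$epoch_duration - config$event_latency),
    config = config
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(
    "<trial_dataset> %d epochs, %d samples each at %g Hz (units %s)\n",
    nrow(x), length(x$samples[[1]]), attr(x, "fs"), attr(x, "units")
  ))
  w <- attr(x, "window")
  cat(sprintf("  epoch window %.3f .. %.3f s relative to event (t0_index %d)\n",
              w[1], w[2], attr(x, "t0_index")))
  NextMethod()
}

#' Crop every epoch to a time window around the event
#'
#' The window is half-open `[start, end)` in seconds relative to the event;
#' sample `i` has time `(i - t0_index) / fs`. Used to restrict epochs to the
#' pre-movement accumulation window (e.g. `c(-3, 0)`) or the reconstruction
#' window (`c(-2.5, 0.5)`).
#'
#' @param dataset A `trial_dataset`.
#' @param window Length-2 numeric, seconds relative to the event.
#' @return A `trial_dataset` with cropped `samples` and updated attributes.
#' @export
crop_epochs <- function(dataset, window) {
  stopifnot(inherits(dataset, "trial_dataset"), length(window) == 2L,
            window[1] < window[2])
  fs <- attr(dataset, "fs")
  t0 <- attr(dataset, "t0_index")
  n <- length(dataset$samples[[1]])
  times <- (seq_len(n) - t0) / fs
  keep <- which(times >= window[1] & times < window[2])
  if (length(keep) == 0) abort("`window` does not overlap the epoch.")
  out <- mutate(as_tibble(dataset), samples = map(.data$samples, ~ .x[keep]))
  new_trial_dataset(
    out,
    fs = fs,
    t0_index = t0 - keep[1] + 1L,
    window = c((keep[1] - t0) / fs, (keep[length(keep)] + 1L - t0) / fs),
    units = attr(dataset, "units"),
    config = attr(dataset, "config")
  )
}

#' Inverse-Gaussian random waiting times
#'
#' Samples from the inverse-Gaussian (Wald) distribution with mean `mu` and
#' shape `lambda` by the Michael-Schucany-Haas transform.
#'
#' @param n Sample size.
#' @param mu Mean, seconds.
#' @param lambda Shape parameter, seconds.
#' @return Numeric vector of `n` positive waiting times.
#' @export
rinvgauss <- function(n, mu, lambda) {
  assert_scalar_number(mu, "mu", positive = TRUE)
  assert_scalar_number(lambda, "lambda", positive = TRUE)
  y <- rnorm(n)^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Generate a synthetic inverse-Gaussian waiting-time sample
#'
#' Convenience wrapper used to exercise the waiting-time fitting machinery
#' against known parameters.
#'
#' @param mu,lambda Inverse-Gaussian mean and shape, seconds.
#' @param n Sample size (`n >= 2`).
#' @param seed Seed for the sampler's substream.
#' @return A `wt_sample` (see [simulate_wt_sample()]) with no censored runs.
#' @export
generate_ig_wt_sample <- function(mu, lambda, n, seed = 1L) {
  if (n < 2) abort("`n` must be at least 2.")
  w <- with_substream(substream_seed(seed, 3L), rinvgauss(n, mu, lambda))
  new_wt_sample(w, n_censored = 0L,
                provenance = list(source = "inverse_gaussian_sampler",
                                  mu = mu, lambda = lambda, seed = seed))
}
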