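#' Simulation settings for first-passage runs
#'
#' @param dt Euler-Maruyama time step, seconds. Default `2^-8` s.
#' @param z0 Initial evidence; every run starts at the same value (default 0).
#' @param n_runs Number of independent runs `N_T` (default 100).
#' @param t_max Cap on simulated time, seconds; runs that have not crossed by
#'   `t_max` are counted as censored. Default 60 s.
#' @param criterion Crossing rule: `"band"` declares a crossing at the first
#'   Euler step with `|z - beta| < band_halfwidth`; `"upcross"` at the first
#'   step with `z >= beta`. The band rule is the reproduction default; note
#'   that with noise amplitude ~1.7 and `dt = 2^-8` the per-step increment
#'   (~0.11) frequently jumps a 0.02-wide band, so band crossings are
#'   detected with delay relative to the first upcrossing.
#' @param band_halfwidth Half-width of the crossing band, evidence units.
#' @param seed Master seed; each run uses a substream keyed by
#'   `(seed, run_index)`, so changing `n_runs` never reshuffles earlier runs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 2^-8, z0 = 0, n_runs = 100L, t_max = 60,
                       criterion = c("band", "upcross"),
                       band_halfwidth = 0.01, seed = 1L) {
  criterion <- match.arg(criterion)
  assert_scalar_number(dt, "dt", positive = TRUE)
  assert_scalar_number(t_max, "t_max", positive = TRUE)
  assert_scalar_number(band_halfwidth, "band_halfwidth", positive = TRUE)
  if (t_max <= dt) abort("`t_max` must exceed `dt`.")
  if (n_runs < 1) abort("`n_runs` must be at least 1.")
  structure(
    list(dt = dt, z0 = z0, n_runs = as.integer(n_runs), t_max = t_max,
         criterion = criterion, band_halfwidth = band_halfwidth,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' One Euler-Maruyama step
#'
#' `z' = z + P_G(z) dt + max(P_H(z), 1e-6) sqrt(dt) * draw` (Ito convention);
#' the floor keeps the SDE defined where a fitted noise polynomial dips to or
#' below zero.
#'
#' @param z Current evidence.
#' @param model A [langevin_model()].
#' @param dt Time step, seconds.
#' @param gaussian_draw A standard-normal draw.
#' @return The updated evidence value.
#' @export
em_step <- function(z, model, dt, gaussian_draw) {
  h <- max(noise_at(model, z), NOISE_EPS)
  z2 <- z + drift_at(model, z) * dt + h * sqrt(dt) * gaussian_draw
  if (!is.finite(z2)) {
    abort(sprintf("non-finite state after step from z = %g with draw = %g",
                  z, gaussian_draw))
  }
  z2
}

#' Simulate an evidence trajectory
#'
#' Euler-Maruyama path of the model without any threshold, useful for
#' spectral analysis of the accumulation process itself.
#'
#' @param model A [langevin_model()].
#' @param n_steps Number of steps.
#' @param dt Time step, seconds.
#' @param z0 Initial state.
#' @param seed Optional seed (substream-isolated); `NULL` uses the current RNG.
#' @return Numeric vector of `n_steps + 1` states including `z0`.
#' @export
simulate_path <- function(model, n_steps, dt = 2^-8, z0 = 0, seed = NULL) {
  run <- function() {
    cpp_sim_path(model$drift_coeffs, model$noise_coeffs, z0, dt,
                 as.integer(n_steps), NOISE_EPS)
  }
  if (is.null(seed)) run() else with_substream(substream_seed(seed, 11L), run())
}

#' First-passage time of a single run
#'
#' @param model A [langevin_model()].
#' @param beta Threshold (evidence units).
#' @param config A [sim_config()].
#' @param run_index 1-based run index selecting the RNG substream.
#' @return Waiting time in seconds (`k * dt` of the first step meeting the
#'   crossing criterion), or `NA` if the run is censored at `t_max`.
#' @export
first_passage <- function(model, beta, config = sim_config(), run_index = 1L) {
  stopifnot(inherits(model, "langevin_model"), is.finite(beta))
  max_steps <- as.integer(floor(config$t_max / config$dt))
  k <- with_substream(
    substream_seed(config$seed, run_index),
    cpp_first_passage(model$drift_coeffs, model$noise_coeffs, beta,
                      config$dt, config$z0, max_steps,
                      config$criterion == "band", config$band_halfwidth,
                      NOISE_EPS)
  )
  if (k == 0L) NA_real_ else k * config$dt
}

new_wt_sample <- function(waiting_times, n_censored, provenance = list()) {
  df <- tibble(
    run = seq_len(length(waiting_times) + n_censored),
    waiting_time = c(waiting_times, rep(NA_real_, n_censored))
  )
  structure(
    df,
    n_censored = as.integer(n_censored),
    provenance = provenance,
    class = c("wt_sample", class(tibble()))
  )
}

#' Simulate a first-passage waiting-time sample
#'
#' Runs `config$n_runs` independent first-passage simulations (per-run RNG
#' substreams) and collects the waiting times. Censored runs (no crossing by
#' `t_max`) are counted and appear as `NA` rows; fitting functions exclude
#' them.
#'
#' @inheritParams first_passage
#' @return A `wt_sample`: tibble with columns `run` and `waiting_time`
#'   (seconds, `NA` when censored) and attribute `n_censored`.
#' @examples
#' lsa <- langevin_model(c(-0.29, 1.43), 1.78)
#' wts <- simulate_wt_sample(lsa, beta = 6.7,
#'                           sim_config(n_runs = 20, seed = 1))
#' fit_inverse_gaussian(wts)
#' @export
simulate_wt_sample <- function(model, beta, config = sim_config()) {
  wt <- map_dbl(seq_len(config$n_runs),
                ~ first_passage(model, beta, config, run_index = .x))
  n_cens <- sum(is.na(wt))
  if (n_cens == config$n_runs) {
    abort(paste0("all ", config$n_runs, " runs were censored at t_max = ",
                 config$t_max, " s; increase `t_max` or reconsider `beta`."))
  }
  new_wt_sample(
    wt[!is.na(wt)], n_cens,
    provenance = list(source = "first_passage", beta = beta, config = config,
                      model = model)
  )
}

#' @export
print.wt_sample <- function(x, ...) {
  w <- x$waiting_time[!is.na(x$waiting_time)]
  cat(sprintf("<wt_sample> %d runs, %d censored; mean WT %.3f s\n",
              nrow(x), attr(x, "n_censored"), mean(w)))
  NextMethod()
}

#' Waiting times as a plain numeric vector (censored runs dropped)
#' @param x A `wt_sample` or numeric vector.
#' @return Numeric vector of positive waiting times.
#' @export
waiting_times <- function(x) {
  if (inherits(x, "wt_sample")) {
    x$waiting_time[!is.na(x$waiting_time)]
  } else {
    as.numeric(x[!is.na(x)])
  }
}

#' @export
autoplot.wt_sample <- function(object, bins = 30, fit = TRUE, ...) {
  df <- tibble(waiting_time = waiting_times(object))
  p <- ggplot(df, aes(.data$waiting_time)) +
    geom_histogram(aes(y = after_stat(.data$density)), bins = bins,
                   fill = "grey70", colour = "grey30") +
    labs(x = "waiting time (s)", y = "density",
         title = "First-passage waiting times")
  if (fit && nrow(df) >= 2 && sd(df$waiting_time) > 0) {
    f <- fit_inverse_gaussian(object)
    grid <- seq(1e-3, max(df$waiting_time) * 1.1, length.out = 400)
    p <- p + geom_line(
      data = tibble(waiting_time = grid,
                    density = ig_pdf(grid, f$mu, f$lambda)),
      aes(y = .data$density), colour = "firebrick"
    )
  }
  p
}
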