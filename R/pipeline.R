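#' Run the full analysis pipeline
#'
#' End-to-end orchestration: generate (or accept) a trial dataset, select
#' the channels most resembling a readiness potential, reconstruct pooled
#' Langevin models per selected channel at both degree sets -- the leaky
#' stochastic accumulator (G = 1, H = 0) and the nonlinear model
#' (G = 3, H = 2) -- optimize the decision threshold of every model against
#' the empirical waiting-time target, pick the globally best model of each
#' type (minimal `E(beta0)` across subjects and channels), compute the L2
#' density distance of each best model to the target, and estimate spectral
#' exponents of the selected channels.
#'
#' @param data A `trial_dataset`, or a [synth_config()] to generate one.
#' @param k Channels to select per subject (capped at the number available).
#' @param target_mu,target_lambda Empirical inverse-Gaussian target `(M, L)`
#'   in seconds; defaults are the empirical waiting-time fit the behavioral
#'   models are optimized against.
#' @param betas Threshold grid for [optimize_threshold()].
#' @param config A [sim_config()]; its seed is substreamed per
#'   (subject, channel, model type).
#' @param window Reconstruction window, seconds relative to the event;
#'   default the pre-movement accumulation window `c(-3, 0)`, intersected
#'   with the epoch.
#' @param scale Evidence scaling applied before reconstruction; `NULL`
#'   (default) uses `1e13` when the dataset is in Tesla, otherwise 1.
#' @param f_range Spectral fit band, Hz.
#' @param seed Master seed for all pipeline randomness.
#' @return An `accubound_run`: list with tibbles `selection`, `models`
#'   (per subject/channel/type fits and scans), `best` (per type, with `D`),
#'   `spectra`, and a `provenance` record.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_trials = 20, n_channels = 2, seed = 5)
#' run <- run_pipeline(cfg, k = 1, betas = seq(4, 8, by = 0.5),
#'                     config = sim_config(n_runs = 50))
#' run$best
#' }
#' @export
run_pipeline <- function(data,
                         k = 5L,
                         target_mu = 5.95,
                         target_lambda = 21.96,
                         betas = seq(2, 8, by = 0.1),
                         config = sim_config(),
                         window = c(-3, 0),
                         scale = NULL,
                         f_range = c(0.5, 40),
                         seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  dataset <- stage("ingest", {
    d <- if (inherits(data, "synth_config")) generate_dataset(data) else data
    stopifnot(inherits(d, "trial_dataset"))
    if (nrow(d) == 0L) abort("empty dataset.")
    d
  })
  if (is.null(scale)) {
    scale <- if (identical(attr(dataset, "units"), "T")) 1e13 else 1
  }

  n_channels <- length(unique(dataset$channel_id))
  selection <- stage("select", select_channels(dataset, min(k, n_channels)))

  epoch_window <- attr(dataset, "window")
  win <- c(max(window[1], epoch_window[1]), min(window[2], epoch_window[2]))

  degree_sets <- tibble(
    model_type = c("lsa", "nonlinear"),
    degree_g = c(1L, 3L),
    degree_h = c(0L, 2L)
  )

  models <- stage("reconstruct_optimize", {
    grid <- tidyr::crossing(selection[c("subject_id", "channel_id")],
                            degree_sets)
    rows <- pmap(grid, function(subject_id, channel_id, model_type,
                                degree_g, degree_h) {
      sub <- dataset[dataset$subject_id == subject_id &
                       dataset$channel_id == channel_id, ]
      sub <- new_trial_dataset(sub, fs = attr(dataset, "fs"),
                               t0_index = attr(dataset, "t0_index"),
                               window = epoch_window,
                               units = attr(dataset, "units"))
      rec <- reconstruct(sub, mode = "pooled", degree_g = degree_g,
                         degree_h = degree_h, window = win, scale = scale)
      model <- rec$model[[1]]
      cfg <- config
      cfg$seed <- substream_seed(seed, match(subject_id, selection$subject_id),
                                 match(channel_id, unique(dataset$channel_id)),
                                 match(model_type, degree_sets$model_type))
      scan <- optimize_threshold(model, target_mu, target_lambda,
                                 betas = betas, config = cfg)
      g <- glance(scan)
      tibble(subject_id = subject_id, channel_id = channel_id,
             model_type = model_type, model = list(model),
             scan = list(scan), beta0 = g$beta0, mu = g$mu,
             lambda = g$lambda, E = g$E)
    })
    list_rbind(rows)
  })

  best <- stage("compare", {
    b <- models |>
      group_by(.data$model_type) |>
      slice_min(.data$E, n = 1, with_ties = FALSE) |>
      ungroup()
    b$D <- purrr::map2_dbl(b$mu, b$lambda, function(m, l) {
      l2_density_distance(c(m, l), c(target_mu, target_lambda))
    })
    b
  })

  spectra <- stage("spectra", {
    rows <- pmap(selection[c("subject_id", "channel_id")],
                 function(subject_id, channel_id) {
      sub <- dataset[dataset$subject_id == subject_id &
                       dataset$channel_id == channel_id, ]
      psds <- map(sub$samples, estimate_psd, fs = attr(dataset, "fs"))
      pow <- Reduce(`+`, map(psds, "power")) / length(psds)
      fit <- fit_spectral_exponent(psds[[1]]$frequency, pow,
                                   f_range = f_range)
      tibble(subject_id = subject_id, channel_id = channel_id,
             alpha = fit$alpha, r_squared = fit$r_squared)
    })
    list_rbind(rows)
  })

  structure(
    list(
      selection = selection,
      models = models,
      best = best,
      spectra = spectra,
      target = c(mu = target_mu, lambda = target_lambda),
      provenance = list(
        seed = seed,
        scale = scale,
        window = win,
        betas = range(betas),
        n_runs = config$n_runs,
        version = as.character(packageVersion("accubound"))
      )
    ),
    class = "accubound_run"
  )
}

#' @export
print.accubound_run <- function(x, ...) {
  cat("<accubound_run>\n")
  cat(sprintf("  %d selected channel(s); target (mu, lambda) = (%.3g, %.3g)\n",
              nrow(x$selection), x$target[1], x$target[2]))
  for (i in seq_len(nrow(x$best))) {
    b <- x$best[i, ]
    cat(sprintf(
      "  best %-9s %s/%s: beta0 = %.2f, mu = %.3g, lambda = %.3g, E = %.3g, D = %.3g\n",
      b$model_type, b$subject_id, b$channel_id, b$beta0, b$mu, b$lambda,
      b$E, b$D
    ))
  }
  cat(sprintf("  mean spectral alpha over selected channels: %.2f\n",
              mean(x$spectra$alpha)))
  invisible(x)
}

#' @export
tidy.accubound_run <- function(x, ...) {
  select(x$models, !c("model", "scan"))
}

#' @export
glance.accubound_run <- function(x, ...) {
  select(x$best, !c("model", "scan"))
}
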