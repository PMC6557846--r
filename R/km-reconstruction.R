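#' Concatenate trial epochs into one composite series
#'
#' Joins the epochs end-to-end while recording trial boundaries, so that
#' downstream conditional-moment estimation never pairs samples across a
#' boundary.
#'
#' @param epochs A `trial_dataset`, a list of numeric vectors, or a single
#'   numeric vector.
#' @return An object of class `concat_series`: list with `series` (the
#'   concatenated values), `starts` (1-based start index of each trial) and
#'   `lengths`.
#' @examples
#' cs <- concatenate_trials(list(c(1, 2), c(3, 4)))
#' cs$series
#' @export
concatenate_trials <- function(epochs) {
  series_list <- as_series_list(epochs)
  lens <- lengths(series_list)
  if (length(unique(lens)) > 1L) {
    # allowed: boundaries make unequal lengths harmless, but flag odd input
    warn("epochs have unequal lengths; trial boundaries are still respected.")
  }
  structure(
    list(series = unlist(series_list, use.names = FALSE),
         starts = cumsum(c(1L, lens[-length(lens)])),
         lengths = lens),
    class = "concat_series"
  )
}

# Normalize the accepted epoch containers to a plain list of numeric vectors.
as_series_list <- function(x) {
  if (inherits(x, "concat_series")) {
    return(purrr::map2(x$starts, x$lengths,
                       ~ x$series[seq(.x, length.out = .y)]))
  }
  if (inherits(x, "trial_dataset")) {
    return(x$samples)
  }
  if (is.numeric(x)) {
    return(list(as.numeric(x)))
  }
  if (is.list(x) && all(vapply(x, is.numeric, logical(1)))) {
    return(lapply(x, as.numeric))
  }
  abort("input must be a numeric series, a list of them, or a trial_dataset.")
}

#' Extrapolate a conditional moment to lag zero
#'
#' Fits `moment(tau) ~ c1 tau + ... + c_order tau^order` (zero intercept) by
#' least squares and returns `c1`, the tau -> 0 rate. The zero intercept
#' enforces `moment(0) = 0` exactly and the quadratic term absorbs the
#' leading finite-lag bias.
#'
#' @param values Moment values at each lag (may contain `NA`).
#' @param taus Lags, seconds.
#' @param order Polynomial order of the fit (default 2).
#' @return The limiting rate in moment-units per second, or `NA` if fewer
#'   than `order` finite points remain.
#' @examples
#' taus <- (1:10) / 250
#' extrapolate_moment(2 * taus + 3 * taus^2, taus)
#' @export
extrapolate_moment <- function(values, taus, order = 2L) {
  ok <- is.finite(values) & is.finite(taus)
  if (sum(ok) < order || length(unique(taus[ok])) < order) {
    return(NA_real_)
  }
  X <- outer(taus[ok], seq_len(order), `^`)
  unname(stats::lm.fit(X, values[ok])$coefficients[1])
}

#' Estimate binned Kramers-Moyal conditional moments
#'
#' The workhorse of Langevin reconstruction. The observed state range is
#' divided into `n_bins` bins; for each bin and each lag `tau` the first and
#' second conditional moments of the increments,
#' `A1 = <x(t+tau) - x(t)>` and `A2 = <(x(t+tau) - x(t))^2>`, are computed
#' over all samples falling in the bin. The drift `D1(x)` and diffusion
#' `D2(x)` are the tau -> 0 limits, obtained per bin by zero-intercept
#' polynomial extrapolation ([extrapolate_moment()]). The final `max(lag)`
#' samples of every trial (the "right boundary") contribute no pairs, and no
#' pair ever straddles a trial boundary.
#'
#' @param x A numeric series, list of trial series, `concat_series`, or
#'   `trial_dataset`.
#' @param fs Sampling rate, Hz (taken from the dataset when available).
#' @param n_bins Number of state bins (default 100).
#' @param taus Lags in seconds; default the 10 values `1/fs ... 10/fs`.
#' @param min_count A bin is valid only if it has at least this many pairs at
#'   every lag (default 10); invalid bins are masked from model fitting.
#' @param order Extrapolation polynomial order (default 2).
#' @param state_range Optional fixed `c(lo, hi)` binning range; by default
#'   the observed range of the input. Supplying a common range lets fields
#'   from different trials of one channel share a binning grid.
#' @return An object of class `km_field`: list with `bins` (tibble of
#'   per-bin `center`, `count`, `D1`, `D2`, `valid`, `valid_h`), `moments`
#'   (tibble of per-bin, per-lag `n`, `A1`, `A2`), `taus`, `fs`, `edges`.
#' @examples
#' x <- seq(0, 3, by = 1 / 250) # deterministic unit ramp
#' f <- estimate_km_field(x, fs = 250)
#' head(tidy(f))
#' @export
estimate_km_field <- function(x, fs = NULL, n_bins = 100L, taus = NULL,
                              min_count = 10L, order = 2L,
                              state_range = NULL) {
  if (inherits(x, "trial_dataset") && is.null(fs)) fs <- attr(x, "fs")
  if (is.null(fs)) abort("`fs` is required unless `x` is a trial_dataset.")
  series_list <- as_series_list(x)
  if (is.null(taus)) taus <- seq_len(10) / fs
  lags <- as.integer(round(taus * fs))
  if (any(lags < 1L)) abort("all lags must be at least one sample.")
  max_lag <- max(lags)
  n_taus <- length(taus)

  all_vals <- unlist(series_list, use.names = FALSE)
  rng <- if (is.null(state_range)) range(all_vals) else as.numeric(state_range)
  if (length(unique(all_vals)) < 2L || rng[1] >= rng[2]) {
    abort("degenerate input: fewer than 2 distinct values, cannot bin.")
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  n_mat <- matrix(0, n_bins, n_taus)
  s1_mat <- matrix(0, n_bins, n_taus)
  s2_mat <- matrix(0, n_bins, n_taus)
  for (y in series_list) {
    L <- length(y)
    if (L <= max_lag) {
      abort(sprintf("series of length %d is too short for max lag %d samples.",
                    L, max_lag))
    }
    idx <- seq_len(L - max_lag) # right boundary excluded for every lag
    b <- findInterval(y[idx], edges, rightmost.closed = TRUE, all.inside = TRUE)
    for (j in seq_len(n_taus)) {
      dx <- y[idx + lags[j]] - y[idx]
      n_mat[, j] <- n_mat[, j] + tabulate(b, n_bins)
      t1 <- rowsum(dx, b)
      t2 <- rowsum(dx^2, b)
      rows <- as.integer(rownames(t1))
      s1_mat[rows, j] <- s1_mat[rows, j] + t1[, 1]
      s2_mat[rows, j] <- s2_mat[rows, j] + t2[, 1]
    }
  }

  A1 <- ifelse(n_mat > 0, s1_mat / n_mat, NA_real_)
  A2 <- ifelse(n_mat > 0, s2_mat / n_mat, NA_real_)
  D1 <- vapply(seq_len(n_bins),
               function(i) extrapolate_moment(A1[i, ], taus, order),
               numeric(1))
  D2_raw <- vapply(seq_len(n_bins),
                   function(i) extrapolate_moment(A2[i, ], taus, order),
                   numeric(1))
  valid <- apply(n_mat >= min_count, 1L, all) & is.finite(D1) &
    is.finite(D2_raw)
  # negative extrapolated diffusion is finite-sample noise: clamp and mask
  valid_h <- valid & (D2_raw > 0)
  D2 <- pmax(D2_raw, 0)

  moments <- tibble(
    bin = rep(seq_len(n_bins), times = n_taus),
    tau = rep(taus, each = n_bins),
    n = as.vector(n_mat),
    A1 = as.vector(A1),
    A2 = as.vector(A2)
  )
  bins <- tibble(
    bin = seq_len(n_bins),
    center = centers,
    count = rowSums(n_mat),
    D1 = D1,
    D2 = D2,
    valid = valid,
    valid_h = valid_h
  )
  structure(
    list(bins = bins, moments = moments, taus = taus, fs = fs, edges = edges,
         min_count = min_count, order = order,
         n_samples = sum(lengths(series_list)),
         n_trials = length(series_list)),
    class = "km_field"
  )
}

#' @export
print.km_field <- function(x, ...) {
  cat(sprintf(
    "<km_field> %d bins (%d valid) from %d samples in %d trial(s); %d lags %.4g..%.4g s\n",
    nrow(x$bins), sum(x$bins$valid), x$n_samples, x$n_trials,
    length(x$taus), min(x$taus), max(x$taus)
  ))
  invisible(x)
}

#' @export
tidy.km_field <- function(x, ...) x$bins

#' @export
glance.km_field <- function(x, ...) {
  tibble(
    n_bins = nrow(x$bins), n_valid = sum(x$bins$valid),
    n_samples = x$n_samples, n_trials = x$n_trials,
    fs = x$fs, min_count = x$min_count
  )
}

#' @export
autoplot.km_field <- function(object, model = NULL, ...) {
  bv <- filter(object$bins, .data$valid)
  bh <- filter(object$bins, .data$valid_h)
  df <- bind_rows(
    tibble(center = bv$center, value = bv$D1, part = "drift D1(x)"),
    tibble(center = bh$center, value = sqrt(bh$D2), part = "noise sqrt(D2(x))")
  )
  p <- ggplot(df, aes(.data$center, .data$value)) +
    geom_point(size = 0.8) +
    facet_wrap(~part, scales = "free_y") +
    labs(x = "state", y = NULL, title = "Reconstructed Langevin functions")
  if (!is.null(model)) {
    rngx <- range(object$bins$center[object$bins$valid])
    z <- seq(rngx[1], rngx[2], length.out = 200)
    fitdf <- bind_rows(
      tibble(center = z, value = drift_at(model, z), part = "drift D1(x)"),
      tibble(center = z, value = noise_at(model, z), part = "noise sqrt(D2(x))")
    )
    p <- p + geom_line(data = fitdf, colour = "firebrick")
  }
  p
}

# Weighted least-squares polynomial fit; returns coefficients
# highest-degree-first (degree + 1 values, constant term included).
fit_poly_wls <- function(x, y, w, degree) {
  ok <- is.finite(x) & is.finite(y) & is.finite(w) & w > 0
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (length(x) < degree + 1L) {
    abort(sprintf(
      "insufficient valid points for a degree-%d fit: have %d, need %d.",
      degree, length(x), degree + 1L
    ))
  }
  X <- outer(x, seq(degree, 0L), `^`)
  fit <- stats::lm.wfit(X, y, w)
  unname(fit$coefficients)
}

#' Fit a polynomial Langevin model to a Kramers-Moyal field
#'
#' Weighted least squares with per-bin total pair counts as weights:
#' the drift polynomial `g` is fit to `D1` against bin centers over valid
#' bins, and the noise polynomial `h` to `sqrt(D2)` over valid bins with
#' positive diffusion.
#'
#' @param field A `km_field`.
#' @param degree_g Drift polynomial degree (1 for the LSA-style linear
#'   drift, 3 for the nonlinear model).
#' @param degree_h Noise polynomial degree (0 for constant noise, 2 for the
#'   nonlinear model).
#' @return A [langevin_model()] with provenance `"field"`.
#' @export
fit_langevin_model <- function(field, degree_g = 1L, degree_h = 2L) {
  stopifnot(inherits(field, "km_field"))
  b <- field$bins
  g_cf <- fit_poly_wls(b$center[b$valid], b$D1[b$valid], b$count[b$valid],
                       degree_g)
  h_cf <- fit_poly_wls(b$center[b$valid_h], sqrt(b$D2[b$valid_h]),
                       b$count[b$valid_h], degree_h)
  langevin_model(
    g_cf, h_cf,
    state_range = range(b$center[b$valid]),
    provenance = list(mode = "field", n_samples = field$n_samples,
                      n_trials = field$n_trials)
  )
}

#' Reconstruct Langevin models from trial-epoched data
#'
#' Three estimation modes, matching the three uses of the conditional-moment
#' method:
#' * `"concatenated"`: all trials are joined (boundaries respected) into one
#'   composite series, one field is estimated and one model fitted. Suits
#'   channel-level description with maximal data (typical degrees G=1, H=2).
#' * `"single_trial"`: a field and model per epoch (typical degrees G=3,
#'   H=2); captures trial-to-trial variation at the cost of noisy fits.
#' * `"pooled"`: a field per epoch, then all valid per-trial
#'   `(bin center, D1)` and `(bin center, sqrt(D2))` points are pooled with
#'   their pair-count weights into a single weighted polynomial fit --
#'   one model per channel built from every trial. This is the mode used for
#'   behavioral (integration-to-bound) model building.
#'
#' @param dataset A `trial_dataset`.
#' @param mode One of `"concatenated"`, `"single_trial"`, `"pooled"`.
#' @param degree_g,degree_h Polynomial degrees of drift and noise.
#' @param window Optional crop window (seconds relative to the event), e.g.
#'   `c(-2.5, 0.5)` for signal-level reconstruction or `c(-3, 0)` for
#'   behavioral-model reconstruction.
#' @param scale Multiplier applied to the samples before estimation, e.g.
#'   `1e13` to convert Tesla-scale recordings into order-one evidence units
#'   (`z = 1e13 x`). Recorded in model provenance.
#' @param n_bins,taus,min_count,order Passed to [estimate_km_field()].
#' @return A tibble with one row per (subject, channel) -- or per epoch for
#'   `"single_trial"` -- and a `model` list-column of [langevin_model()]s.
#' @examples
#' dat <- generate_dataset(synth_config(n_trials = 8, seed = 2,
#'                                      amplitude_scale = 1))
#' reconstruct(dat, mode = "concatenated", degree_g = 1, degree_h = 0)
#' @export
reconstruct <- function(dataset,
                        mode = c("concatenated", "single_trial", "pooled"),
                        degree_g = 1L, degree_h = 2L,
                        window = NULL, scale = 1,
                        n_bins = 100L, taus = NULL, min_count = 10L,
                        order = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "trial_dataset"))
  if (nrow(dataset) == 0L) abort("empty dataset.")
  if (!is.null(window)) dataset <- crop_epochs(dataset, window)
  fs <- attr(dataset, "fs")
  df <- as_tibble(dataset)
  if (scale != 1) df <- mutate(df, samples = map(.data$samples, ~ .x * scale))

  fit_group <- function(series_list, sid, cid, trial_index = NULL) {
    prov <- list(mode = mode, subject_id = sid, channel_id = cid,
                 scale = scale)
    if (mode == "concatenated") {
      field <- estimate_km_field(series_list, fs = fs, n_bins = n_bins,
                                 taus = taus, min_count = min_count,
                                 order = order)
      m <- fit_langevin_model(field, degree_g, degree_h)
      m$provenance <- modifyList(m$provenance, prov)
      return(tibble(subject_id = sid, channel_id = cid, model = list(m)))
    }
    # pooled fields share one binning grid spanning all trials of the
    # channel, so per-trial range extremes do not distort bin placement
    common_range <- if (mode == "pooled") {
      range(unlist(series_list, use.names = FALSE))
    } else {
      NULL
    }
    fields <- map(series_list,
                  ~ estimate_km_field(.x, fs = fs, n_bins = n_bins,
                                      taus = taus, min_count = min_count,
                                      order = order,
                                      state_range = common_range))
    if (mode == "single_trial") {
      models <- map(fields, function(f) {
        m <- fit_langevin_model(f, degree_g, degree_h)
        m$provenance <- modifyList(m$provenance, prov)
        m
      })
      return(tibble(subject_id = sid, channel_id = cid,
                    trial_index = trial_index, model = models))
    }
    # pooled: gather valid per-trial points, one fit
    pts <- map(fields, function(f) {
      b <- f$bins
      list(
        g = tibble(x = b$center[b$valid], y = b$D1[b$valid],
                   w = b$count[b$valid]),
        h = tibble(x = b$center[b$valid_h], y = sqrt(b$D2[b$valid_h]),
                   w = b$count[b$valid_h])
      )
    })
    gp <- list_rbind(map(pts, "g"))
    hp <- list_rbind(map(pts, "h"))
    if (nrow(gp) == 0L) abort("no valid bins in any trial; cannot pool.")
    # pooled points enter unweighted: per-trial occupation counts are
    # correlated with the moment noise in short trials, and count-weighting
    # measurably attenuates the fitted drift (see the methods vignette)
    g_cf <- fit_poly_wls(gp$x, gp$y, rep(1, nrow(gp)), degree_g)
    h_cf <- fit_poly_wls(hp$x, hp$y, rep(1, nrow(hp)), degree_h)
    m <- langevin_model(g_cf, h_cf, state_range = range(gp$x),
                        provenance = c(prov, list(
                          n_trials = length(series_list),
                          n_points = nrow(gp)
                        )))
    tibble(subject_id = sid, channel_id = cid, model = list(m))
  }

  groups <- df |>
    group_by(.data$subject_id, .data$channel_id) |>
    group_split()
  out <- map(groups, function(g) {
    fit_group(g$samples, g$subject_id[1], g$channel_id[1], g$trial_index)
  })
  list_rbind(out)
}
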