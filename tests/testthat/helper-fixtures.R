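# Shared fixtures: the two printed behavioral models and small builders.

lsa_model <- function() {
  langevin_model(c(-0.29, 1.43), 1.78, provenance = list(mode = "manual"))
}

nonlinear_model <- function() {
  langevin_model(c(-0.03, 0.17, 0, 0.81), c(0.01, -0.01, 1.72),
                 provenance = list(mode = "manual"))
}

# Empirical waiting-time target (mu, lambda), seconds.
empirical_target <- c(5.95, 21.96)

# Hand-built trial_dataset from a list of per-channel trial matrices:
# `channels` is a named list, each element a list of numeric trials.
make_dataset <- function(channels, fs = 250, t0_index = NULL) {
  n <- length(channels[[1]][[1]])
  if (is.null(t0_index)) t0_index <- n %/% 2L
  rows <- purrr::imap(channels, function(trials, ch) {
    tibble::tibble(
      subject_id = "S01",
      channel_id = ch,
      trial_index = seq_along(trials),
      samples = trials,
      fs = fs,
      t0_index = t0_index
    )
  })
  df <- purrr::list_rbind(rows)
  accubound:::new_trial_dataset(
    df, fs = fs, t0_index = t0_index,
    window = c(-(t0_index - 1) / fs, (n - t0_index + 1) / fs)
  )
}

# Brute-force conditional-moment oracle: exhaustive pairing per bin,
# independent of the production estimator's accumulation strategy.
brute_force_moments <- function(series_list, edges, lags) {
  n_bins <- length(edges) - 1L
  max_lag <- max(lags)
  out <- list()
  for (j in seq_along(lags)) {
    A1 <- rep(NA_real_, n_bins)
    A2 <- rep(NA_real_, n_bins)
    nn <- rep(0L, n_bins)
    for (b in seq_len(n_bins)) {
      dxs <- c()
      for (y in series_list) {
        for (i in seq_len(length(y) - max_lag)) {
          v <- y[i]
          inbin <- if (b == n_bins) {
            v >= edges[b] & v <= edges[b + 1]
          } else {
            v >= edges[b] & v < edges[b + 1]
          }
          if (inbin) dxs <- c(dxs, y[i + lags[j]] - y[i])
        }
      }
      nn[b] <- length(dxs)
      if (nn[b] > 0) {
        A1[b] <- mean(dxs)
        A2[b] <- mean(dxs^2)
      }
    }
    out[[j]] <- list(n = nn, A1 = A1, A2 = A2)
  }
  out
}
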