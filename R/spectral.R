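#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the series is cut into overlapping
#' segments, each demeaned, Hann-tapered and Fourier transformed; the
#' one-sided density is averaged over segments and normalized so that the
#' integral of the PSD over frequency equals the signal variance
#' (Parseval).
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param segment_length Samples per segment (default 256).
#' @param overlap_fraction Fractional overlap between segments (default 0.5).
#' @return A tibble with columns `frequency` (Hz) and `power` (units^2/Hz).
#' @export
estimate_psd <- function(x, fs, segment_length = 256L,
                         overlap_fraction = 0.5) {
  n <- length(x)
  seg <- as.integer(segment_length)
  if (n < seg) {
    abort(sprintf("series of length %d is shorter than one segment (%d samples).",
                  n, seg))
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("`overlap_fraction` must be in [0, 1).")
  }
  step <- max(1L, as.integer(round(seg * (1 - overlap_fraction))))
  starts <- seq(1L, n - seg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg - 1L) / (seg - 1L)) # Hann
  u <- sum(win^2)
  n_freq <- seg %/% 2L + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    segment <- x[s:(s + seg - 1L)]
    segment <- (segment - mean(segment)) * win
    p <- Mod(fft(segment))^2 / (fs * u)
    p <- p[seq_len(n_freq)]
    # one-sided: double everything except DC (and Nyquist for even seg)
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (seg %% 2L == 0L) dbl[n_freq] <- 1
    acc <- acc + p * dbl
  }
  tibble(
    frequency = (seq_len(n_freq) - 1L) * fs / seg,
    power = acc / length(starts)
  )
}

#' Fit the 1/f^alpha spectral exponent
#'
#' Least-squares line through `log10(power)` versus `log10(frequency)` over
#' a frequency band; `alpha` is the negative slope, so white noise gives
#' `alpha ~ 0` and Brownian noise (a random walk, the output of any
#' constant-noise accumulator) gives `alpha ~ 2`.
#'
#' @param frequencies,power PSD as returned by [estimate_psd()] (or any
#'   frequency/power pair). A data frame with those columns is also
#'   accepted as the first argument.
#' @param f_range Fit band `c(f_lo, f_hi)` in Hz, default 0.5-40 Hz.
#' @return An object of class `spectral_fit` with fields `alpha`,
#'   `r_squared`, `f_range`, and the `psd` points used.
#' @examples
#' f <- 1:100
#' fit_spectral_exponent(f, f^-1.5, f_range = c(1, 100))$alpha
#' @export
fit_spectral_exponent <- function(frequencies, power = NULL,
                                  f_range = c(0.5, 40)) {
  if (is.data.frame(frequencies)) {
    power <- frequencies$power
    frequencies <- frequencies$frequency
  }
  stopifnot(length(frequencies) == length(power), length(f_range) == 2L,
            f_range[1] > 0, f_range[1] < f_range[2])
  keep <- frequencies >= f_range[1] & frequencies <= f_range[2]
  if (sum(keep) < 5L) abort("fewer than 5 frequency bins in `f_range`.")
  if (any(power[keep] <= 0)) abort("nonpositive power inside `f_range`.")
  lf <- log10(frequencies[keep])
  lp <- log10(power[keep])
  fit <- lm(lp ~ lf)
  # r.squared by hand: summary.lm warns on numerically perfect fits
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((lp - mean(lp))^2)
  structure(
    list(
      alpha = -unname(coef(fit)[2]),
      r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
      f_range = f_range,
      psd = tibble(frequency = frequencies[keep], power = power[keep])
    ),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> alpha = %.3f (R^2 = %.3f) over %g-%g Hz\n",
              x$alpha, x$r_squared, x$f_range[1], x$f_range[2]))
  invisible(x)
}

#' @export
glance.spectral_fit <- function(x, ...) {
  tibble(alpha = x$alpha, r_squared = x$r_squared,
         f_lo = x$f_range[1], f_hi = x$f_range[2])
}

#' @export
autoplot.spectral_fit <- function(object, ...) {
  ggplot(object$psd, aes(.data$frequency, .data$power)) +
    geom_line() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "firebrick", linewidth = 0.5) +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = "frequency (Hz)", y = "power (units²/Hz)",
         title = sprintf("1/f^alpha fit: alpha = %.2f", object$alpha))
}

#' Spectral exponent of a series in one call
#'
#' Convenience wrapper: [estimate_psd()] then [fit_spectral_exponent()].
#'
#' @inheritParams estimate_psd
#' @inheritParams fit_spectral_exponent
#' @return A `spectral_fit`.
#' @export
spectral_exponent <- function(x, fs, f_range = c(0.5, 40),
                              segment_length = 256L, overlap_fraction = 0.5) {
  psd <- estimate_psd(x, fs, segment_length, overlap_fraction)
  fit_spectral_exponent(psd, f_range = f_range)
}
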