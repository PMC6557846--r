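#' Inverse-Gaussian (Wald) density and distribution function
#'
#' \deqn{\rho(w; \mu, \lambda) = \sqrt{\lambda / (2 \pi w^3)}
#'   \exp\{-\lambda (w - \mu)^2 / (2 \mu^2 w)\},}
#' the first-passage-time law of drifted Brownian motion to a fixed bound;
#' `mu` is the mean and `lambda` the shape parameter. Defined as 0 for
#' `w <= 0`.
#'
#' @param w Waiting times, seconds.
#' @param mu Mean, seconds (`> 0`).
#' @param lambda Shape, seconds (`> 0`).
#' @return `ig_pdf()`: density values (1/s); `ig_cdf()`: distribution
#'   function values.
#' @examples
#' ig_pdf(1, 1, 1) # 1/sqrt(2*pi)
#' @export
ig_pdf <- function(w, mu, lambda) {
  assert_scalar_number(mu, "mu", positive = TRUE)
  assert_scalar_number(lambda, "lambda", positive = TRUE)
  out <- numeric(length(w))
  pos <- is.finite(w) & w > 0
  wp <- w[pos]
  out[pos] <- sqrt(lambda / (2 * pi * wp^3)) *
    exp(-lambda * (wp - mu)^2 / (2 * mu^2 * wp))
  out
}

#' @rdname ig_pdf
#' @export
ig_cdf <- function(w, mu, lambda) {
  assert_scalar_number(mu, "mu", positive = TRUE)
  assert_scalar_number(lambda, "lambda", positive = TRUE)
  out <- numeric(length(w))
  pos <- is.finite(w) & w > 0
  wp <- w[pos]
  s <- sqrt(lambda / wp)
  out[pos] <- pnorm(s * (wp / mu - 1)) +
    exp(2 * lambda / mu) * pnorm(-s * (wp / mu + 1))
  out
}

new_ig_fit <- function(mu, lambda, n, loglik, n_censored = 0L) {
  structure(
    list(mu = mu, lambda = lambda, n = n, loglik = loglik,
         n_censored = n_censored),
    class = "ig_fit"
  )
}

#' Maximum-likelihood inverse-Gaussian fit
#'
#' Closed-form MLE for the inverse-Gaussian family:
#' `mu_hat = mean(w)` and `lambda_hat = n / sum(1/w - 1/mu_hat)`.
#' Censored runs of a `wt_sample` are excluded from the fit (and counted).
#'
#' @param sample A `wt_sample` or numeric vector of positive waiting times
#'   (seconds), at least 2 of them.
#' @return An object of class `ig_fit` with fields `mu`, `lambda`, `n`,
#'   `loglik`.
#' @examples
#' fit_inverse_gaussian(c(1, 2, 4))
#' @export
fit_inverse_gaussian <- function(sample) {
  n_cens <- if (inherits(sample, "wt_sample")) attr(sample, "n_censored") else 0L
  w <- waiting_times(sample)
  if (length(w) < 2L) abort("need at least 2 uncensored waiting times.")
  if (any(w <= 0)) abort("waiting times must be strictly positive.")
  mu <- mean(w)
  denom <- sum(1 / w - 1 / mu)
  if (denom <= .Machine$double.eps * length(w)) {
    abort("degenerate sample: zero dispersion (all waiting times equal), shape parameter diverges.")
  }
  lambda <- length(w) / denom
  ll <- sum(log(ig_pdf(w, mu, lambda)))
  new_ig_fit(mu, lambda, length(w), ll, n_cens)
}

#' @export
print.ig_fit <- function(x, ...) {
  cat(sprintf("<ig_fit> mu = %.4g s, lambda = %.4g s (n = %d", x$mu,
              x$lambda, x$n))
  if (x$n_censored > 0) cat(",", x$n_censored, "censored")
  cat(sprintf("), loglik = %.4g\n", x$loglik))
  invisible(x)
}

#' @export
tidy.ig_fit <- function(x, ...) {
  # asymptotic standard errors of the MLE
  tibble(
    term = c("mu", "lambda"),
    estimate = c(x$mu, x$lambda),
    std.error = c(sqrt(x$mu^3 / (x$lambda * x$n)), x$lambda * sqrt(2 / x$n))
  )
}

#' @export
glance.ig_fit <- function(x, ...) {
  tibble(mu = x$mu, lambda = x$lambda, n = x$n, n_censored = x$n_censored,
         loglik = x$loglik)
}

# Accept an ig_fit or a (mu, lambda) pair.
as_ig_params <- function(x, name) {
  if (inherits(x, "ig_fit")) {
    c(x$mu, x$lambda)
  } else if (is.numeric(x) && length(x) == 2L) {
    as.numeric(x)
  } else {
    abort(sprintf("`%s` must be an ig_fit or a numeric (mu, lambda) pair.", name))
  }
}

#' Euclidean parameter distance E in the (mu, lambda) plane
#'
#' `E = sqrt((mu - M)^2 + (lambda - L)^2)` between a fitted waiting-time
#' distribution and a target, the objective minimized when optimizing the
#' decision threshold.
#'
#' @param fit An `ig_fit` or `(mu, lambda)` pair.
#' @param target_mu,target_lambda Target parameters `(M, L)`, seconds.
#' @return Nonnegative distance (seconds-scale).
#' @export
param_distance <- function(fit, target_mu, target_lambda) {
  p <- as_ig_params(fit, "fit")
  sqrt((p[1] - target_mu)^2 + (p[2] - target_lambda)^2)
}

#' L2 distance between two inverse-Gaussian densities
#'
#' `D(rho1, rho2) = sqrt(integral (rho1(w) - rho2(w))^2 dw)`, the Hilbert
#' space (L2) metric, evaluated by adaptive quadrature over `(0, upper]`
#' seconds. For the waiting-time parameters involved here the densities are
#' below 1e-12 beyond 50 s, so the default upper limit is 50.
#'
#' @param fit1,fit2 `ig_fit` objects or `(mu, lambda)` pairs.
#' @param upper Upper integration limit, seconds.
#' @return The distance, units s^-1/2.
#' @examples
#' l2_density_distance(c(7.01, 22.55), c(5.95, 21.96))
#' @export
l2_density_distance <- function(fit1, fit2, upper = 50) {
  p1 <- as_ig_params(fit1, "fit1")
  p2 <- as_ig_params(fit2, "fit2")
  q <- integrate(
    function(w) (ig_pdf(w, p1[1], p1[2]) - ig_pdf(w, p2[1], p2[2]))^2,
    lower = 0, upper = upper, rel.tol = 1e-10, abs.tol = 1e-10,
    subdivisions = 400L
  )
  if (q$message != "OK") abort(paste("quadrature failed:", q$message))
  sqrt(q$value)
}

#' Optimize the decision threshold against an empirical target
#'
#' For every threshold `beta` in the grid: simulate a first-passage
#' waiting-time sample of the model ([simulate_wt_sample()]), fit an inverse
#' Gaussian, and compute the parameter distance `E(beta)` to the target
#' `(M, L)`. The optimum `beta0 = argmin E(beta)`. Grid points where all
#' runs censor (or the fit degenerates) are marked invalid and excluded.
#'
#' @param model A [langevin_model()].
#' @param target_mu,target_lambda Empirical target parameters `(M, L)`.
#' @param betas Threshold grid (default `seq(2, 8, by = 0.1)`).
#' @param config A [sim_config()]; each grid point simulates on its own
#'   substream derived from `config$seed` unless `share_noise = TRUE`, in
#'   which case all points reuse the same per-run streams (useful for
#'   variance-reduced, monotone `mu(beta)` scans).
#' @param share_noise Reuse identical noise streams across grid points.
#' @return A `threshold_scan`: tibble with per-beta `mu`, `lambda`, `E`,
#'   censoring counts and `valid` flag; attributes `beta0`, `target`,
#'   `model`.
#' @export
optimize_threshold <- function(model, target_mu, target_lambda,
                               betas = seq(2, 8, by = 0.1),
                               config = sim_config(),
                               share_noise = FALSE) {
  if (length(betas) == 0L) abort("`betas` grid is empty.")
  assert_scalar_number(target_mu, "target_mu", positive = TRUE)
  assert_scalar_number(target_lambda, "target_lambda", positive = TRUE)
  rows <- imap(betas, function(beta, i) {
    cfg <- config
    if (!share_noise) cfg$seed <- substream_seed(config$seed, 17L, i)
    res <- tryCatch({
      wts <- simulate_wt_sample(model, beta, cfg)
      fit <- fit_inverse_gaussian(wts)
      tibble(beta = beta, mu = fit$mu, lambda = fit$lambda,
             E = param_distance(fit, target_mu, target_lambda),
             n_crossed = fit$n, n_censored = attr(wts, "n_censored"),
             valid = TRUE)
    }, error = function(e) {
      tibble(beta = beta, mu = NA_real_, lambda = NA_real_, E = NA_real_,
             n_crossed = NA_integer_, n_censored = NA_integer_,
             valid = FALSE)
    })
    res
  })
  scan <- list_rbind(rows)
  if (!any(scan$valid)) {
    abort("every grid point was invalid (all runs censored or degenerate fits).")
  }
  beta0 <- scan$beta[scan$valid][which.min(scan$E[scan$valid])]
  structure(
    scan,
    beta0 = beta0,
    target = c(mu = target_mu, lambda = target_lambda),
    model = model,
    config = config,
    class = c("threshold_scan", class(tibble()))
  )
}

#' @export
print.threshold_scan <- function(x, ...) {
  b0 <- attr(x, "beta0")
  row <- x[x$beta == b0, ]
  cat(sprintf(
    "<threshold_scan> %d grid points; beta0 = %.3g (mu = %.3g, lambda = %.3g, E = %.3g)\n",
    nrow(x), b0, row$mu[1], row$lambda[1], row$E[1]
  ))
  NextMethod()
}

#' @export
glance.threshold_scan <- function(x, ...) {
  b0 <- attr(x, "beta0")
  row <- x[x$beta == b0, ]
  tibble(beta0 = b0, mu = row$mu[1], lambda = row$lambda[1], E = row$E[1],
         n_valid = sum(x$valid), n_grid = nrow(x))
}

#' @export
autoplot.threshold_scan <- function(object, ...) {
  b0 <- attr(object, "beta0")
  ggplot(filter(object, .data$valid), aes(.data$beta, .data$E)) +
    geom_line() +
    geom_point(size = 0.8) +
    geom_vline(xintercept = b0, linetype = "dashed", colour = "firebrick") +
    labs(x = expression(beta), y = expression(E(beta)),
         title = "Threshold optimization",
         subtitle = sprintf("beta0 = %.3g", b0))
}
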