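#' Polynomial Langevin model
#'
#' A first-order stochastic differential equation
#' \deqn{dz/dt = P_G(z) + P_H(z)\,\Gamma(t),}
#' where `P_G` (the drift, degree `G`) and `P_H` (the noise amplitude,
#' degree `H`) are polynomials and `Gamma(t)` is Gaussian white noise
#' (`<Gamma(t) Gamma(t')> = delta(t - t')`). The drift equals the
#' Fokker-Planck drift coefficient `D1(z)` and `P_H(z)^2` the diffusion
#' coefficient `D2(z)`. The leaky stochastic accumulator (LSA) is the special
#' case `G = 1`, `H = 0`; the nonlinear generalization used for neural data
#' has `G = 3`, `H = 2`.
#'
#' Coefficient vectors are highest-degree-first, so a cubic drift is
#' `c(a, b, c, d)` meaning `a z^3 + b z^2 + c z + d`.
#'
#' @param drift_coeffs Numeric vector of drift-polynomial coefficients
#'   (highest-degree-first), units: model units per second.
#' @param noise_coeffs Numeric vector of noise-amplitude coefficients
#'   (highest-degree-first), units: model units per sqrt(second).
#' @param state_units Label for the state variable's units.
#' @param state_range Optional length-2 numeric, the state interval over
#'   which the model is supported (e.g. the fitted bin range).
#' @param provenance Named list recording how the model was obtained
#'   (mode tag, scale factors, source identifiers).
#'
#' @return An object of class `langevin_model`.
#' @examples
#' lsa <- langevin_model(c(-0.29, 1.43), 1.78)
#' drift_at(lsa, 0:3)
#' tidy(lsa)
#' @export
langevin_model <- function(drift_coeffs, noise_coeffs,
                           state_units = "model units",
                           state_range = NULL,
                           provenance = list(mode = "manual")) {
  if (!is.numeric(drift_coeffs) || length(drift_coeffs) < 1L ||
      !all(is.finite(drift_coeffs))) {
    abort("`drift_coeffs` must be a non-empty finite numeric vector.")
  }
  if (!is.numeric(noise_coeffs) || length(noise_coeffs) < 1L ||
      !all(is.finite(noise_coeffs))) {
    abort("`noise_coeffs` must be a non-empty finite numeric vector.")
  }
  if (!is.null(state_range)) {
    stopifnot(length(state_range) == 2L, is.finite(state_range),
              state_range[1] <= state_range[2])
  }
  model <- structure(
    list(
      drift_coeffs = as.numeric(drift_coeffs),
      noise_coeffs = as.numeric(noise_coeffs),
      degree_g = length(drift_coeffs) - 1L,
      degree_h = length(noise_coeffs) - 1L,
      state_units = state_units,
      state_range = state_range,
      provenance = provenance
    ),
    class = "langevin_model"
  )
  model$noise_positive <- is.null(state_range) ||
    min(noise_at(model, seq(state_range[1], state_range[2], length.out = 201))) > 0
  model
}

#' Evaluate a model's drift or noise amplitude
#'
#' @param model A [langevin_model()].
#' @param z State values (model units).
#' @return Numeric vector: `drift_at()` gives `P_G(z)` (model units/s);
#'   `noise_at()` gives `P_H(z)` without the positivity floor applied.
#' @export
drift_at <- function(model, z) eval_poly(model$drift_coeffs, z)

#' @rdname drift_at
#' @export
noise_at <- function(model, z) eval_poly(model$noise_coeffs, z)

#' @export
print.langevin_model <- function(x, ...) {
  fmt_poly <- function(cf) {
    deg <- length(cf) - 1L
    terms <- purrr::imap_chr(cf, function(ci, i) {
      p <- deg - i + 1L
      v <- format(ci, digits = 4)
      if (p == 0) v else if (p == 1) paste0(v, " z") else paste0(v, " z^", p)
    })
    paste(terms, collapse = " + ")
  }
  cat("<langevin_model> dz/dt = P_G(z) + P_H(z) Gamma(t)\n")
  cat("  drift  P_G (degree", x$degree_g, "):", fmt_poly(x$drift_coeffs), "\n")
  cat("  noise  P_H (degree", x$degree_h, "):", fmt_poly(x$noise_coeffs), "\n")
  if (!is.null(x$state_range)) {
    cat("  state range: [", format(x$state_range[1], digits = 4), ",",
        format(x$state_range[2], digits = 4), "]", x$state_units, "\n")
  }
  if (!is.null(x$provenance$mode)) cat("  provenance:", x$provenance$mode, "\n")
  if (isFALSE(x$noise_positive)) {
    cat("  note: fitted noise amplitude is non-positive somewhere on the",
        "state range; simulation applies a floor of", NOISE_EPS, "\n")
  }
  invisible(x)
}

#' @export
tidy.langevin_model <- function(x, ...) {
  drift <- tibble(
    part = "drift",
    degree = rev(seq_along(x$drift_coeffs)) - 1L,
    estimate = x$drift_coeffs
  )
  noise <- tibble(
    part = "noise",
    degree = rev(seq_along(x$noise_coeffs)) - 1L,
    estimate = x$noise_coeffs
  )
  bind_rows(drift, noise)
}

#' @export
glance.langevin_model <- function(x, ...) {
  tibble(
    degree_g = x$degree_g,
    degree_h = x$degree_h,
    noise_positive = isTRUE(x$noise_positive),
    state_lo = if (is.null(x$state_range)) NA_real_ else x$state_range[1],
    state_hi = if (is.null(x$state_range)) NA_real_ else x$state_range[2],
    mode = x$provenance$mode %||% NA_character_
  )
}

#' @export
autoplot.langevin_model <- function(object, n = 201, ...) {
  rng <- object$state_range %||% c(-3, 3)
  z <- seq(rng[1], rng[2], length.out = n)
  df <- bind_rows(
    tibble(z = z, value = drift_at(object, z), part = "drift P_G(z)"),
    tibble(z = z, value = noise_at(object, z), part = "noise P_H(z)")
  )
  ggplot(df, aes(.data$z, .data$value)) +
    geom_line() +
    facet_wrap(~part, scales = "free_y") +
    labs(x = paste0("z (", object$state_units, ")"), y = NULL,
         title = "Langevin model functions")
}
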