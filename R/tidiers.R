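# broom-style tidiers for the fitted-object classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single-exponential fit
#'
#' @param x A `quadkin_exp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`tau`, `amplitude`,
#'   `offset`): `term`, `estimate`, `std.error` (reported for `tau`).
#' @method tidy quadkin_exp_fit
#' @export
tidy.quadkin_exp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("tau", "amplitude", "offset"),
    estimate = c(x$tau, x$amplitude, x$offset),
    std.error = c(x$tau_stderr, NA_real_, NA_real_))
}

#' @rdname tidy.quadkin_exp_fit
#' @return `glance()`: a one-row tibble with `tau`, `tau_stderr`,
#'   `direction`, `sigma` (residual s.d.), `nobs`.
#' @method glance quadkin_exp_fit
#' @export
glance.quadkin_exp_fit <- function(x, ...) {
  tibble::tibble(
    tau = x$tau, tau_stderr = x$tau_stderr, direction = x$direction,
    sigma = stats::sd(x$residuals), nobs = x$n)
}

#' Tidy a four-state kinetic global fit
#'
#' @param x A `quadkin_kinetic_fit`.
#' @param ... Unused.
#' @return A tibble with one row per rate constant: `term`, `estimate`,
#'   `std.error`, `fixed`.
#' @method tidy quadkin_kinetic_fit
#' @export
tidy.quadkin_kinetic_fit <- function(x, ...) x$rates

#' @rdname tidy.quadkin_kinetic_fit
#' @return `glance()`: one-row tibble with `ratio` (k2/k3),
#'   `ratio_stderr`, `residual_norm`, `rss`, `nobs`, `flat_likelihood`,
#'   `convergence`.
#' @method glance quadkin_kinetic_fit
#' @export
glance.quadkin_kinetic_fit <- function(x, ...) {
  tibble::tibble(ratio = x$ratio, ratio_stderr = x$ratio_stderr,
                 residual_norm = x$residual_norm, rss = x$rss,
                 nobs = x$n_points, flat_likelihood = x$flat_likelihood,
                 convergence = x$convergence)
}

#' Tidy a melting-temperature estimate
#'
#' @param x A `quadkin_tm`.
#' @param ... Unused.
#' @return A one-row tibble: `term = "tm"`, `estimate`, `std.error`,
#'   `wavelength_nm`.
#' @method tidy quadkin_tm
#' @export
tidy.quadkin_tm <- function(x, ...) {
  tibble::tibble(term = "tm", estimate = x$tm, std.error = x$tm_stderr,
                 wavelength_nm = x$wavelength_nm)
}

#' Tidy a population estimate
#'
#' @param x A `quadkin_population`.
#' @param ... Unused.
#' @return A tibble with one row per reporter residue plus an `overall`
#'   row: `residue`, `fraction_g4i`, `fraction_g4ii`.
#' @method tidy quadkin_population
#' @export
tidy.quadkin_population <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$per_residue, fraction_g4ii = 1 - .data$fraction_g4i),
    tibble::tibble(residue = "overall", fraction_g4i = x$fraction_g4i,
                   fraction_g4ii = x$fraction_g4ii))
}
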