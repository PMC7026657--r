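# Synthetic-data generators. Every input the analysis consumes can be
# generated here with the statistical structure the estimators assume:
# dual-wavelength CD kinetic traces from the four-state forward model with
# additive Gaussian noise, sigmoidal melting curves with sloping baselines,
# single-exponential HDX decays with multiplicative noise, and peak-volume
# tables at a prescribed conformer ratio. All generators are pure functions
# of (parameters, seed).

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Oligonucleotide variants of the WNT1-promoter sequence WT22m
#'
#' The WT22m family: the 22-mer parent, the four single C-to-T mutants
#' (T4 locks the G4(I) fold), and the four epigenetically modified C4
#' variants (5mC, 5hmC, 5fC, 5caC). Modified cytosines are annotated by
#' `mod_code`/`mod_position` on the unmodified base sequence. `tm_C` is
#' the CD melting temperature where measured.
#'
#' @return A tibble with columns `name`, `sequence` (5'->3', 22 nt),
#'   `mod_code`, `mod_position`, `tm_C`.
#' @examples
#' builtin_variants()
#' @export
builtin_variants <- function() {
  tibble::tibble(
    name = c("WT22m", "WT22m-T4", "WT22m-T5", "WT22m-T7", "WT22m-T8",
             "WT22m-5mC4", "WT22m-5hmC4", "WT22m-5fC4", "WT22m-5caC4"),
    sequence = c("GGGCCACCGGGCAGTGGGCGGG",
                 "GGGTCACCGGGCAGTGGGCGGG",
                 "GGGCTACCGGGCAGTGGGCGGG",
                 "GGGCCATCGGGCAGTGGGCGGG",
                 "GGGCCACTGGGCAGTGGGCGGG",
                 rep("GGGCCACCGGGCAGTGGGCGGG", 4)),
    mod_code = c(NA, NA, NA, NA, NA, "5mC", "5hmC", "5fC", "5caC"),
    mod_position = c(NA, NA, NA, NA, NA, 4L, 4L, 4L, 4L),
    tm_C = c(73.0, 69.2, NA, NA, NA, 73.0, 69.5, 69.5, 69.5)
  )
}

#' Fitted rate constants for the characterised variants
#'
#' The five transition rate constants (min^-1) of the four-state model for
#' the three variants whose CD kinetics were fitted, with their standard
#' uncertainties (`*_err` columns).
#'
#' @return A tibble with columns `name`, `k1`..`k5` and `k1_err`..`k5_err`.
#' @examples
#' builtin_rates()
#' @export
builtin_rates <- function() {
  tibble::tibble(
    name = c("WT22m", "WT22m-5mC4", "WT22m-5fC4"),
    k1 = c(0.23, 0.12, 0.58),   k1_err = c(0.03, 0.01, 0.14),
    k2 = c(533, 1173, 653),     k2_err = c(173, 777, 120),
    k3 = c(50, 147, 73),        k3_err = c(20, 83, 27),
    k4 = c(0.037, 0.029, 0.027), k4_err = c(0.010, 0.010, 0.010),
    k5 = c(2.7e-4, 1.7e-4, 0.023), k5_err = c(0.9e-4, 0.9e-4, 0.006)
  )
}

#' Default per-wavelength CD response coefficients
#'
#' The 265-nm channel reports G4(I) with a minor G4(II) shoulder
#' (c_B = 1, c_C = 0.2); the 295-nm channel reports G4(II) with a minor
#' G4(I) contribution (c_B = 0.1, c_C = 1). These reproduce the observed
#' qualitative pattern: rapid 265-nm growth, slow 265-nm decay, slow
#' 295-nm growth.
#'
#' @name default_cd_coefficients
#' @return A `quadkin_cd_coefficients` object.
#' @export
default_coeff265 <- function() cd_coefficients(265, c_B = 1, c_C = 0.2)

#' @rdname default_cd_coefficients
#' @export
default_coeff295 <- function() cd_coefficients(295, c_B = 0.1, c_C = 1)

#' Synthetic dual-wavelength CD kinetic traces
#'
#' Runs the four-state forward model from pure hairpin and maps the
#' populations through the linear CD response at both wavelengths, then
#' adds Gaussian noise with standard deviation `sigma_rel` times each
#' trace's noiseless peak-to-peak amplitude. The default noise level of
#' 2% reflects the tightness of experimental kinetic CD traces.
#'
#' @param k Rate constants ([as_rate_constants()]).
#' @param coeff265,coeff295 [cd_coefficients()] for the two channels.
#' @param times Time grid in minutes (default 0-600, 1-min steps: the
#'   duration over which the conversion was monitored).
#' @param sigma_rel Noise s.d. as a fraction of peak-to-peak amplitude.
#' @param seed Integer seed; the generator is deterministic given the seed
#'   and does not disturb the global RNG state.
#' @param x0 Initial populations, default pure hairpin.
#' @return A list with elements `trace265` and `trace295`
#'   (`quadkin_cd_trace`).
#' @examples
#' k <- rate_constants(k1 = 0.23, k2 = 533, k3 = 50, k4 = 0.037, k5 = 2.7e-4)
#' tr <- gen_cd_traces(k, seed = 1)
#' @export
gen_cd_traces <- function(k, coeff265 = default_coeff265(),
                          coeff295 = default_coeff295(),
                          times = 0:600, sigma_rel = 0.02, seed = NULL,
                          x0 = c(1, 0, 0, 0)) {
  if (sigma_rel < 0) stop("`sigma_rel` must be >= 0", call. = FALSE)
  traj <- solve_populations(k, x0 = x0, times = times)
  clean <- list(trace265 = cd_signal(traj, coeff265),
                trace295 = cd_signal(traj, coeff295))
  .with_seed(seed, {
    lapply(clean, function(tr) {
      amp <- diff(range(tr$signal))
      noisy <- tr$signal + stats::rnorm(nrow(tr), 0, sigma_rel * amp)
      cd_trace(tr$time_min, noisy, cd_wavelength(tr))
    })
  })
}

#' Synthetic CD melting curve
#'
#' Two-state logistic melt: fraction folded
#' `theta(T) = 1 / (1 + exp((T - tm)/width))` mixed with linear folded and
#' unfolded baselines, plus additive Gaussian noise scaled to the
#' peak-to-peak amplitude. The logistic places the derivative extremum of
#' the noiseless curve exactly at `tm`, so generator truth is exact for
#' the first-derivative estimator.
#'
#' @param tm Midpoint in degrees C (must lie inside the grid).
#' @param width Transition width in degrees C (> 0); default 3.
#' @param baseline_folded,baseline_unfolded Length-2 `c(intercept, slope)`
#'   of the folded/unfolded baselines (signal units, per degC).
#' @param temps Temperature grid, default `seq(10, 95, by = 1)` (1 C/min
#'   ramp sampling).
#' @param amplitude Folded-minus-unfolded signal amplitude at `tm`.
#' @param sigma_rel Noise s.d. as a fraction of peak-to-peak amplitude;
#'   default 0.01.
#' @param seed Integer seed (see [gen_cd_traces()]).
#' @param wavelength Monitoring wavelength recorded on the curve.
#' @return A `quadkin_melting_curve`.
#' @examples
#' estimate_tm(gen_melting_curve(tm = 73, seed = 7))
#' @export
gen_melting_curve <- function(tm, width = 3,
                              baseline_folded = c(0, -0.004),
                              baseline_unfolded = c(0, 0.002),
                              temps = seq(10, 95, by = 1),
                              amplitude = 1, sigma_rel = 0.01, seed = NULL,
                              wavelength = 295) {
  if (tm <= min(temps) || tm >= max(temps)) {
    stop("`tm` must lie strictly inside the temperature grid", call. = FALSE)
  }
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  theta <- 1 / (1 + exp((temps - tm) / width))
  bf <- amplitude + baseline_folded[1] + baseline_folded[2] * (temps - tm)
  bu <- baseline_unfolded[1] + baseline_unfolded[2] * (temps - tm)
  y <- theta * bf + (1 - theta) * bu
  amp <- diff(range(y))
  y <- .with_seed(seed, y + stats::rnorm(length(y), 0, sigma_rel * amp))
  melting_curve(temps, y, wavelength)
}

#' Synthetic HDX peak-volume decay series
#'
#' `volume(t) = floor + v0 * exp(-t/tau)`, sampled on the experimental
#' grid (10 min, 30 min, 1 h, 2 h, 24 h by default) with multiplicative
#' Gaussian noise of relative s.d. `sigma_rel`.
#'
#' @param tau Exchange time in minutes (> 0).
#' @param times Sampling grid, default [hdx_default_times].
#' @param v0 Exchangeable amplitude; default 1.
#' @param floor Non-exchanging volume floor; default 0.
#' @param sigma_rel Relative noise s.d.; default 0.02.
#' @param seed Integer seed.
#' @param residue Optional residue label stored as attribute `residue`.
#' @return A tibble with columns `time_min`, `volume`, class
#'   `quadkin_hdx_series`.
#' @examples
#' gen_hdx_series(tau = 3800, seed = 3)
#' @export
gen_hdx_series <- function(tau, times = hdx_default_times, v0 = 1,
                           floor = 0, sigma_rel = 0.02, seed = NULL,
                           residue = NULL) {
  if (tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be non-negative and increasing", call. = FALSE)
  }
  v <- floor + v0 * exp(-times / tau)
  v <- .with_seed(seed, v * (1 + stats::rnorm(length(v), 0, sigma_rel)))
  v <- pmax(v, 0)
  out <- tibble::tibble(time_min = as.numeric(times), volume = v)
  attr(out, "residue") <- residue
  class(out) <- c("quadkin_hdx_series", class(out))
  out
}

#' Synthetic imino-proton peak-volume table
#'
#' Splits a total volume between the G4(I) and G4(II) peaks of each
#' reporter residue at the prescribed G4(I) fraction, with multiplicative
#' Gaussian volume noise.
#'
#' @param fraction_g4i True G4(I) population fraction in `[0, 1]`.
#' @param residues Reporter residue labels; default `c("G16", "G18")`.
#' @param total_volume Total peak volume per residue; default 100.
#' @param sigma_rel Relative volume noise s.d.; default 0.05.
#' @param seed Integer seed.
#' @return A tibble with columns `residue`, `vol_g4i`, `vol_g4ii`.
#' @examples
#' gen_peak_table(0.85, seed = 2)
#' @export
gen_peak_table <- function(fraction_g4i, residues = c("G16", "G18"),
                           total_volume = 100, sigma_rel = 0.05,
                           seed = NULL) {
  if (fraction_g4i < 0 || fraction_g4i > 1) {
    stop("`fraction_g4i` must be in [0, 1]", call. = FALSE)
  }
  v1 <- rep(fraction_g4i * total_volume, length(residues))
  v2 <- rep((1 - fraction_g4i) * total_volume, length(residues))
  .with_seed(seed, {
    v1 <- pmax(v1 * (1 + stats::rnorm(length(v1), 0, sigma_rel)), 0)
    v2 <- pmax(v2 * (1 + stats::rnorm(length(v2), 0, sigma_rel)), 0)
  })
  tibble::tibble(residue = residues, vol_g4i = v1, vol_g4ii = v2)
}
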