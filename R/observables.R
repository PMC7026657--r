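# Mapping state populations to measurable signals: linear CD response at a
# chosen wavelength, the qualitative tetrad-directionality CD heuristic, and
# trapezoidal peak integration for NMR spectra.

.cd_standard_wavelengths <- c(265, 290, 295)

#' Per-species CD response coefficients at one wavelength
#'
#' A CD kinetic trace is modelled as a linear response of the state
#' populations: `signal(t) = baseline + c_A A(t) + c_B B(t) + c_C C(t) +
#' c_D D(t)`. The experiments monitor 265 nm (reports G4(I)) and 290/295 nm
#' (reports G4(II)); other wavelengths are permitted but flagged with a
#' warning. The hairpin and unfolded ensemble are not assumed CD-silent:
#' their coefficients default to 0 but are fittable.
#'
#' @param wavelength Wavelength in nm.
#' @param c_A,c_B,c_C,c_D Response per unit population of Hp, G4(I), G4(II)
#'   and U respectively (signal units).
#' @param baseline Constant offset in signal units.
#' @return An object of class `quadkin_cd_coefficients`.
#' @examples
#' cd_coefficients(265, c_B = 1, c_C = 0.2)
#' @export
cd_coefficients <- function(wavelength, c_A = 0, c_B = 0, c_C = 0, c_D = 0,
                            baseline = 0) {
  vals <- c(wavelength = wavelength, c_A = c_A, c_B = c_B, c_C = c_C,
            c_D = c_D, baseline = baseline)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("CD coefficients must be finite numbers", call. = FALSE)
  }
  if (!wavelength %in% .cd_standard_wavelengths) {
    warning("wavelength ", wavelength, " nm is outside the standard set (",
            paste(.cd_standard_wavelengths, collapse = ", "),
            " nm)", call. = FALSE)
  }
  structure(as.list(vals), class = "quadkin_cd_coefficients")
}

#' Construct a CD kinetic trace
#'
#' @param time_min Strictly increasing times in minutes.
#' @param signal Ellipticity (arbitrary units), same length as `time_min`.
#' @param wavelength Wavelength in nm, stored as attribute `wavelength_nm`.
#' @return A tibble with columns `time_min`, `signal`, class
#'   `quadkin_cd_trace`.
#' @export
cd_trace <- function(time_min, signal, wavelength = NA_real_) {
  if (length(time_min) != length(signal)) {
    stop("`time_min` and `signal` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time_min)) || is.unsorted(time_min, strictly = TRUE)) {
    stop("`time_min` must be finite and strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(time_min = as.numeric(time_min),
                        signal = as.numeric(signal))
  attr(out, "wavelength_nm") <- as.numeric(wavelength)
  class(out) <- c("quadkin_cd_trace", class(out))
  out
}

#' Wavelength of a CD trace or melting curve
#' @param x A `quadkin_cd_trace` or `quadkin_melting_curve`.
#' @return Wavelength in nm (NA if unset).
#' @export
cd_wavelength <- function(x) {
  w <- attr(x, "wavelength_nm")
  if (is.null(w)) NA_real_ else w
}

#' Predicted CD trace from a state trajectory
#'
#' Applies the linear response model to a trajectory:
#' `signal(t) = baseline + c_A A(t) + c_B B(t) + c_C C(t) + c_D D(t)`.
#'
#' @param traj A `quadkin_trajectory` from [solve_populations()].
#' @param coeff A [cd_coefficients()] object.
#' @return A `quadkin_cd_trace` at the trajectory's time points.
#' @examples
#' k <- rate_constants(k1 = 0.23, k2 = 533, k3 = 50, k4 = 0.037, k5 = 2.7e-4)
#' traj <- solve_populations(k, times = 0:600)
#' cd_signal(traj, cd_coefficients(265, c_B = 1, c_C = 0.2))
#' @export
cd_signal <- function(traj, coeff) {
  stopifnot(inherits(coeff, "quadkin_cd_coefficients"))
  req <- c("time_min", "A_hp", "B_g4i", "D_u", "C_g4ii")
  if (!all(req %in% names(traj))) {
    stop("`traj` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  s <- coeff$baseline + coeff$c_A * traj$A_hp + coeff$c_B * traj$B_g4i +
    coeff$c_C * traj$C_g4ii + coeff$c_D * traj$D_u
  cd_trace(traj$time_min, s, coeff$wavelength)
}

#' Describe a G-quadruplex fold topology
#'
#' @param name Label for the fold.
#' @param tetrad_directionalities Character vector, one entry per tetrad
#'   layer (>= 2 layers), each `"clockwise"` or `"counterclockwise"`: the
#'   hydrogen-bonding directionality of that G-tetrad.
#' @param glycosidic_states Optional `"syn"`/`"anti"` per core guanine;
#'   must supply exactly 4 guanines per tetrad layer when given.
#' @return An object of class `quadkin_topology`.
#' @export
fold_topology <- function(name, tetrad_directionalities,
                          glycosidic_states = NULL) {
  d <- match.arg(tetrad_directionalities,
                 c("clockwise", "counterclockwise"), several.ok = TRUE)
  if (length(d) != length(tetrad_directionalities)) {
    stop("directionalities must each be \"clockwise\" or \"counterclockwise\"",
         call. = FALSE)
  }
  if (length(d) < 2L) {
    stop("a G-quadruplex needs at least 2 tetrad layers", call. = FALSE)
  }
  if (!is.null(glycosidic_states)) {
    g <- match.arg(glycosidic_states, c("syn", "anti"), several.ok = TRUE)
    if (length(g) != 4L * length(d)) {
      stop("each tetrad has exactly 4 guanines: expected ",
           4L * length(d), " glycosidic states", call. = FALSE)
    }
    glycosidic_states <- g
  }
  structure(list(name = name, tetrad_directionalities = d,
                 glycosidic_states = glycosidic_states),
            class = "quadkin_topology")
}

#' Qualitative CD signature from tetrad hydrogen-bonding directionality
#'
#' The 265- and 295-nm CD bands of a G4 are governed mainly by the
#' hydrogen-bonding directionality pattern of its stacked tetrads: uniform
#' directionality (all tetrad-tetrad stacking interfaces alike, as in
#' parallel-like folds such as the locked G4(I)) gives a dominant 265-nm
#' band; strictly alternating directionality (every interface heterogeneous)
#' gives a 295-dominant, antiparallel-like signature; a mixture of both
#' interface kinds (hybrid folds such as G4(II)) gives both bands.
#'
#' @param topo A [fold_topology()].
#' @return One of `"265-dominant"`, `"295-dominant"`, `"mixed 265+295"`.
#' @examples
#' predict_cd_signature(
#'   fold_topology("locked G4(I)", rep("clockwise", 3)))
#' @export
predict_cd_signature <- function(topo) {
  stopifnot(inherits(topo, "quadkin_topology"))
  d <- topo$tetrad_directionalities
  if (length(unique(d)) == 1L) return("265-dominant")
  homo <- d[-1] == d[-length(d)]
  if (any(homo)) "mixed 265+295" else "295-dominant"
}

#' Trapezoidal peak integration over a chemical-shift window
#'
#' Integrates a 1D spectrum (e.g. imino-proton region of a 1H NMR spectrum)
#' over a ppm window by the trapezoidal rule, interpolating the window
#' edges onto the grid. Used to turn peak intensities into the peak volumes
#' from which conformer populations are estimated.
#'
#' @param spectrum Data frame with numeric columns `ppm` (strictly
#'   monotone) and `intensity`.
#' @param window Length-2 numeric ppm interval, within the grid range.
#' @return The integral (volume), a single number.
#' @examples
#' sp <- tibble::tibble(ppm = seq(10, 12, by = 0.01),
#'                      intensity = dnorm(seq(10, 12, by = 0.01), 11, 0.05))
#' integrate_peak(sp, c(10.5, 11.5))
#' @export
integrate_peak <- function(spectrum, window) {
  if (!all(c("ppm", "intensity") %in% names(spectrum))) {
    stop("`spectrum` needs columns `ppm` and `intensity`", call. = FALSE)
  }
  x <- spectrum$ppm
  y <- spectrum$intensity
  if (length(x) < 2L || any(!is.finite(x))) {
    stop("`ppm` grid must be finite with >= 2 points", call. = FALSE)
  }
  if (is.unsorted(x, strictly = TRUE)) {
    if (is.unsorted(rev(x), strictly = TRUE)) {
      stop("`ppm` grid must be strictly monotone", call. = FALSE)
    }
    x <- rev(x)
    y <- rev(y)
  }
  if (length(window) != 2L || any(!is.finite(window))) {
    stop("`window` must be a length-2 finite ppm interval", call. = FALSE)
  }
  lo <- min(window); hi <- max(window)
  if (lo == hi) stop("empty window: zero width", call. = FALSE)
  if (lo < min(x) || hi > max(x)) {
    stop("`window` [", lo, ", ", hi, "] extends outside the ppm grid [",
         min(x), ", ", max(x), "]", call. = FALSE)
  }
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inside],
          stats::approx(x, y, xout = hi)$y)
  pracma::trapz(xs, ys)
}
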