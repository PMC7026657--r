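# ggplot2 autoplot methods for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.species_labels <- c(A_hp = "Hp", B_g4i = "G4(I)", D_u = "U",
                     C_g4ii = "G4(II)")

#' Plot a state trajectory
#'
#' Population of each species versus time. Set `log_time = TRUE` to
#' resolve the fast hairpin-unfolding transient and the slow
#' G4(I) -> G4(II) conversion on one axis.
#'
#' @param object A `quadkin_trajectory`.
#' @param log_time Log-scale the time axis (drops t = 0).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quadkin_trajectory
#' @export
autoplot.quadkin_trajectory <- function(object, log_time = FALSE, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(names(.species_labels)),
                              names_to = "species", values_to = "population")
  long$species <- factor(.species_labels[long$species],
                         levels = unname(.species_labels))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min,
                                          y = .data$population,
                                          colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "population fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (log_time) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a single-exponential fit
#'
#' Data points with the fitted exponential overlaid.
#'
#' @param object A `quadkin_exp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quadkin_exp_fit
#' @export
autoplot.quadkin_exp_fit <- function(object, ...) {
  d <- object$data
  sgn <- if (object$direction == "decay") 1 else -1
  grid <- tibble::tibble(
    time_min = seq(min(d$time_min), max(d$time_min), length.out = 200))
  grid$value <- object$offset + sgn * object$amplitude *
    exp(-grid$time_min / object$tau)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "time (min)", y = "signal",
                  subtitle = sprintf("%s, tau = %.3g min",
                                     object$direction, object$tau)) +
    ggplot2::theme_minimal()
}

#' Plot a dual-wavelength kinetic global fit
#'
#' Both CD traces with the fitted four-state model, faceted by channel.
#'
#' @param object A `quadkin_kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quadkin_kinetic_fit
#' @export
autoplot.quadkin_kinetic_fit <- function(object, ...) {
  lab <- function(ch) {
    w <- cd_wavelength(object$data[[ch]])
    if (is.finite(w)) paste0(w, " nm") else ch
  }
  d <- dplyr::bind_rows(
    dplyr::mutate(object$data$g4i, channel = lab("g4i")),
    dplyr::mutate(object$data$g4ii, channel = lab("g4ii")))
  f <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(object$fitted$g4i),
                  channel = lab("g4i")),
    dplyr::mutate(tibble::as_tibble(object$fitted$g4ii),
                  channel = lab("g4ii")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$signal)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(data = f, colour = "red") +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "CD signal") +
    ggplot2::theme_minimal()
}

#' Plot a melting-curve analysis
#'
#' Baseline-corrected signal and its smoothed first derivative, with the
#' estimated Tm marked.
#'
#' @param object A `quadkin_tm`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quadkin_tm
#' @export
autoplot.quadkin_tm <- function(object, ...) {
  d <- tidyr::pivot_longer(object$derivative,
                           cols = c("corrected", "derivative"),
                           names_to = "panel", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temp_C, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$tm, colour = "red",
                        linetype = 2) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "temperature (degC)", y = NULL,
                  subtitle = sprintf("Tm = %.2f +/- %.2f degC", object$tm,
                                     object$tm_stderr)) +
    ggplot2::theme_minimal()
}
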