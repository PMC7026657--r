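# Single-exponential fitting: CD arising curves (rise) and HDX decays.

.pick_value_col <- function(data, value_col) {
  if (!is.null(value_col)) return(value_col)
  hit <- intersect(c("signal", "volume"), names(data))
  if (length(hit)) hit[1] else names(data)[2]
}

#' Fit a single-exponential rise or decay
#'
#' Least-squares fit of `offset + amplitude * exp(-t/tau)` (decay) or
#' `offset - amplitude * exp(-t/tau)` (rise) to a time series, the model
#' used for the CD arising curve (fit up to 20 min to extract the ~4 min
#' hairpin unfolding time) and for HDX peak-volume decays. Fitting is by
#' Levenberg-Marquardt with multiple log-spaced starting values of `tau`
#' to guard against local minima; `amplitude` and `tau` are bounded
#' positive.
#'
#' @param data Data frame with a time column (minutes) and a value column.
#' @param direction `"rise"` or `"decay"`.
#' @param t_max Optional cutoff in minutes; only points with `t <= t_max`
#'   are fitted (the arising-time protocol uses 20 min).
#' @param time_col Name of the time column (default `"time_min"`).
#' @param value_col Name of the value column; defaults to `"signal"` or
#'   `"volume"`, whichever is present, else the second column.
#' @param offset_bounds Optional length-2 bounds on the fitted offset, used
#'   e.g. to keep an HDX floor non-negative.
#' @param fix_offset Optional number: hold the offset fixed at this value
#'   instead of fitting it (a two-parameter fit).
#' @return An object of class `quadkin_exp_fit` with elements `tau`,
#'   `tau_stderr`, `amplitude`, `offset`, `direction`, `residuals`,
#'   `fitted`, `n`, `data`. Supports [tidy()], [glance()] and `autoplot()`.
#' @examples
#' tr <- gen_hdx_series(tau = 25, seed = 1)
#' fit_exponential(tr, direction = "decay")
#' @export
fit_exponential <- function(data, direction = c("rise", "decay"),
                            t_max = NULL, time_col = "time_min",
                            value_col = NULL, offset_bounds = NULL,
                            fix_offset = NULL) {
  direction <- match.arg(direction)
  value_col <- .pick_value_col(data, value_col)
  if (!all(c(time_col, value_col) %in% names(data))) {
    stop("`data` needs columns `", time_col, "` and `", value_col, "`",
         call. = FALSE)
  }
  t <- as.numeric(data[[time_col]])
  y <- as.numeric(data[[value_col]])
  if (!is.null(t_max)) {
    keep <- t <= t_max
    t <- t[keep]
    y <- y[keep]
  }
  n <- length(t)
  n_par <- if (is.null(fix_offset)) 3L else 2L
  if (n < n_par + 1L) {
    stop("need at least ", n_par + 1L,
         " points to fit this exponential (have ", n, ")", call. = FALSE)
  }
  sgn <- if (direction == "decay") 1 else -1
  model <- function(p, t) p[["offset"]] + sgn * p[["amplitude"]] *
    exp(-t / p[["tau"]])

  span <- diff(range(t))
  if (span <= 0) stop("time points are degenerate", call. = FALSE)
  tau_starts <- exp(seq(log(max(span / 50, min(diff(sort(t))))),
                        log(3 * span), length.out = 5))
  amp0 <- max(abs(y[1] - y[n]), diff(range(y)), 1e-12)
  off0 <- if (direction == "decay") min(y) else max(y)
  lower <- c(offset = if (is.null(offset_bounds)) -Inf else offset_bounds[1],
             amplitude = 0, tau = 1e-8)
  upper <- c(offset = if (is.null(offset_bounds)) Inf else offset_bounds[2],
             amplitude = Inf, tau = Inf)
  off0 <- min(max(off0, lower[["offset"]]), upper[["offset"]])

  df <- data.frame(t = t, y = y)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                     ptol = 1e-14)
  best <- NULL
  msgs <- character()
  for (tau0 in tau_starts) {
    fit <- tryCatch(
      if (is.null(fix_offset)) {
        minpack.lm::nlsLM(
          y ~ offset + sgn * amplitude * exp(-t / tau), data = df,
          start = list(offset = off0, amplitude = amp0, tau = tau0),
          lower = lower, upper = upper, control = ctrl)
      } else {
        fo <- fix_offset
        minpack.lm::nlsLM(
          y ~ fo + sgn * amplitude * exp(-t / tau), data = df,
          start = list(amplitude = amp0, tau = tau0),
          lower = lower[c("amplitude", "tau")],
          upper = upper[c("amplitude", "tau")], control = ctrl)
      },
      error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      msgs <- c(msgs, fit)
      next
    }
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("exponential fit failed to converge from all ", length(tau_starts),
         " starts; last errors: ", paste(unique(msgs), collapse = " | "),
         call. = FALSE)
  }
  cf <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_,
                                                         length(cf)),
                                                     names(cf)))
  structure(list(
    tau = unname(cf[["tau"]]),
    tau_stderr = unname(se[["tau"]]),
    amplitude = unname(cf[["amplitude"]]),
    offset = if (is.null(fix_offset)) unname(cf[["offset"]]) else
      fix_offset,
    offset_fitted = is.null(fix_offset),
    direction = direction,
    fitted = as.numeric(stats::fitted(best)),
    residuals = as.numeric(stats::residuals(best)),
    n = n,
    t_max = t_max,
    data = tibble::tibble(time_min = t, value = y)
  ), class = "quadkin_exp_fit")
}

#' @export
print.quadkin_exp_fit <- function(x, ...) {
  cat("<quadkin_exp_fit> single-exponential ", x$direction, "\n", sep = "")
  cat(sprintf("  tau       = %.6g min (se %.3g)\n", x$tau, x$tau_stderr))
  cat(sprintf("  amplitude = %.6g, offset = %.6g, n = %d\n",
              x$amplitude, x$offset, x$n))
  invisible(x)
}
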