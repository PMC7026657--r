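# Hydrogen-deuterium exchange analysis. An imino-proton peak volume decays
# single-exponentially after dissolution in D2O; the exchange time reports
# the opening/unfolding of that hydrogen bond, and because exchange only
# counts the unfolding direction (no refolding term), its reciprocal fixes
# the unfolding rate constants k4 (from G4(I)) and k5 (from G4(II)).

#' Default HDX sampling grid (minutes)
#'
#' The measurement times used after dissolution in D2O: 10 min, 30 min,
#' 1 h, 2 h and 24 h.
#' @export
hdx_default_times <- c(10, 30, 60, 120, 1440)

#' Exchange time of an imino-proton HDX decay
#'
#' Fits `floor + amplitude * exp(-t/tau)` to a peak-volume series and
#' returns the fit; `tau` is the exchange time. The constant floor absorbs
#' residual protonation or peak overlap and is constrained to
#' `[0, min(volume)]` (volumes cannot go below the most-exchanged
#' observation). Because a free floor makes slow decays degenerate on the
#' sparse five-point sampling grid (a shallow fast decay onto a high floor
#' mimics a slow decay), the floor is only retained when it improves the
#' fit significantly over the zero-floor model (partial F-test at
#' `floor_alpha`); otherwise the two-parameter zero-floor fit is
#' reported. A series whose volumes rise overall is rejected: HDX
#' volumes cannot grow.
#'
#' @param series Data frame with columns `time_min` and `volume` (>= 4
#'   points), e.g. from [gen_hdx_series()] or [read_hdx_series()].
#' @param floor_alpha Significance level of the partial F-test that admits
#'   a nonzero floor; default 0.05.
#' @return A `quadkin_exp_fit` with `direction = "decay"`.
#' @examples
#' hdx_exchange_time(gen_hdx_series(tau = 25, seed = 1))
#' @export
hdx_exchange_time <- function(series, floor_alpha = 0.05) {
  if (!all(c("time_min", "volume") %in% names(series))) {
    stop("`series` needs columns `time_min` and `volume`", call. = FALSE)
  }
  v <- series$volume
  if (length(v) < 4L) {
    stop("need at least 4 HDX time points", call. = FALSE)
  }
  if (any(v < 0)) stop("peak volumes must be >= 0", call. = FALSE)
  if (v[length(v)] > v[1]) {
    stop("rising series: HDX peak volumes cannot grow over time",
         call. = FALSE)
  }
  fit0 <- fit_exponential(series, direction = "decay",
                          value_col = "volume", fix_offset = 0)
  fit <- fit0
  n <- length(v)
  if (n >= 5L) {
    fit1 <- tryCatch(
      fit_exponential(series, direction = "decay", value_col = "volume",
                      offset_bounds = c(0, min(v))),
      error = function(e) NULL)
    if (!is.null(fit1)) {
      rss0 <- sum(fit0$residuals^2)
      rss1 <- sum(fit1$residuals^2)
      df1 <- n - 3L
      if (df1 > 0 && rss1 > 0) {
        f_stat <- (rss0 - rss1) / (rss1 / df1)
        if (stats::pf(f_stat, 1, df1, lower.tail = FALSE) < floor_alpha) {
          fit <- fit1
        }
      }
    }
  }
  fit$residue <- attr(series, "residue")
  fit
}

#' Unfolding rate from an HDX exchange-time fit
#'
#' Because exchange from a folded G4 requires an opening event and the HDX
#' time does not count refolding, the unfolding rate is the reciprocal of
#' the exchange time: `k_unfold = 1/tau`. Applied to the G4(I) exchange
#' time this fixes k4; applied to the G4(II) exchange time it fixes k5.
#'
#' @param fit A `quadkin_exp_fit` with `direction = "decay"` (e.g. from
#'   [hdx_exchange_time()]).
#' @return Unfolding rate in min^-1.
#' @examples
#' unfolding_rate_from_hdx(hdx_exchange_time(gen_hdx_series(25, seed = 1)))
#' @export
unfolding_rate_from_hdx <- function(fit) {
  if (!inherits(fit, "quadkin_exp_fit")) {
    stop("`fit` must be a quadkin_exp_fit", call. = FALSE)
  }
  if (!identical(fit$direction, "decay")) {
    stop("HDX unfolding rates come from decay fits, not a rise fit",
         call. = FALSE)
  }
  time_to_rate(fit$tau)
}
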