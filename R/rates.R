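#' Five first-order rate constants of the four-state transition model
#'
#' Bundles the rate constants of the hairpin -> G4(I) -> G4(II) conversion
#' network: `k1` (hairpin unfolding, Hp -> G4(I)), `k2` (folding of the
#' unfolded ensemble U into G4(I)), `k3` (U -> G4(II)), `k4` (G4(I)
#' unfolding, G4(I) -> U) and `k5` (G4(II) unfolding, G4(II) -> U). All
#' rates are first-order and expressed per minute, the unit in which the
#' experimental time constants (CD arising times, HDX exchange times) are
#' measured.
#'
#' @param k1,k2,k3,k4,k5 Non-negative rates in min^-1. Default 0.
#' @return An object of class `quadkin_rates`: a named list with elements
#'   `k1`..`k5`.
#' @examples
#' rate_constants(k1 = 0.25, k4 = 0.04, k5 = 2.6e-4)
#' @export
rate_constants <- function(k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0) {
  k <- list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5)
  for (nm in names(k)) {
    v <- k[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("rate constant `", nm, "` must be a single finite number",
           call. = FALSE)
    }
    if (v < 0) {
      stop("invalid parameter: rate constant `", nm, "` is negative (",
           format(v), "); all rates must be >= 0", call. = FALSE)
    }
  }
  structure(k, class = "quadkin_rates")
}

#' Coerce to a rate-constant set
#'
#' Accepts a `quadkin_rates` object, a named numeric vector or list with
#' elements `k1`..`k5` (missing entries default to 0), or a one-row data
#' frame with those columns (e.g. a row of [builtin_rates()]).
#'
#' @param x Object to coerce.
#' @return A `quadkin_rates` object.
#' @export
as_rate_constants <- function(x) {
  if (inherits(x, "quadkin_rates")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) {
      stop("a data frame of rates must have exactly one row", call. = FALSE)
    }
    x <- as.list(x[intersect(c("k1", "k2", "k3", "k4", "k5"), names(x))])
  }
  x <- as.list(x)
  bad <- setdiff(names(x), c("k1", "k2", "k3", "k4", "k5"))
  if (length(bad) || is.null(names(x))) {
    stop("rates must be named k1..k5 (unexpected: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  do.call(rate_constants, lapply(x, as.numeric))
}

#' @export
print.quadkin_rates <- function(x, ...) {
  cat("<quadkin_rates> (min^-1)\n")
  print(unlist(x))
  invisible(x)
}

#' Convert a measured time constant to a first-order rate
#'
#' The experimental protocol fixes rate constants from measured time
#' constants as their reciprocals: the CD arising time gives the hairpin
#' unfolding rate k1 (4 min -> 0.25 min^-1) and HDX exchange times give the
#' unfolding rates k4 and k5 (25 min -> 0.04 min^-1; 3800 min ->
#' 2.6e-4 min^-1).
#'
#' @param tau Time constant(s) in minutes, strictly positive.
#' @return Rate(s) in min^-1, `1/tau`.
#' @examples
#' time_to_rate(c(4, 25, 3800))
#' @export
time_to_rate <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0)) {
    stop("time constant `tau` must be finite and > 0", call. = FALSE)
  }
  1 / tau
}
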