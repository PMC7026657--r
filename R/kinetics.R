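# Four-state linear kinetic model
#
# State ordering is fixed everywhere in the package as
#   (A, B, D, C) = (Hp, G4(I), U, G4(II))
# with column names (A_hp, B_g4i, D_u, C_g4ii). The network wiring is
#   A --k1--> B,  B --k4--> D,  D --k2--> B,  D --k3--> C,  C --k5--> D
# i.e. the hairpin feeds G4(I) irreversibly (no reverse flux into A), and
# G4(I) and G4(II) exchange through the lumped unfolded ensemble U.

.quadkin_species <- c("A_hp", "B_g4i", "D_u", "C_g4ii")

#' Generator matrix of the four-state model
#'
#' Builds the 4x4 first-order generator over the state order
#' (Hp, G4(I), U, G4(II)). Off-diagonal entry (row j, column i) is the rate
#' of the i -> j transition; diagonal entries make every column sum to zero
#' so that total population is conserved. The hairpin state only loses
#' population (no transition re-enters it).
#'
#' @param k Rate constants; anything accepted by [as_rate_constants()].
#' @return A 4x4 numeric matrix with dimnames
#'   `c("A_hp", "B_g4i", "D_u", "C_g4ii")`.
#' @examples
#' rate_matrix(rate_constants(k1 = 0.25, k2 = 533, k3 = 50,
#'                            k4 = 0.04, k5 = 2.6e-4))
#' @export
rate_matrix <- function(k) {
  k <- as_rate_constants(k)
  M <- matrix(0, 4, 4, dimnames = list(.quadkin_species, .quadkin_species))
  M["B_g4i", "A_hp"]   <- k$k1
  M["D_u", "B_g4i"]    <- k$k4
  M["B_g4i", "D_u"]    <- k$k2
  M["C_g4ii", "D_u"]   <- k$k3
  M["D_u", "C_g4ii"]   <- k$k5
  diag(M) <- diag(M) - colSums(M)
  M
}

.check_state_vector <- function(x0) {
  if (!is.numeric(x0) || length(x0) != 4L || any(!is.finite(x0))) {
    stop("`x0` must be 4 finite numbers in state order (Hp, G4(I), U, G4(II))",
         call. = FALSE)
  }
  if (any(x0 < -1e-9)) {
    stop("`x0` has negative populations", call. = FALSE)
  }
  unname(x0)
}

#' Exact state populations over time
#'
#' Solves the linear rate equations dx/dt = M x exactly by eigendecomposition
#' of the generator matrix: x(t) = V exp(Lambda t) V^-1 x0. For a
#' near-defective spectrum (ill-conditioned eigenvector basis) the solver
#' falls back to a scaling-and-squaring matrix exponential per time point
#' and emits a warning.
#'
#' @param k Rate constants ([as_rate_constants()]).
#' @param x0 Initial populations in state order (Hp, G4(I), U, G4(II)).
#'   Defaults to pure hairpin `c(1, 0, 0, 0)`, the state just before K+
#'   addition.
#' @param times Strictly increasing non-negative times in minutes.
#' @return A tibble with columns `time_min`, `A_hp`, `B_g4i`, `D_u`,
#'   `C_g4ii`, of class `quadkin_trajectory`.
#' @examples
#' k <- rate_constants(k1 = 0.23, k2 = 533, k3 = 50, k4 = 0.037, k5 = 2.7e-4)
#' solve_populations(k, times = c(0, 1, 10, 100, 600))
#' @export
solve_populations <- function(k, x0 = c(1, 0, 0, 0), times) {
  x0 <- .check_state_vector(x0)
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)) ||
      any(times < 0)) {
    stop("`times` must be finite, non-negative minutes", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  M <- rate_matrix(k)
  states <- tryCatch({
    eg <- eigen(M)
    V <- eg$vectors
    if (rcond(Re(V)) < 1e-12) stop("near-defective spectrum")
    coef <- solve(V, x0)
    # 4 x n matrix of populations; coef recycles down the rows
    Re(V %*% (exp(outer(eg$values, times)) * coef))
  }, error = function(e) {
    warning("eigendecomposition ill-conditioned (", conditionMessage(e),
            "); falling back to matrix exponential", call. = FALSE)
    vapply(times,
           function(t) as.numeric(Matrix::expm(M * t) %*% x0),
           numeric(4))
  })
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(t(states)), .quadkin_species))
  out <- dplyr::bind_cols(tibble::tibble(time_min = as.numeric(times)), out)
  class(out) <- c("quadkin_trajectory", class(out))
  out
}

#' Detailed-balance equilibrium populations
#'
#' At long times the hairpin is fully drained (A = 0) and the
#' G4(I) <-> U <-> G4(II) subsystem satisfies detailed balance:
#' B k4 = D k2 and C k5 = D k3, so B : D : C = (k2/k4) : 1 : (k3/k5),
#' normalised to sum to 1. This is how the model connects the fitted rate
#' constants to the NMR-observed conformer populations (~10% G4(I) for
#' WT22m, ~85% for WT22m-5fC4).
#'
#' @param k Rate constants; `k2`, `k3`, `k4`, `k5` must all be > 0.
#' @return A one-row tibble with columns `A_hp` (0), `B_g4i`, `D_u`,
#'   `C_g4ii` summing to 1.
#' @examples
#' equilibrium_populations(
#'   rate_constants(k1 = 0.23, k2 = 533, k3 = 50, k4 = 0.037, k5 = 2.7e-4))
#' @export
equilibrium_populations <- function(k) {
  k <- as_rate_constants(k)
  if (k$k2 <= 0 || k$k3 <= 0 || k$k4 <= 0 || k$k5 <= 0) {
    stop("undefined equilibrium: k2, k3, k4 and k5 must all be > 0",
         call. = FALSE)
  }
  w <- c(k$k2 / k$k4, 1, k$k3 / k$k5)
  f <- w / sum(w)
  tibble::tibble(A_hp = 0, B_g4i = f[1], D_u = f[2], C_g4ii = f[3])
}

#' Slow relaxation time of the G4(I)/U/G4(II) subsystem
#'
#' After the hairpin has drained, interconversion between G4(I) and G4(II)
#' relaxes with the eigenvalues of the three-state sub-generator over
#' (B, D, C). Its nonzero eigenvalues are the roots of
#' \deqn{\lambda^2 - \lambda (k_2+k_3+k_4+k_5) +
#'       (k_4 k_3 + k_4 k_5 + k_2 k_5) = 0,}
#' and the observable slow time constant is the reciprocal of the
#' smaller-magnitude root. With the WT22m rates this is ~290 min, matching
#' the 250 +/- 50 min interconversion time seen by time-resolved NMR.
#' The slow root is evaluated as `p / lambda_fast` (product over the larger
#' root) to avoid cancellation when the two roots are far apart.
#'
#' @param k Rate constants; at least one of `k2`..`k5` must be > 0.
#' @return The slow relaxation time in minutes, with the fast time attached
#'   as attribute `"fast"`. If the slow eigenvalue vanishes (e.g. `k4 = k5 =
#'   0`: no exchange out of the folded states) the relaxation never
#'   completes and `Inf` is returned with a warning.
#' @examples
#' slow_relaxation_time(
#'   rate_constants(k1 = 0.23, k2 = 533, k3 = 50, k4 = 0.037, k5 = 2.7e-4))
#' @export
slow_relaxation_time <- function(k) {
  k <- as_rate_constants(k)
  s <- k$k2 + k$k3 + k$k4 + k$k5
  p <- k$k4 * k$k3 + k$k4 * k$k5 + k$k2 * k$k5
  if (s <= 0) {
    stop("no relaxation: k2..k5 are all zero", call. = FALSE)
  }
  disc <- s^2 - 4 * p
  # wiring guarantees real roots; clamp tiny negative discriminants
  disc <- max(disc, 0)
  lambda_fast <- (s + sqrt(disc)) / 2
  lambda_slow <- if (lambda_fast > 0) p / lambda_fast else 0
  if (lambda_slow <= 0) {
    warning("slow eigenvalue is zero; relaxation time is infinite",
            call. = FALSE)
    return(structure(Inf, fast = 1 / lambda_fast))
  }
  structure(1 / lambda_slow, fast = 1 / lambda_fast)
}
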