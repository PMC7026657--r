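# Four-state model core: generator matrix, exact solution, equilibrium,
# relaxation. Oracle values frozen from independent computations: a stiff
# lsoda integration of the rate equations and a numeric eigensolver of the
# three-state sub-generator.

test_that("rate matrix has generator structure for the network wiring", {
  # no dynamics
  expect_equal(rate_matrix(rate_constants()), matrix(
    0, 4, 4, dimnames = list(c("A_hp", "B_g4i", "D_u", "C_g4ii"),
                             c("A_hp", "B_g4i", "D_u", "C_g4ii"))))
  # single edge Hp -> G4(I)
  M1 <- rate_matrix(rate_constants(k1 = 1))
  expect_equal(M1["A_hp", "A_hp"], -1)
  expect_equal(M1["B_g4i", "A_hp"], 1)
  expect_equal(sum(M1 != 0), 2L)
  # characterised regime: columns conserve, diagonal collects total efflux
  M <- rate_matrix(wt22m_rates())
  expect_equal(unname(colSums(M)), rep(0, 4))
  expect_equal(unname(diag(M)), c(-0.23, -0.037, -583, -2.7e-4))
  # nothing ever returns to the hairpin
  expect_equal(unname(M["A_hp", -1]), rep(0, 3))
  expect_error(rate_constants(k2 = -1), "negative")
})

test_that("exact solution matches closed forms and preserves x0 at t = 0", {
  # frozen system
  traj <- solve_populations(rate_constants(), x0 = c(0.2, 0.3, 0.1, 0.4),
                            times = c(0, 5, 500))
  for (tt in 1:3) {
    expect_equal(unlist(traj[tt, -1], use.names = FALSE),
                 c(0.2, 0.3, 0.1, 0.4), tolerance = 1e-12)
  }
  # single-exponential half-life
  traj <- solve_populations(rate_constants(k1 = 0.25),
                            times = c(0, log(2) / 0.25))
  expect_equal(traj$A_hp[2], 0.5, tolerance = 1e-10)
  expect_equal(traj$B_g4i[2], 0.5, tolerance = 1e-10)
  expect_equal(traj$C_g4ii[2], 0, tolerance = 1e-12)
  expect_equal(unlist(traj[1, -1], use.names = FALSE), c(1, 0, 0, 0),
               tolerance = 1e-12)
  # long-time limit against the stiff-integration oracle (frozen)
  traj <- solve_populations(wt22m_rates(), times = c(0, 1e6))
  expect_equal(traj$B_g4i[2], 0.0721744106, tolerance = 1e-6)
  expect_equal(traj$C_g4ii[2], 0.9278205792, tolerance = 1e-6)
  expect_equal(traj$D_u[2], 5.010231e-06, tolerance = 1e-4)
  expect_lt(traj$A_hp[2], 1e-12)
  expect_error(solve_populations(wt22m_rates(), times = c(3, 2)),
               "increasing")
  expect_error(solve_populations(wt22m_rates(), x0 = c(-1, 0, 0, 1),
                                 times = 0:1), "negative")
})

test_that("populations are conserved and non-negative for random rates", {
  withr::with_seed(42, {
    for (i in 1:25) {
      k <- random_rates()
      x0 <- stats::runif(4)
      traj <- solve_populations(k, x0 = x0,
                                times = c(0, 10^seq(-3, 4, length.out = 15)))
      tot <- rowSums(traj[, -1])
      expect_equal(tot, rep(sum(x0), nrow(traj)), tolerance = 1e-9)
      expect_true(all(as.matrix(traj[, -1]) >= -1e-9))
    }
  })
})

test_that("with no G4(II) unfolding, C(t) is non-decreasing", {
  k <- rate_constants(k1 = 0.25, k2 = 500, k3 = 50, k4 = 0.04, k5 = 0)
  traj <- solve_populations(k, times = seq(0, 2000, by = 2))
  expect_true(all(diff(traj$C_g4ii) >= -1e-12))
})

test_that("detailed-balance equilibrium matches frozen fractions", {
  # symmetry: equal folded/unfolded ratios give B = C
  eq <- equilibrium_populations(rate_constants(k2 = 80, k3 = 8,
                                               k4 = 10, k5 = 1))
  expect_equal(eq$B_g4i, eq$C_g4ii, tolerance = 1e-12)
  # frozen from the ratio formula, cross-checked by stiff integration
  eq <- equilibrium_populations(wt22m_rates())
  expect_equal(eq$B_g4i, 0.0721744106, tolerance = 1e-8)
  expect_equal(eq$C_g4ii, 0.9278205792, tolerance = 1e-8)
  expect_equal(eq$A_hp, 0)
  eq5 <- equilibrium_populations(fc4_rates())
  expect_equal(eq5$B_g4i, 0.8839582732, tolerance = 1e-8)
  # consistency with the dynamic solution at long times
  traj <- solve_populations(wt22m_rates(), times = c(0, 1e7))
  expect_equal(traj$B_g4i[2], eq$B_g4i, tolerance = 1e-6)
  expect_error(equilibrium_populations(rate_constants(k2 = 1, k3 = 1,
                                                      k4 = 1)),
               "undefined equilibrium")
})

test_that("slow relaxation time matches quadratic closed form and oracle", {
  # frozen numeric-eigensolver oracle for the characterised regime
  expect_equal(as.numeric(slow_relaxation_time(wt22m_rates())),
               292.40584, tolerance = 1e-6)
  # hand-checked symmetric case: quadratic roots are exactly 0.04, 1000.04
  tau <- slow_relaxation_time(rate_constants(k2 = 500, k3 = 500,
                                             k4 = 0.04, k5 = 0.04))
  expect_equal(as.numeric(tau), 25, tolerance = 1e-9)
  # agreement with an eigensolver on random rate sets
  withr::with_seed(7, {
    for (i in 1:20) {
      k <- random_rates(1e-3, 1e3)
      Msub <- rate_matrix(k)[2:4, 2:4]
      ev <- sort(abs(eigen(Msub, only.values = TRUE)$values))
      lam_slow <- ev[ev > 1e-11 * max(ev)][1]
      expect_equal(as.numeric(slow_relaxation_time(k)), 1 / lam_slow,
                   tolerance = 1e-7)
    }
  })
  # no exchange out of the folded states: relaxation never completes
  expect_warning(tau0 <- slow_relaxation_time(
    rate_constants(k2 = 1, k3 = 1)), "infinite")
  expect_identical(as.numeric(tau0), Inf)
  expect_error(slow_relaxation_time(rate_constants(k1 = 1)),
               "no relaxation")
})

test_that("G4(I) is a transient kinetic product at the WT22m rates", {
  traj <- solve_populations(wt22m_rates(), times = seq(0, 600, by = 0.5))
  b_eq <- equilibrium_populations(wt22m_rates())$B_g4i
  expect_gt(max(traj$B_g4i) / b_eq, 5)
})
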