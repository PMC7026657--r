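# Linear CD response, the tetrad-directionality CD heuristic, and peak
# integration.

test_that("cd_signal applies the linear response model", {
  traj <- solve_populations(wt22m_rates(), times = 0:100)
  # all coefficients zero: constant baseline
  tr <- cd_signal(traj, cd_coefficients(265, baseline = 7))
  expect_equal(tr$signal, rep(7, 101))
  # pure G4(I) channel: rises on the hairpin-unfolding scale, decays on
  # the slow interconversion scale
  trB <- cd_signal(traj, cd_coefficients(265, c_B = 1))
  expect_equal(trB$signal, traj$B_g4i)
  expect_gt(which.max(trB$signal), 2)
  expect_lt(which.max(trB$signal), 40)
  expect_lt(trB$signal[101], max(trB$signal))
  # qualitative dual-wavelength pattern: rapid 265 growth + slow decay,
  # slow 290/295 growth
  long <- solve_populations(wt22m_rates(), times = 0:600)
  s265 <- cd_signal(long, cd_coefficients(265, c_B = 1, c_C = 0.2))
  s295 <- cd_signal(long, cd_coefficients(295, c_B = 0.1, c_C = 1))
  expect_lt(which.max(s265$signal), 31)
  expect_gt(s265$signal[which.max(s265$signal)], s265$signal[601])
  expect_equal(which.max(s295$signal), 601)
  expect_warning(cd_coefficients(280), "outside the standard set")
})

test_that("cd_signal is linear in the state populations", {
  k <- wt22m_rates()
  co <- cd_coefficients(265, c_A = 0.3, c_B = 1, c_C = 0.2, c_D = 0.1)
  t1 <- solve_populations(k, x0 = c(1, 0, 0, 0), times = 0:50)
  t2 <- solve_populations(k, x0 = c(0, 0.5, 0.25, 0.25), times = 0:50)
  mix <- t1
  mix[, -1] <- 0.6 * t1[, -1] + 0.4 * t2[, -1]
  s_mix <- cd_signal(mix, co)$signal
  s_lin <- 0.6 * cd_signal(t1, co)$signal + 0.4 * cd_signal(t2, co)$signal +
    (1 - 0.6 - 0.4) * co$baseline
  expect_equal(s_mix, s_lin + 0 * s_lin, tolerance = 1e-12)
})

test_that("CD signature follows tetrad hydrogen-bonding directionality", {
  # uniform directionality (parallel-like, the locked intermediate fold)
  expect_identical(predict_cd_signature(
    fold_topology("G4(I)", rep("clockwise", 3))), "265-dominant")
  expect_identical(predict_cd_signature(
    fold_topology("2-layer", rep("counterclockwise", 2))), "265-dominant")
  # hybrid fold: one homo and one hetero stacking interface
  expect_identical(predict_cd_signature(
    fold_topology("G4(II)", c("clockwise", "clockwise",
                              "counterclockwise"))), "mixed 265+295")
  # strictly alternating: antiparallel-like
  expect_identical(predict_cd_signature(
    fold_topology("anti", c("clockwise", "counterclockwise",
                            "clockwise"))), "295-dominant")
  expect_error(fold_topology("thin", "clockwise"), "at least 2")
  expect_error(fold_topology("bad", c("clockwise", "up")))
  # guanine labels within a tetrad are unordered: any permutation of the
  # per-tetrad glycosidic states describes the same fold
  g <- c("syn", "anti", "anti", "anti", rep("anti", 8))
  t_a <- fold_topology("x", rep("clockwise", 3), g)
  t_b <- fold_topology("x", rep("clockwise", 3),
                       c(g[c(3, 1, 4, 2)], g[5:12]))
  expect_identical(predict_cd_signature(t_a), predict_cd_signature(t_b))
  expect_error(fold_topology("x", rep("clockwise", 3), g[1:7]),
               "exactly 4 guanines")
})

test_that("peak integration is trapezoidal with interpolated edges", {
  # unit-height rectangle of width 0.2 ppm
  sp <- tibble::tibble(ppm = seq(10, 11, by = 0.001), intensity = 1)
  expect_equal(integrate_peak(sp, c(10.4, 10.6)), 0.2, tolerance = 1e-9)
  expect_equal(integrate_peak(
    tibble::tibble(ppm = seq(10, 11, 0.001), intensity = 0),
    c(10.2, 10.8)), 0)
  # Lorentzian: the analytic area over +/- w half-widths is
  # a*gamma*2*atan(w); at w = 20 the truncated tails still hold ~3% of
  # a*pi*gamma, so the wide-window integral approaches the full area
  a <- 3; gam <- 0.02
  grid <- seq(11 - 80 * gam, 11 + 80 * gam, by = gam / 50)
  lor <- tibble::tibble(ppm = grid,
                        intensity = a * gam^2 / ((grid - 11)^2 + gam^2))
  vol20 <- integrate_peak(lor, c(11 - 20 * gam, 11 + 20 * gam))
  expect_equal(vol20, a * gam * 2 * atan(20), tolerance = 2e-3)
  vol64 <- integrate_peak(lor, c(11 - 64 * gam, 11 + 64 * gam))
  expect_equal(vol64, a * pi * gam, tolerance = 0.01)
  # descending ppm axis (NMR convention) gives the same volume
  expect_equal(integrate_peak(lor[nrow(lor):1, ],
                              c(11 - 20 * gam, 11 + 20 * gam)), vol20)
  expect_error(integrate_peak(lor, c(11, 11)), "empty window")
  expect_error(integrate_peak(lor, c(0, 1)), "outside")
})
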