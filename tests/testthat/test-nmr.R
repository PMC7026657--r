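# HDX exchange times, peak-volume populations, and melting temperatures.

test_that("HDX exchange-time fits recover the generating tau", {
  # noiseless self-consistency on the experimental grid
  expect_equal(hdx_exchange_time(gen_hdx_series(25, sigma_rel = 0))$tau,
               25, tolerance = 1e-6)
  # middle-quartet set: all residues recovered within 20%
  for (i in seq_along(res <- c("G1", "G10", "G17", "G21"))) {
    s <- gen_hdx_series(25, sigma_rel = 0.02, seed = 40 + i,
                        residue = res[i])
    f <- hdx_exchange_time(s)
    expect_lt(abs(f$tau - 25) / 25, 0.2)
    expect_identical(f$residue, res[i])
  }
  # the destabilised G4(II) regime
  for (seed in 1:5) {
    f <- hdx_exchange_time(gen_hdx_series(40, sigma_rel = 0.02,
                                          seed = 50 + seed))
    expect_lt(abs(f$tau - 40) / 40, 0.2)
  }
  expect_error(hdx_exchange_time(
    tibble::tibble(time_min = c(1, 2, 3, 4), volume = c(1, 2, 3, 4))),
    "rising")
  expect_error(hdx_exchange_time(gen_hdx_series(25)[1:3, ]), "at least")
})

test_that("a residual floor does not bias the exchange time", {
  # noiseless floored decay is recovered exactly
  f0 <- hdx_exchange_time(gen_hdx_series(25, floor = 0.1, sigma_rel = 0))
  expect_equal(f0$tau, 25, tolerance = 1e-6)
  expect_equal(f0$offset, 0.1, tolerance = 1e-6)
  # at 2% noise the median bias stays under 10%
  taus <- vapply(1:60, function(s)
    hdx_exchange_time(gen_hdx_series(25, floor = 0.1,
                                     seed = 700 + s))$tau, numeric(1))
  expect_lt(abs(stats::median(taus) - 25) / 25, 0.1)
})

test_that("recovered exchange times preserve ordering", {
  withr::with_seed(3, {
    for (i in 1:10) {
      tau1 <- exp(stats::runif(1, log(5), log(100)))
      tau2 <- tau1 * exp(stats::runif(1, log(1.5), log(10)))
      f1 <- hdx_exchange_time(gen_hdx_series(tau1, sigma_rel = 0))
      f2 <- hdx_exchange_time(gen_hdx_series(tau2, sigma_rel = 0))
      expect_lt(f1$tau, f2$tau)
    }
  })
})

test_that("HDX exchange times convert to unfolding rates", {
  f25 <- hdx_exchange_time(gen_hdx_series(25, sigma_rel = 0))
  expect_equal(unfolding_rate_from_hdx(f25), 0.04, tolerance = 1e-6)
  f3800 <- hdx_exchange_time(gen_hdx_series(3800, sigma_rel = 0))
  expect_equal(signif(unfolding_rate_from_hdx(f3800), 2), 2.6e-4)
  f1 <- hdx_exchange_time(gen_hdx_series(1, sigma_rel = 0,
                                         times = c(0.1, 0.5, 1, 2, 5)))
  expect_equal(unfolding_rate_from_hdx(f1), 1, tolerance = 1e-6)
  rise <- fit_exponential(gen_arising_trace(4, sigma_rel = 0),
                          direction = "rise")
  expect_error(unfolding_rate_from_hdx(rise), "decay")
})

test_that("peak-volume population estimation", {
  tbl <- tibble::tibble(residue = c("G16", "G18"),
                        vol_g4i = c(10, 10), vol_g4ii = c(90, 90))
  est <- estimate_populations(tbl)
  expect_equal(est$fraction_g4i, 0.10)
  expect_equal(est$fraction_g4ii, 0.90)
  expect_equal(est$dispersion, 0)
  # noiseless generator round-trip is exact
  est2 <- estimate_populations(gen_peak_table(0.37, sigma_rel = 0))
  expect_equal(est2$fraction_g4i, 0.37, tolerance = 1e-12)
  # the demethylated regime at 5% volume noise
  est3 <- estimate_populations(gen_peak_table(0.85, seed = 8))
  expect_gt(est3$fraction_g4i, 0.80)
  expect_lt(est3$fraction_g4i, 0.90)
  # discordant reporters are flagged
  bad <- tibble::tibble(residue = c("G16", "G18"),
                        vol_g4i = c(20, 60), vol_g4ii = c(80, 40))
  expect_warning(est4 <- estimate_populations(bad), "disagree")
  expect_equal(est4$fraction_g4i, 0.4)
  expect_equal(est4$dispersion, 0.4)
  expect_true(est4$flagged)
  expect_error(estimate_populations(tbl, reporters = c("G16", "G99")),
               "G99")
  zero <- tibble::tibble(residue = c("G16", "G18"),
                         vol_g4i = c(0, 1), vol_g4ii = c(0, 1))
  expect_error(estimate_populations(zero), "G16")
})

test_that("Tm estimation recovers generator midpoints", {
  # noiseless: derivative extremum at the logistic midpoint
  tm0 <- estimate_tm(gen_melting_curve(73.0, sigma_rel = 0))
  expect_lt(abs(tm0$tm - 73.0), 0.2)
  expect_gte(tm0$tm_stderr, 0.5)  # never better than half the grid step
  # the locked-fold variant at 1% noise
  tm1 <- estimate_tm(gen_melting_curve(69.2, seed = 17))
  expect_lt(abs(tm1$tm - 69.2), 0.5)
  # degenerate inputs
  expect_error(estimate_tm(melting_curve(10:95, 0.2 * (10:95) + 3)),
               "no transition")
  expect_error(estimate_tm(gen_melting_curve(73)[1:10, ]), ">= 20")
})

test_that("Tm is invariant under affine transforms of the signal", {
  base <- gen_melting_curve(73.0, seed = 23)
  tm_a <- estimate_tm(base)$tm
  for (tf in list(c(5, 0), c(-2, 7), c(0.01, -3))) {
    scaled <- melting_curve(base$temp_C, tf[1] * base$signal + tf[2],
                            cd_wavelength(base))
    expect_lt(abs(estimate_tm(scaled)$tm - tm_a), 0.1)
  }
})

test_that("sharper transitions give larger derivative extrema", {
  sharp <- estimate_tm(gen_melting_curve(50, width = 0.5, sigma_rel = 0))
  broad <- estimate_tm(gen_melting_curve(50, width = 5, sigma_rel = 0))
  expect_gt(max(abs(sharp$derivative$derivative)),
            max(abs(broad$derivative$derivative)))
  expect_lt(abs(sharp$tm - 50), 0.2)
})
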