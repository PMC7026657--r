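# Exponential fitting, time-to-rate conversion, and the constrained
# dual-wavelength global fit.

test_that("single-exponential fits recover noiseless parameters", {
  tr <- gen_hdx_series(tau = 25, sigma_rel = 0)
  f <- fit_exponential(tr, direction = "decay", value_col = "volume")
  expect_equal(f$tau, 25, tolerance = 1e-6)
  expect_equal(f$offset, 0, tolerance = 1e-6)
  rise <- gen_arising_trace(tau = 4, sigma_rel = 0)
  fr <- fit_exponential(rise, direction = "rise")
  expect_equal(fr$tau, 4, tolerance = 1e-6)
  expect_equal(fr$offset, 1, tolerance = 1e-6)
  expect_error(fit_exponential(tr[1:3, ], direction = "decay",
                               value_col = "volume"), "at least")
})

test_that("the arising-time protocol recovers ~4 min from a noisy rise", {
  # fit restricted to the first 20 min, as in the measurement protocol
  for (seed in 1:10) {
    rise <- gen_arising_trace(tau = 4, sigma_rel = 0.02, seed = seed)
    f <- fit_exponential(rise, direction = "rise", t_max = 20)
    expect_lt(abs(f$tau - 4) / 4, 0.15)
    expect_true(all(f$data$time_min <= 20))
  }
})

test_that("measured time constants convert to the protocol's fixed rates", {
  expect_identical(time_to_rate(4), 0.25)
  expect_identical(time_to_rate(25), 0.04)
  expect_equal(signif(time_to_rate(3800), 2), 2.6e-4)
  expect_equal(time_to_rate(c(4, 25)), c(0.25, 0.04))
  expect_error(time_to_rate(0), "> 0")
  expect_error(time_to_rate(-3), "> 0")
})

test_that("noiseless dual-wavelength traces round-trip k2 and k3", {
  tr <- gen_cd_traces(wt22m_rates(), sigma_rel = 0)
  fit <- fit_kinetics(tr$trace265, tr$trace295, fixed = wt22m_fixed)
  k <- setNames(fit$rates$estimate, fit$rates$term)
  expect_lt(abs(k[["k2"]] - 533) / 533, 1e-3)
  expect_lt(abs(k[["k3"]] - 50) / 50, 1e-3)
  # fixed rates are returned bit-exactly
  expect_identical(k[["k1"]], wt22m_fixed[["k1"]])
  expect_identical(k[["k4"]], wt22m_fixed[["k4"]])
  expect_identical(k[["k5"]], wt22m_fixed[["k5"]])
  expect_lt(fit$residual_norm, 1e-6)
  # the fitted response coefficients recover the generator's channels
  co <- fit$coefficients
  cB265 <- co$estimate[co$channel == "g4i" & co$term == "c_B"]
  cC265 <- co$estimate[co$channel == "g4i" & co$term == "c_C"]
  expect_equal(cC265 / cB265, 0.2, tolerance = 1e-3)
})

test_that("noiseless round-trip holds across the fast-folding regime", {
  # k2, k3 log-uniform over the plausible ranges; recovery to <= 1%
  withr::with_seed(11, {
    k2s <- exp(stats::runif(12, log(10), log(2000)))
    k3s <- exp(stats::runif(12, log(5), log(500)))
  })
  for (i in seq_along(k2s)) {
    k <- rate_constants(0.23, k2s[i], k3s[i], 0.037, 2.7e-4)
    tr <- gen_cd_traces(k, sigma_rel = 0)
    fit <- fit_kinetics(tr$trace265, tr$trace295, fixed = wt22m_fixed)
    expect_lt(abs(fit$rates$estimate[2] - k2s[i]) / k2s[i], 0.01)
    expect_lt(abs(fit$rates$estimate[3] - k3s[i]) / k3s[i], 0.01)
  }
})

test_that("noisy WT22m-regime fits stay inside the reported uncertainties", {
  for (seed in 1:5) {
    tr <- gen_cd_traces(wt22m_rates(), sigma_rel = 0.02, seed = 300 + seed)
    fit <- suppressWarnings(
      fit_kinetics(tr$trace265, tr$trace295, fixed = wt22m_fixed))
    expect_lt(abs(fit$rates$estimate[2] - 533), 173)
    expect_lt(abs(fit$rates$estimate[3] - 50), 20)
    # the partition ratio is the identified combination: finite stderr
    expect_true(is.finite(fit$ratio_stderr))
    expect_lt(abs(fit$ratio - 533 / 50) / (533 / 50), 0.1)
  }
})

test_that("the flat k2/k3 magnitude direction is flagged, not hidden", {
  tr <- gen_cd_traces(wt22m_rates(), sigma_rel = 0.02, seed = 99)
  expect_warning(
    fit <- fit_kinetics(tr$trace265, tr$trace295, fixed = wt22m_fixed),
    "flat likelihood")
  expect_true(fit$flat_likelihood)
  expect_true(all(!is.finite(fit$rates$std.error[2:3]) |
                    fit$rates$std.error[2:3] / fit$rates$estimate[2:3] > 1))
})

test_that("fit_kinetics validates its inputs", {
  tr <- gen_cd_traces(wt22m_rates(), sigma_rel = 0, times = 0:50)
  expect_error(fit_kinetics(tr$trace265, tr$trace295,
                            fixed = c(k1 = 0.23, k4 = 0.037)), "k5")
  expect_error(fit_kinetics(tr$trace265, tr$trace295,
                            fixed = c(k1 = 0.23, k4 = 0, k5 = 1)), "> 0")
  flat <- tr$trace265
  flat$signal <- rep(1, nrow(flat))
  expect_error(fit_kinetics(flat, tr$trace295, fixed = wt22m_fixed),
               "constant")
  expect_error(fit_kinetics(tr$trace265, tr$trace295, fixed = wt22m_fixed,
                            init_guess = c(k2 = -5, k3 = 10)), "positive")
})
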