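# Shared fixtures: the characterised rate regimes and their fixed-rate
# subsets, used across the kinetics, estimation and acceptance tests.

wt22m_rates <- function() {
  rate_constants(k1 = 0.23, k2 = 533, k3 = 50, k4 = 0.037, k5 = 2.7e-4)
}

fc4_rates <- function() {
  rate_constants(k1 = 0.58, k2 = 653, k3 = 73, k4 = 0.027, k5 = 0.023)
}

wt22m_fixed <- c(k1 = 0.23, k4 = 0.037, k5 = 2.7e-4)
fc4_fixed <- c(k1 = 0.58, k4 = 0.027, k5 = 0.023)

# log-uniform random rate set in a given regime, for property tests
random_rates <- function(lo = 1e-4, hi = 1e3) {
  r <- exp(stats::runif(5, log(lo), log(hi)))
  rate_constants(r[1], r[2], r[3], r[4], r[5])
}
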