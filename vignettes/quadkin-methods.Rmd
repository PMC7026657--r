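---
title: "Four-state kinetics of the hairpin to G-quadruplex transition: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-state kinetics of the hairpin to G-quadruplex transition: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadkin)
```

## The system and the model

The WNT1-promoter 22-mer WT22m
(`GGGCCACCGGGCAGTGGGCGGG`) folds as a Watson-Crick hairpin (Hp) in the
absence of potassium. On addition of K+ it converts first into an
atypical, parallel-like quadruplex G4(I) — the kinetically trapped
intermediate, which a C4-to-T substitution can lock — and then slowly
into the thermodynamically favoured hybrid quadruplex G4(II). The two
folded forms exchange through an ensemble of unfolded and partially
folded chains, lumped here into a single well-mixed state U with no
internal structure.

`quadkin` models this as a linear first-order network over the state
vector (A, B, D, C) = (Hp, G4(I), U, G4(II)):

$$
\mathrm{Hp} \xrightarrow{k_1} \mathrm{G4(I)}
\underset{k_2}{\overset{k_4}{\rightleftharpoons}} \mathrm{U}
\underset{k_5}{\overset{k_3}{\rightleftharpoons}} \mathrm{G4(II)}
$$

with no reverse flux into the hairpin (refolding of Hp against the K+
drive is negligible on the experimental timescale). All rates are in
min^-1; all times in minutes. The state ordering (A, B, D, C) is fixed
throughout the package, including file formats.

Because the system is linear, `solve_populations()` computes the exact
solution $x(t) = V e^{\Lambda t} V^{-1} x_0$ by eigendecomposition of the
generator matrix; a scaling-and-squaring matrix exponential is the
fallback when the eigenvector basis is ill-conditioned
(reciprocal condition number below 1e-12). The default initial
condition is pure hairpin, the state at the moment of K+ addition.

Two derived quantities connect the rates to independent observations:

* **Equilibrium populations** (`equilibrium_populations()`). With A
  drained, detailed balance on the B–D–C chain gives
  B : D : C = (k2/k4) : 1 : (k3/k5). With the characterised WT22m rates
  this yields ~7% G4(I), matching the ~10% seen in equilibrium NMR
  spectra; with the 5fC4-modified rates it yields ~88% G4(I) against the
  observed ~85%.
* **Slow relaxation time** (`slow_relaxation_time()`). The nonzero
  eigenvalues of the three-state sub-generator solve
  $\lambda^2 - \lambda(k_2+k_3+k_4+k_5) + (k_4 k_3 + k_4 k_5 + k_2 k_5) = 0$;
  the reciprocal slow root is ~292 min for WT22m, inside the 250 ± 50 min
  interconversion time observed by time-resolved NMR. The slow root is
  evaluated as the constant term divided by the fast root, which is
  numerically stable when the roots are far apart.

## The measurement protocol

The package reproduces the experimental fitting chain:

1. **Arising time → k1.** The initial growth of the 265-nm CD signal is
   fit with a single exponential restricted to the first 20 min
   (`fit_exponential(..., t_max = 20)`); its time constant is the
   hairpin unfolding time (~4 min), and `time_to_rate()` fixes
   k1 = 1/tau = 0.25 min^-1.
2. **HDX → k4, k5.** Imino-proton peak volumes after dissolution in D2O
   decay single-exponentially; because exchange counts only unfolding
   (refolding does not return a proton), the unfolding rates are the
   reciprocal exchange times: k4 = (25 min)^-1 = 0.04 min^-1 from
   G4(I), k5 = (3800 min)^-1 = 2.6e-4 min^-1 from G4(II) in WT22m.
3. **Global fit → k2, k3.** `fit_kinetics()` jointly fits the 265-nm
   (G4(I)-reporting) and 290/295-nm (G4(II)-reporting) kinetic traces
   with k1, k4, k5 fixed. The species CD responses enter linearly, so
   each trial (k2, k3) is scored by variable projection: solve the
   trajectory once, then solve the per-trace linear least-squares
   problem in closed form. The free rates are optimised on the log
   scale (positivity; tames the ten-fold scale difference), from a
   5 × 5 log-spaced multi-start grid over k2 ∈ [10, 2000] and
   k3 ∈ [5, 500] min^-1, polishing the best grid point by Nelder-Mead.

Whether the two wavelengths were fitted simultaneously or sequentially
is not prescribed by the protocol; joint fitting is adopted here, with
both traces normalised to unit peak-to-peak amplitude so neither
channel dominates the joint residual, and equal weights within a trace.
The 290 nm versus 295 nm labelling of the G4(II) channel is preserved
as metadata and not resolved; both labels address the same channel.

### The linear response model and what is identifiable

The measured signal is modelled as
`baseline + c_A A(t) + c_B B(t) + c_C C(t) + c_D D(t)`. Hp and U are not
assumed CD-silent, but population conservation (A+B+C+D constant)
together with the quasi-stationary, never-accumulating U makes the
regressors [1, A, B, C, D] numerically rank-deficient. The fitted linear
model is therefore `baseline + c_B B + c_C C`, with the Hp and U
responses absorbed into the baseline and the B/C coefficients; this
changes nothing observable and keeps the linear stage well-conditioned.
Whether pure G4(II) contributes a minor 265-nm shoulder is left to the
data: `c_C` at 265 nm is a free coefficient.

A genuine identifiability limit shapes the design of `fit_kinetics()`
and deserves emphasis. U folds on the sub-second scale
(k2 + k3 of order several hundred per minute) while the traces are
sampled every minute, so U is always at its quasi-steady level of order
1e-5 of the population. Every slow observable — the partition of the
initial rise, the slow relaxation rate, the equilibrium plateau —
depends on k2 and k3 only through their ratio. The *common magnitude*
of (k2, k3) touches the data only through that 1e-5 steady-state U
population: far below any realistic noise. Consequences, all verified
by simulation in the test suite:

* On noiseless synthetic data the magnitude *is* identified (the
  residual minimum is exactly at the generating values), and the fit
  recovers k2 and k3 to better than 0.1%. The optimiser detects the
  effectively-noiseless case from the residual scale and then refines
  to full precision; on noisy data it stops once improvements fall
  below the noise-driven plateau, which leaves the magnitude near the
  best multi-start grid point.
* On noisy data the magnitude direction is flat. The fit reports
  honestly wide (typically infinite) standard errors for k2 and k3,
  sets the `flat_likelihood` flag, and additionally reports the
  *identified* combination — the partition ratio k2/k3 — with its
  finite standard error (the log-ratio is orthogonal to the flat
  direction). Uncertainty calibration is therefore assessed on the
  log-ratio: across 200 noisy replicates at the WT22m setting, ~68% of
  fits cover the true ratio at 1 sigma.
* The polish is soft-constrained to the multi-start box: U is
  spectroscopically invisible in the experiments, so solutions in which
  it accumulates (small k2 + k3) are excluded a priori. Without this
  constraint a noisy fit can wander into a structurally different
  low-rate regime that overfits noise.
* In the 5fC4-modified regime the limit is more severe: there
  k4 ≈ k5, so the slow relaxation rate
  (k3 k4 + k2 k5)/(k2 + k3) is nearly independent of the partition
  ratio, and the 265-nm trace shows no decay (G4(I) transient ≈
  equilibrium share). At 2% noise the traces then carry almost no
  information about k2 and k3 individually, and single-replicate
  recovery within the reported uncertainties cannot be expected from
  these two traces alone.

Standard errors come from the Jacobian covariance of the full residual
vector at the optimum, computed by eigendecomposition of the normal
matrix so that curvature-free directions yield infinite marginal
variance rather than a misleadingly finite number; an optional check of
any direction's variance uses only the identified subspace (profile
variance).

## Auxiliary estimators

**HDX exchange times** (`hdx_exchange_time()`) are fit on the
experimental sampling grid (10, 30, 60, 120, 1440 min). A constant
floor absorbs residual protonation or peak overlap, but a free floor
makes slow decays degenerate on five points: a shallow fast decay onto
a high floor reproduces a tau ≈ 3800 min series to within noise. The
floor is therefore admitted only when a partial F-test (alpha = 0.05)
prefers it over the zero-floor model. With this rule the median
recovery error at tau = 3800 min and 2% noise is ~0.2% (it was ~86%
with an always-free floor), while a genuinely floored decay
(floor = 0.1 v0) is still recovered without bias.

**Melting temperatures** (`estimate_tm()`) follow the operational rule:
baseline-correct, smooth, differentiate, and take the temperature of
the first-derivative extremum. Baseline correction uses separate linear
fits to the coolest and hottest 10% of points and converts the signal
to fraction folded, `(y - b_unfolded)/(b_folded - b_unfolded)` — for a
two-state melt this removes baseline-slope bias exactly, where
subtracting a single common line leaves a bias of a few tenths of a
degree. Smoothing is Savitzky-Golay (window 7 points, order 2, suited
to the 1 °C grid; both exposed as arguments). The grid extremum is
refined by a quadratic fit to the derivative over ±5 points (the
two-state derivative peak is locally quadratic over about its
half-width); the reported uncertainty is the larger of half the grid
step and the quadratic vertex standard error. The estimator is exactly
invariant under affine transforms of the signal, and the extremum of
|derivative| is used with the sign recorded, so rising- and
falling-signal channels are both handled.

**Populations from peak volumes** (`estimate_populations()`) use the
resolved reporter residues G16 and G18 by default: per residue,
fraction G4(I) = V_I/(V_I + V_II); the overall fraction is the mean
over reporters and the spread (max − min) is reported as a dispersion,
with a warning above 0.15 — a threshold motivated by the protocol's use
of exactly two reporters with no stated concordance rule. Peak volumes
themselves can be obtained from a 1D spectrum with `integrate_peak()`
(trapezoidal, with edge interpolation; note that a Lorentzian
integrated over ±20 half-widths still misses ~3% of its total area, so
windows should be generous).

**CD signature heuristic** (`predict_cd_signature()`): the 265- and
295-nm bands are governed mainly by the hydrogen-bonding
directionality pattern of the stacked G-tetrads. Uniform directionality
(all stacking interfaces alike) → "265-dominant"; strictly alternating
→ "295-dominant"; both interface kinds present (hybrid folds such as
G4(II)) → "mixed 265+295". This is a qualitative three-way label, not a
spectrum simulation.

## The synthetic-data generators

All inputs the pipeline consumes can be generated
(`gen_cd_traces()`, `gen_melting_curve()`, `gen_hdx_series()`,
`gen_peak_table()`, `gen_arising_trace()`), as pure functions of
(parameters, seed) that leave the global RNG untouched. They emulate:

* CD kinetic traces: the four-state forward model on a 1-min grid to
  600 min (the monitored duration), with additive Gaussian noise of
  2% of the noiseless peak-to-peak amplitude by default — chosen to
  match the visual tightness of experimental kinetic traces, which
  publish no noise figure. Default channel responses are c_B = 1,
  c_C = 0.2 at 265 nm and c_B = 0.1, c_C = 1 at 295 nm, reproducing
  the observed rapid-growth/slow-decay and slow-growth pattern.
* Melting curves: a logistic fraction-folded
  θ(T) = 1/(1 + exp((T − Tm)/width)) mixed with sloping linear
  baselines on the 10–95 °C, 1 °C grid, 1% noise. A logistic is used
  rather than a full van't Hoff two-state form because only the
  derivative-extremum location matters to the estimator, and the
  logistic places that truth exactly at Tm.
* HDX series: floor + v0 exp(−t/tau) on the experimental grid with 2%
  multiplicative noise.
* Peak tables: a total volume split at the prescribed G4(I) fraction
  with 5% multiplicative volume noise.

`builtin_variants()` carries the nine-member WT22m sequence family with
measured melting temperatures, and `builtin_rates()` the three
characterised rate regimes (WT22m, 5mC4, 5fC4); the epigenetic variants
map to their regimes by parameter lookup — no chemistry is modelled.

What the generators deliberately do not emulate: spectrometer drift and
baseline wander in time, photobleaching, correlated (1/f) noise, NMR
lineshape distortions and peak overlap, temperature-dependent rate
constants, and intermolecular quadruplex species (excluded by the
sequence design). Passing tests on synthetic data therefore demonstrate
correctness of the estimators under the stated noise model, not
robustness to every artefact of real spectra.

## Numerical and design choices

* Eigendecomposition is the primary solver (exact for a linear system);
  the `Matrix::expm` fallback triggers on an ill-conditioned
  eigenvector basis and warns.
* `slow_relaxation_time()` uses the product-over-fast-root form of the
  quadratic to avoid catastrophic cancellation; with k4 = k5 = 0 the
  slow root vanishes and the function returns `Inf` with a warning.
* Degenerate inputs error early with informative messages: negative
  rates, non-monotone time grids, rising HDX series, melting curves
  with no detectable transition (signal range below five times the
  local noise estimated from the end segments), reporter residues that
  are missing or have zero volume.
* File formats are plain CSV with `# key=value` metadata comments; LF
  and CRLF both parse, and malformed rows are reported with their line
  number. Reports are JSON plus a text summary, with no timestamps, so
  identical (config, seed) runs are byte-identical.
* The full pipeline (`run_full_pipeline()`) derives one sub-seed per
  stage from the configured seed, so every stage is independently
  reproducible.

Problem sizes used in the shipped tests and acceptance analyses — 600
1-min points per CD trace, 86-point melting curves, 5-point HDX series,
and 100–200 replicates for oracle, recovery and calibration checks —
mirror the experimental designs they emulate while keeping each
analysis in the seconds-to-a-minute range.

## Known limitations

* The k2/k3 magnitude is not identifiable from noisy CD traces (see
  above); only the ratio and the relaxation rate are. Reported k2, k3
  values on noisy data inherit their scale from the multi-start
  protocol and should be read together with `flat_likelihood`, the
  ratio, and its standard error.
* U is a single well-mixed state; any internal structure of the
  intermediate ensemble (additional transient states between the two
  folds) is beyond the model's resolution.
* No temperature dependence of rates, no stochastic single-molecule
  simulation, no van't Hoff thermodynamics from melting curves, no
  multi-exponential HDX, and no ab initio CD spectrum prediction.
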