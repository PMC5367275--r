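---
title: "Decoding fish chronotypes from acoustic telemetry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding fish chronotypes from acoustic telemetry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chronotrack` implements a complete analysis chain for quantifying
*chronotypes* — consistent between-individual differences in the daily
timing of behaviour — in free-ranging fish tracked with acoustic telemetry.
This vignette explains the models, the tunable parameters, the synthetic
data generator used for validation, and the design choices made where the
method left room for judgement.

## The analysis chain

A tagged fish emits an acoustic ping roughly every minute while it is out of
the sand; when it buries to rest, the sand attenuates the signal and
detections almost cease. The pipeline turns the raw detection time series
into population-level statements in five stages:

1. **Cleaning and binning** (`cleanDetections()`, `binDetections()`):
   detections recorded during a post-tagging abnormal-behaviour window are
   discarded (default 2 days, configurable) and isolated detections — fewer
   than `spuriousK = 2` companions in the surrounding 24 h — are removed as
   spurious, iterating to a fixed point so cleaning is idempotent. Surviving
   detections are pooled into contiguous 5-min bins (half-open intervals,
   whole midnight-to-midnight days).
2. **State decoding** (`fitHMM()`, `decodeStates()`): one two-state hidden
   Markov model with Poisson emissions is fitted per fish over its whole
   multi-day chain by expectation–maximization (Baum–Welch), and the
   active/rest path decoded globally by the Viterbi algorithm.
3. **Circadian traits** (`buildTraitTable()`): per fish-day, awakening time
   (start of the first active bin minus sunrise, signed minutes), rest onset
   (end of the last active bin minus sunset, signed minutes) and rest
   duration (previous day's rest onset to the current day's awakening, in
   hours).
4. **Movement** (`fitOU()`, `smoothPositions()`, `dailyDistance()`): noisy
   positions on a 15-min grid are smoothed under an Ornstein–Uhlenbeck (OU)
   home-range model and daily travelled distance is the summed Euclidean
   length of the smoothed path within each day.
5. **Variance decomposition** (`fitLMM()`, `adjustedR()`, `fitBivariate()`):
   Bayesian random-intercept mixed models decompose each trait's variance
   into between- (V_ind0) and within-individual (V_e0) components; adjusted
   repeatability is R = V_ind0 / (V_ind0 + V_e0). Bivariate models decompose
   the correlation of each trait pair into between-individual (r_ind) and
   residual (r_e) parts.

`runPipeline()` composes all stages and derives every stage seed
deterministically from one master seed via `deriveSeed()`, so a rerun with
the same inputs reproduces every reported number.

## The hidden Markov model

The observation chain for one fish is the sequence of detection counts in
5-min bins. Counts are modelled as Poisson with state-dependent rate:
lambda_A per bin while active, lambda_R while resting (resting detections
are rare but not absent — a fish buried near a receiver still gets through
occasionally). The latent state follows a two-state Markov chain with a
2 x 2 transition matrix. Numerics:

- Forward–backward uses scaled recursions with a per-bin log-shift, so
  underflow is impossible at any chain length (a 14-day chain is 4032 bins).
- EM runs five seeded restarts (first from a two-group split of the counts,
  the rest randomized), keeps the best likelihood, and asserts the
  log-likelihood trace is non-decreasing. Convergence is a relative
  tolerance of 1e-8, at most 500 iterations.
- After fitting, `labelStates()` names the larger-rate state "active". A
  chain that cannot separate two rates (e.g. all zeros) is flagged
  degenerate rather than relabelled.
- Decoding is global (Viterbi) by default; ties are broken toward rest,
  which is conservative for awakening detection. Posterior (local) decoding
  is available as a sensitivity option; the two differ only at ambiguous
  bins.

## Trait definitions and edge cases

Days are midnight-to-midnight local time (timestamps are naive local time;
the tracking window is assumed DST-free). Awakening uses the *start* of the
first active bin, rest onset the *end* of the last active bin — the moments
activity begins and ceases. Rest duration spans the night, so it pairs the
previous day's onset with the current day's awakening; the first tracked day
of each fish therefore has no rest duration, and days with no decoded active
bin yield invalid (NA) traits rather than zeros or censored values. Isolated
single active bins are kept as decoded; an optional minimum-bout filter
(`minBout`) exists but is off by default, so the decoded path is reported
as-is.

## The movement model

Each coordinate axis follows a mean-reverting OU process with home-range
centre c, attraction rate beta (h^-1) and diffusion sigma (m h^-1/2); the
stationary standard deviation sigma / sqrt(2 beta) sets the home-range size.
The exact discretization is used both for simulation and for the
linear-Gaussian Kalman filter/smoother; observations add i.i.d. Gaussian
positional noise (`obsSd`, metres), and missing grid points are skipped by
the filter so irregular coverage is supported. Parameters are estimated by
maximizing the prediction-error likelihood with positivity enforced on the
log scale; bound hits are flagged (`obsSd` is weakly identified when the
step displacement dwarfs the positional noise, and honestly pins itself at a
bound in such fits). Distances use the posterior-mean positions.

Defaults (beta = 0.2 h^-1, stationary sd = 15 m, obsSd = 5 m) were chosen so
that a fish travelling on this home range at 15-min steps covers roughly
550 m per day, the scale reported for the study species; they are generator
settings, not fitting constraints.

## The mixed models

Per trait, the univariate model is trait ~ fixed effects + fish intercept,
with fixed effects drawn from sex, home-range-centre latitude/longitude
(mean-centred, per km) and year plus their two-way interactions. Rest
duration and travelled distance are log-transformed. The Gibbs sampler uses
the conjugate updates with the weak defaults of the standard animal-model
software this mirrors: fixed effects N(0, 1e10), variances
inverse-gamma(nu/2, nu V/2) with nu = 0.002, V = 1 (a `nuScale` flag doubles
or halves nu for sensitivity checks); 13 000 iterations, 3 000 burn-in,
thinning 10. Split-chain potential-scale-reduction diagnostics are reported
per parameter. The bivariate model gives the pair of fish intercepts a 2 x 2
between-individual covariance and the residuals a 2 x 2 residual covariance,
both with the weak inverse-Wishart prior (V = identity, nu = 1.002); its
reference settings are 1 300 000 / 300 000 / 1000, with desk-scale defaults
one tenth of that (130 000 / 30 000 / 100), which reproduce the same
posterior summaries to well within Monte-Carlo error on study-sized data.

**DIC.** Model comparison uses the *conditional*-deviance DIC:
Dbar = posterior mean of -2 log L(y | beta, u, V_e) and
DIC = 2 Dbar - D(posterior means). DIC variants differ across software; this
is the variant of the mixed-model engine the analysis mirrors, and all
delta-DIC rules in the package (significance of R when the
V_ind0-constrained model loses by more than 2; significance of each
covariance against its diagonal-constrained model) use it consistently.

Two behavioural consequences of the conditional focus are worth knowing.
First, the random intercepts dominate the effective-parameter count, so the
delta-DIC test of V_ind0 is well behaved (see the calibration tests).
Second, *between-individual* fixed effects trade off against the fish
intercepts and contribute almost nothing to the effective-parameter count;
dropping a pure-noise between-fish covariate therefore tends to *raise* the
conditional DIC slightly, and the bidirectional stepwise search
(`stepwiseReduce()`) is intentionally conservative — it reliably keeps real
effects and respects marginality (an interaction is only present with both
mains), but often retains weak covariates too. Since adjusted repeatability
conditions on the retained fixed effects either way, this conservatism
changes R very little. Each stepwise candidate is fitted with a seed derived
from its term set, so DIC comparisons are not dominated by Monte-Carlo
noise, and the DIC's Monte-Carlo standard error is reported alongside.

**Durbin–Watson.** Temporal autocorrelation of the residuals would inflate R
(pseudo-repeatability). The statistic is the within-fish sum of squared
lag-1 residual differences over the total sum of squares (differences never
span fish boundaries; about 2 under independence). The one-sided p-value
(alternative: autocorrelation > 0) comes from a within-fish permutation null
(2000 permutations by default, seeded) — the reference analysis does not
state its p-value source, and the permutation null is exact under
exchangeability without distributional assumptions.

**Correlation decomposition.** Per posterior draw,
r_ind = Sigma_ind[1,2] / sqrt(Sigma_ind[1,1] Sigma_ind[2,2]), r_e
analogously, and the phenotypic correlation r_P is computed from the summed
matrix Sigma_ind + Sigma_e (the model-implied phenotypic covariance) rather
than from the raw product-moment correlation: this keeps the algebraic
identity r_P = r_ind sqrt(R1 R2) + r_e sqrt((1 - R1)(1 - R2)) exact per
draw, which the tests verify to 1e-12. Each covariance is tested separately
against its own diagonal-constrained refit, mirroring how between- and
residual covariances are reported separately.

## The synthetic-data generator

`generateDataset()` simulates the whole study forward from a
`PopulationTruth`: per-fish latent trait means from a multivariate normal
with covariance diag(sqrt(V_ind)) rho_ind diag(sqrt(V_ind)) around
covariate-shifted population means; daily values add within-individual
deviations with covariance from rho_e and V_e; the active window between the
realized awakening and rest onset is snapped to the 5-min grid; per-bin
detection counts are Poisson(lambda_A or lambda_R) and expanded into
sub-second timestamps (or deterministic one-per-minute pings for exact
round-trip checks). Defaults mirror the study: 14 fish (6 + 8 across two
years) for 14 days, variance components and fixed-effect coefficients at the
reported posterior means, lambda_A = 4 per 5-min bin (minute-spaced pings at
realistic detection probability) and lambda_R = 0.2 (a free choice — the
resting detection rate is not reported — kept configurable).

Design points:

- The within-day structure is a single rest → active → rest cycle (a
  diurnal, sand-burying species); no midday rest bouts by default.
- Rest duration is **derived**, not drawn: it is computed from the realized
  previous-day onset and current-day awakening, so its variance components
  are implied by those of the two timing traits. With independent traits the
  components add; consequently the rest-duration repeatability always lies
  between the awakening and onset repeatabilities, and the recovery tests
  choose equal total variances (awakening R = 0.5, onset R = 0.3, each with
  total variance 1000 min^2) precisely so the implied rest-duration R is
  exactly 0.4. The same arithmetic makes the *residual correlation* between
  rest duration and the timing traits large by construction, so properties
  that posit independent trait noise (e.g. the correlation-structure check)
  use the `fullyGaussianTraits` shortcut, under which all four traits are
  drawn directly from their variance layers.
- Distance is generated through the movement layer by default: each fish
  gets an OU parameter set whose log-diffusion carries the distance trait's
  between-individual spread and covariate effects, plus a day-to-day
  log-normal activity multiplier (`dailySdLog = 0.25`) supplying
  within-individual variance. Because daily distance averages ~96 steps and
  smoothing removes day-level noise, the *estimated* distance repeatability
  from the movement pipeline is emergent and typically higher than the
  nominal Gaussian-layer value — a property of the estimation chain, not a
  bug. A fully-Gaussian shortcut (`distanceMode = "gaussian"`) draws daily
  log-distances directly when exact control of R is needed (as in the
  recovery tests).
- Coordinate fixed effects are applied per km of mean-centred home-range
  coordinate (the printed coefficients' scale is not stated in the source
  table; per-km is the only scale at which effects of that magnitude are
  physically sensible for a rectangle a couple of km across).
- Sun times drift linearly by 0.5 min/day across the window; all fish share
  one simulated tracking window, with year as a pure factor covariate.

What the generator does *not* emulate: receiver-array geometry and
environment-dependent detection probability (positions are observed with
plain Gaussian noise), activity-coupled movement (the track runs all day,
night steps included), tag failure, or mid-day predator-driven rest bouts
(available via an optional flag in spirit, off by default). Passing the
recovery tests therefore demonstrates that the estimation chain inverts the
generative assumptions correctly — not that those assumptions capture every
feature of field data.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
exhaustive path enumeration for the HMM (likelihood, posteriors, Viterbi on
short chains), dense multivariate-normal conditioning for the Kalman
smoother, method-of-moments/REML estimators for the variance components,
exact conjugate posteriors for the Gibbs intercepts, and hand-computed
Durbin–Watson cases. Simulation-based checks use 30 fish x 20 days for
parameter recovery and delta-DIC calibration, 14 x 14 (the study scale) for
the correlation-structure property, and 10 seeds or 20 replicates per
property — sizes at which the Monte-Carlo spread of each statistic is
comfortably inside the asserted tolerance.

## Known limitations

- Only two HMM states, no covariate-dependent transitions; fish with
  genuinely richer behavioural repertoires will fold extra states into the
  nearest of active/rest.
- The movement observation model is i.i.d. Gaussian noise on a regular grid;
  real acoustic positioning error is heteroscedastic and gappy in ways the
  filter's missing-data support only partly captures.
- Conditional-DIC stepwise reduction is conservative (see above).
- r_P is model-implied; with strong non-normality the raw phenotypic
  correlation can differ.
- The per-stage results are not cached across runs; reruns recompute every
  stage from the master seed (cheap at study scale, and it keeps
  reproducibility trivially auditable).
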