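# chronotrack

Chronotypes — consistent between-individual differences in the daily timing
of behaviour — can be measured in free-ranging fish by acoustic telemetry: a
tagged fish pings every minute while it forages over the sand, and nearly
falls silent when it buries to rest at night. `chronotrack` turns such
detection time series into population-level chronotype statistics:

- **State decoding.** Per fish, detection counts pooled in 5-min bins form
  the observation chain of a two-state hidden Markov model with Poisson
  emissions (rates λ_A > λ_R), fitted by Baum–Welch EM and decoded by
  Viterbi.
- **Circadian traits.** From the decoded path and local sun times:
  awakening time (first active bin relative to sunrise, min), rest onset
  (last active bin relative to sunset, min) and rest duration (previous
  onset to current awakening, h).
- **Daily travelled distance.** Noisy 15-min positions are smoothed under an
  Ornstein–Uhlenbeck home-range model (Kalman filter/smoother, ML parameter
  estimation) and daily distance is the summed Euclidean path length.
- **Repeatability.** Bayesian random-intercept mixed models (Gibbs
  sampling, weak conjugate priors) decompose each trait's variance into
  between- (V_ind0) and within-individual (V_e0) parts; adjusted
  repeatability is

  R = V_ind0 / (V_ind0 + V_e0),

  with 95% credible intervals, DIC-based fixed-effect reduction, a ΔDIC > 2
  significance rule against the V_ind0 = 0 model, and a Durbin–Watson
  permutation check against pseudo-repeatability.
- **Behavioural syndromes.** Bivariate mixed models (inverse-Wishart priors,
  V = I₂, ν = 1.002) decompose each trait pair's correlation into
  between-individual (r_ind), residual (r_e) and phenotypic (r_P)
  correlations with ΔDIC significance per covariance.

A synthetic-telemetry generator (`generateDataset()`) simulates the whole
study — latent individual means, daily trait realizations, Poisson
detection rendering, OU movement tracks — with known ground truth, so every
stage is validated by parameter recovery without any field data.

## Worked example

```r
library(chronotrack)

ds  <- generateDataset(populationTruth(), seed = 42)   # 14 fish x 14 days
res <- runPipeline(ds = ds, seed = 42)
res$reportTables$repeatability[, c("trait", "V_ind0", "V_e0",
                                   "R", "R_lower", "R_upper",
                                   "delta_DIC", "DW")]
```

```
       trait   V_ind0    V_e0     R R_lower R_upper delta_DIC   DW
   awakening 2455.254 3639.17 0.310   0.065   0.800      20.8 2.06
  rest_onset   78.527   40.06 0.485   0.151   0.920      29.2 2.20
    rest_dur    0.0094   0.006 0.467   0.134   0.885      19.4 2.13
    distance    0.9480   0.022 0.962   0.902   0.994     446.6 2.21
```

Reading the output: each row is one trait; `V_ind0`/`V_e0` are the posterior
means of the between- and within-individual variance components (min²,
log-h², log-m²), `R` the adjusted repeatability with its 95% credible
interval, and `delta_DIC` the information lost by forcing V_ind0 = 0 —
values above 2 mean the trait is significantly repeatable, i.e. fish carry
individual chronotypes. `DW` near 2 means no residual temporal
autocorrelation, so the repeatability is not inflated by time-dependence.
`res$reportTables$correlations` holds the r_ind / r_e / r_P decomposition
for all six trait pairs with their ΔDIC flags.

## Package layout

S4 classes with validity checks cover the model objects (`PoissonHMM`,
`StateSequence`, `OUParams`, `PosteriorDraws`, `BivariateDraws`,
`RepeatabilityResult`, `CorrelationDecomposition`, `PopulationTruth`);
tabular data (detection series, sun tables, binned chains, trait tables)
are plain data frames with validating readers. The numerical cores (HMM
recursions, both Gibbs samplers) are C++ (Rcpp/RcppArmadillo) using R's
RNG, so `set.seed()` governs everything. See the vignette
(`vignettes/chronotype-pipeline.Rmd`) for the models, priors, numerical
choices and limitations.
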