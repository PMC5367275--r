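#' @include chronotrack-package.R
NULL

setOldClass("POSIXct")

#' Two-state Poisson hidden Markov model
#'
#' Parameters of a fitted (or constructed) hidden Markov model with Poisson
#' emissions over 5-min detection-count bins. By package convention, once a
#' model has been canonicalized with [labelStates()], state 1 is "active"
#' (larger emission rate) and state 2 is "rest".
#'
#' @slot initProb numeric(2), initial state distribution.
#' @slot transMat 2x2 row-stochastic transition matrix, rows/cols ordered
#'   (active, rest).
#' @slot rates numeric(2), Poisson detection rate per bin for each state.
#' @slot logLik log-likelihood at the returned parameters.
#' @slot nIter number of EM iterations performed.
#' @slot converged logical, EM convergence flag.
#' @slot degenerate logical, TRUE when the two states are not separated
#'   (near-equal rates; e.g. an all-zero chain).
#' @slot labelled logical, TRUE after [labelStates()] has enforced the
#'   active-first ordering.
#' @export
setClass("PoissonHMM",
  representation(initProb = "numeric", transMat = "matrix",
                 rates = "numeric", logLik = "numeric", nIter = "integer",
                 converged = "logical", degenerate = "logical",
                 labelled = "logical"),
  prototype(initProb = c(0.5, 0.5),
            transMat = matrix(0.5, 2, 2), rates = c(1, 0),
            logLik = NA_real_, nIter = 0L, converged = NA,
            degenerate = FALSE, labelled = FALSE))

setValidity("PoissonHMM", function(object) {
  msg <- character()
  if (length(object@initProb) != 2L || any(object@initProb < 0))
    msg <- c(msg, "initProb must be a length-2 non-negative vector")
  if (abs(sum(object@initProb) - 1) > 1e-8)
    msg <- c(msg, "initProb must sum to 1")
  if (!all(dim(object@transMat) == c(2L, 2L)))
    msg <- c(msg, "transMat must be 2x2")
  else if (any(abs(rowSums(object@transMat) - 1) > 1e-8))
    msg <- c(msg, "transMat rows must sum to 1")
  if (length(object@rates) != 2L || any(object@rates < 0))
    msg <- c(msg, "rates must be length-2 and non-negative")
  if (isTRUE(object@labelled) && object@rates[1] < object@rates[2])
    msg <- c(msg, "labelled model must have rates[active] >= rates[rest]")
  if (length(msg)) msg else TRUE
})

#' Decoded behavioural state sequence
#'
#' Per-bin active/rest labels for one fish, with the posterior probability of
#' the active state from the forward-backward recursions.
#'
#' @slot fishId fish identifier.
#' @slot binStart POSIXct vector of bin start times.
#' @slot binMinutes bin width in minutes.
#' @slot state character vector, "active" or "rest" per bin.
#' @slot postActive numeric vector in \[0, 1\], posterior probability of the
#'   active state per bin.
#' @export
setClass("StateSequence",
  representation(fishId = "character", binStart = "POSIXct",
                 binMinutes = "numeric", state = "character",
                 postActive = "numeric"))

setValidity("StateSequence", function(object) {
  msg <- character()
  n <- length(object@binStart)
  if (length(object@state) != n || length(object@postActive) != n)
    msg <- c(msg, "state and postActive must match binStart in length")
  if (!all(object@state %in% c("active", "rest")))
    msg <- c(msg, "state labels must be 'active' or 'rest'")
  if (any(object@postActive < -1e-12 | object@postActive > 1 + 1e-12))
    msg <- c(msg, "postActive must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ornstein-Uhlenbeck home-range movement parameters
#'
#' Mean-reverting movement model on planar (UTM-like) coordinates: each axis
#' follows dX = -beta (X - centre) dt + sigma dW, observed with i.i.d.
#' Gaussian positional noise. The stationary standard deviation
#' sigma/sqrt(2 beta) sets the home-range size scale.
#'
#' @slot centre numeric(2), home-range centre (easting, northing) in metres.
#' @slot beta attraction/exploration rate, per hour.
#' @slot sigma diffusion scale, m h^-1/2.
#' @slot obsSd positional observation noise s.d., metres.
#' @slot converged logical, optimizer convergence (NA when constructed
#'   directly rather than fitted).
#' @slot note character, fitting diagnostics (e.g. bound hits).
#' @export
setClass("OUParams",
  representation(centre = "numeric", beta = "numeric", sigma = "numeric",
                 obsSd = "numeric", converged = "logical", note = "character"),
  prototype(converged = NA, note = ""))

setValidity("OUParams", function(object) {
  msg <- character()
  if (length(object@centre) != 2L || !all(is.finite(object@centre)))
    msg <- c(msg, "centre must be a finite (easting, northing) pair")
  if (!(object@beta > 0)) msg <- c(msg, "beta must be > 0")
  if (!(object@sigma > 0)) msg <- c(msg, "sigma must be > 0")
  if (object@obsSd < 0) msg <- c(msg, "obsSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Posterior draws from the univariate random-intercept model
#'
#' MCMC output of [fitLMM()] (or [constrainedFit()], in which case the
#' between-individual variance is identically zero).
#'
#' @slot beta matrix of fixed-effect draws (draws x terms).
#' @slot u matrix of per-fish intercept draws (draws x fish).
#' @slot Vind numeric vector, between-individual variance draws.
#' @slot Ve numeric vector, residual variance draws.
#' @slot deviance numeric vector, conditional deviance per draw.
#' @slot response response (trait) name.
#' @slot transform "identity" or "log".
#' @slot terms fixed-effect term labels (design-matrix columns).
#' @slot fishIds fish identifiers, in the order of the u columns.
#' @slot mcmc list with nitt, burnin, thin, seed.
#' @slot rhat split-chain potential scale reduction per monitored quantity.
#' @slot data list carrying the model frame needed to recompute the deviance
#'   at posterior means (design matrix, response, fish index).
#' @export
setClass("PosteriorDraws",
  representation(beta = "matrix", u = "matrix", Vind = "numeric",
                 Ve = "numeric", deviance = "numeric", response = "character",
                 transform = "character", terms = "character",
                 fishIds = "character", mcmc = "list", rhat = "numeric",
                 data = "list"))

setValidity("PosteriorDraws", function(object) {
  msg <- character()
  m <- length(object@Ve)
  if (nrow(object@beta) != m || length(object@Vind) != m ||
      length(object@deviance) != m)
    msg <- c(msg, "draw components must have a common number of draws")
  if (any(object@Vind < 0)) msg <- c(msg, "Vind draws must be >= 0")
  if (any(object@Ve <= 0)) msg <- c(msg, "Ve draws must be > 0")
  if (length(msg)) msg else TRUE
})

#' Adjusted repeatability result
#'
#' Posterior summary of the adjusted repeatability
#' R = V_ind0 / (V_ind0 + V_e0) for one trait, with the DIC of the fitted
#' model, the DIC of the variance-constrained model (V_ind0 = 0) and their
#' difference; delta DIC > 2 is read as a significant R.
#'
#' @slot response trait name.
#' @slot RMean posterior mean of R.
#' @slot RCI numeric(2), 2.5% and 97.5% posterior percentiles of R.
#' @slot VindMean,VeMean posterior means of the variance components.
#' @slot DIC,DICc DIC of the fitted and the constrained model.
#' @slot deltaDIC DICc - DIC.
#' @slot significant logical, deltaDIC > 2.
#' @slot fixef data.frame of fixed-effect posterior means and BCIs.
#' @export
setClass("RepeatabilityResult",
  representation(response = "character", RMean = "numeric", RCI = "numeric",
                 VindMean = "numeric", VeMean = "numeric", DIC = "numeric",
                 DICc = "numeric", deltaDIC = "numeric",
                 significant = "logical", fixef = "data.frame"))

setValidity("RepeatabilityResult", function(object) {
  msg <- character()
  if (object@RMean < 0 || object@RMean > 1)
    msg <- c(msg, "R must lie in [0, 1]")
  if (length(object@RCI) != 2L || object@RCI[1] > object@RCI[2])
    msg <- c(msg, "RCI must be an ordered (lower, upper) pair")
  if (length(msg)) msg else TRUE
})

#' Posterior draws from a bivariate random-intercept model
#'
#' MCMC output of [fitBivariate()]: fixed effects for both responses and the
#' 2x2 between-individual and residual covariance matrices (stored per draw
#' as var1, var2, cov).
#'
#' @slot traits character(2), the trait pair.
#' @slot B matrix of fixed-effect draws (draws x 2p; trait-1 coefficients
#'   then trait-2 coefficients).
#' @slot U1,U2 per-fish intercept draws for each trait.
#' @slot SigmaInd,SigmaE matrices (draws x 3): var1, var2, cov.
#' @slot deviance conditional deviance per draw.
#' @slot terms design-matrix column labels.
#' @slot fishIds fish identifiers.
#' @slot mcmc list with nitt, burnin, thin, seed.
#' @slot constrained "none", "ind" or "e" (which covariance was forced
#'   diagonal).
#' @slot data list carrying the model frame for DIC recomputation.
#' @export
setClass("BivariateDraws",
  representation(traits = "character", B = "matrix", U1 = "matrix",
                 U2 = "matrix", SigmaInd = "matrix", SigmaE = "matrix",
                 deviance = "numeric", terms = "character",
                 fishIds = "character", mcmc = "list",
                 constrained = "character", data = "list"))

setValidity("BivariateDraws", function(object) {
  msg <- character()
  for (nm in c("SigmaInd", "SigmaE")) {
    S <- slot(object, nm)
    if (ncol(S) != 3L) { msg <- c(msg, paste(nm, "must have 3 columns")); next }
    det2 <- S[, 1] * S[, 2] - S[, 3]^2
    if (any(S[, 1] <= 0 | S[, 2] <= 0 | det2 <= 0))
      msg <- c(msg, paste(nm, "draws must be positive definite"))
  }
  if (length(object@traits) != 2L) msg <- c(msg, "traits must name a pair")
  if (length(msg)) msg else TRUE
})

#' Correlation decomposition for a trait pair
#'
#' Posterior summaries of the between-individual (r_ind), residual (r_e) and
#' phenotypic (r_P) correlations for one trait pair, with the delta-DIC
#' significance of each covariance against its diagonal-constrained model.
#'
#' @slot traits character(2).
#' @slot rInd,rE,rP numeric(3): posterior mean, 2.5% and 97.5% percentiles.
#' @slot deltaDICInd,deltaDICE DIC(constrained) - DIC(unconstrained).
#' @slot sigInd,sigE logical flags (delta DIC > 2).
#' @export
setClass("CorrelationDecomposition",
  representation(traits = "character", rInd = "numeric", rE = "numeric",
                 rP = "numeric", deltaDICInd = "numeric",
                 deltaDICE = "numeric", sigInd = "logical", sigE = "logical"))

setValidity("CorrelationDecomposition", function(object) {
  msg <- character()
  for (nm in c("rInd", "rE", "rP")) {
    v <- slot(object, nm)
    if (length(v) != 3L || any(v < -1 - 1e-9 | v > 1 + 1e-9))
      msg <- c(msg, paste(nm, "must be (mean, lower, upper) within [-1, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth parameters of the synthetic telemetry study
#'
#' Population-level parameters from which [generateDataset()] simulates a
#' study: per-trait population means, between- (V_ind) and within-individual
#' (V_e) variances, fixed-effect coefficients, between/within-individual
#' correlation structure, Poisson detection rates for the active and resting
#' states, and the movement-model parameter ranges.
#'
#' @slot traits data.frame with one row per trait (awakening, rest_onset,
#'   rest_dur, distance) and columns mean, Vind, Ve, betaLat, betaLon,
#'   betaYear, transform, unit.
#' @slot rhoInd,rhoE 4x4 between- and within-individual correlation matrices
#'   (unit diagonal, positive semi-definite), trait order as in `traits`.
#' @slot lambdaActive,lambdaRest Poisson detection rates per 5-min bin.
#' @slot ou list of movement-model settings (beta, stationarySd, obsSd,
#'   betaCV, dailySdLog).
#' @slot nFish,nDays study dimensions.
#' @slot config list of remaining study settings (coordinate rectangle,
#'   base sunrise/sunset, year split, bin width, distance mode).
#' @export
setClass("PopulationTruth",
  representation(traits = "data.frame", rhoInd = "matrix", rhoE = "matrix",
                 lambdaActive = "numeric", lambdaRest = "numeric",
                 ou = "list", nFish = "integer", nDays = "integer",
                 config = "list"))

setValidity("PopulationTruth", function(object) {
  msg <- character()
  tr <- object@traits
  need <- c("mean", "Vind", "Ve", "betaLat", "betaLon", "betaYear")
  if (!all(need %in% names(tr)))
    msg <- c(msg, paste("traits must have columns", paste(need, collapse = ", ")))
  else {
    if (any(tr$Vind < 0)) msg <- c(msg, "Vind must be >= 0")
    if (any(tr$Ve <= 0)) msg <- c(msg, "Ve must be > 0")
  }
  for (nm in c("rhoInd", "rhoE")) {
    R <- slot(object, nm)
    if (!all(dim(R) == c(4L, 4L)) || any(abs(diag(R) - 1) > 1e-8) ||
        any(abs(R - t(R)) > 1e-8))
      msg <- c(msg, paste(nm, "must be symmetric 4x4 with unit diagonal"))
    else if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      msg <- c(msg, paste(nm, "must be positive semi-definite"))
  }
  if (!(object@lambdaActive > object@lambdaRest) || object@lambdaRest < 0)
    msg <- c(msg, "need lambdaActive > lambdaRest >= 0")
  if (object@nFish < 1L || object@nDays < 1L)
    msg <- c(msg, "nFish and nDays must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A complete synthetic telemetry dataset with ground truth
#'
#' @slot detections data.frame (fish_id, timestamp) of simulated detections.
#' @slot sunTable data.frame (date, sunrise, sunset).
#' @slot metadata data.frame of per-fish covariates.
#' @slot positions data.frame of noisy 15-min position observations
#'   (fish_id, timestamp, x_m, y_m); empty in "gaussian" distance mode.
#' @slot trueStates data.frame (fish_id, bin_start, state) of latent
#'   active/rest labels per 5-min bin.
#' @slot trueTraits data.frame of true daily trait values (continuous and
#'   bin-snapped awakening/onset).
#' @slot truth the [PopulationTruth-class] used.
#' @export
setClass("SyntheticDataset",
  representation(detections = "data.frame", sunTable = "data.frame",
                 metadata = "data.frame", positions = "data.frame",
                 trueStates = "data.frame", trueTraits = "data.frame",
                 truth = "PopulationTruth"))
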