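#' @include repeatability.R
NULL

#' Default transform for a trait column
#'
#' Rest duration and daily travelled distance are log-transformed to reach
#' residual normality; the sun-relative timing traits (signed minutes) are
#' not.
#'
#' @param response trait column name.
#' @return "log" or "identity".
#' @export
defaultTransform <- function(response) {
  if (response %in% c("rest_dur_h", "dist_m")) "log" else "identity"
}

.biv_frame <- function(pair, transforms, traits, metadata) {
  .assert_cols(traits, c("fish_id", "date", pair), "trait table")
  df <- merge(traits, metadata, by = "fish_id")
  Y <- cbind(df[[pair[1]]], df[[pair[2]]])
  keep <- complete.cases(Y)
  for (j in 1:2) if (transforms[j] == "log") keep <- keep & Y[, j] > 0
  df <- df[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  for (j in 1:2) if (transforms[j] == "log") Y[, j] <- log(Y[, j])
  ord <- order(df$fish_id, df$date)
  df <- df[ord, , drop = FALSE]
  Y <- Y[ord, , drop = FALSE]
  frame <- data.frame(
    fish_id = df$fish_id, date = df$date,
    lat = (df$centre_northing - mean(df$centre_northing)) / 1000,
    lon = (df$centre_easting - mean(df$centre_easting)) / 1000,
    sex = factor(df$sex), year = factor(df$year),
    stringsAsFactors = FALSE)
  list(frame = frame, Y = Y)
}

#' Fit a bivariate random-intercept model for a trait pair
#'
#' Gibbs sampler for the paired mixed model that decomposes the covariance
#' of two traits into a 2x2 between-individual matrix (Sigma_ind, over fish
#' random intercepts) and a 2x2 residual matrix (Sigma_e), both with the
#' weak inverse-Wishart prior (V = identity of size 2, nu = 1.002). Rows are
#' pairwise-complete fish-days; transforms are applied per
#' [defaultTransform()] unless overridden.
#'
#' @param pair character(2) of trait column names.
#' @param traits daily trait table.
#' @param metadata fish metadata.
#' @param covariates fixed-effect terms (typically those retained by
#'   [stepwiseReduce()] for either trait); applied to both responses.
#' @param mcmc list overriding nitt (130000), burnin (30000), thin (100);
#'   the long-run setting used for final reported fits is
#'   1300000/300000/1000.
#' @param prior list overriding nu (1.002), V (identity 2x2), betaV (1e10).
#' @param transforms character(2) overriding the default transforms.
#' @param constrain "none" (default), "ind" or "e": force the corresponding
#'   covariance matrix diagonal (off-diagonal = 0).
#' @param seed RNG seed.
#' @return a [BivariateDraws-class].
#' @export
fitBivariate <- function(pair, traits, metadata, covariates = character(),
                         mcmc = list(), prior = list(),
                         transforms = vapply(pair, defaultTransform, ""),
                         constrain = c("none", "ind", "e"), seed = 1) {
  constrain <- match.arg(constrain)
  stopifnot(length(pair) == 2L)
  mcmc <- utils::modifyList(list(nitt = 130000L, burnin = 30000L,
                                 thin = 100L), mcmc)
  prior <- utils::modifyList(list(nu = 1.002, V = diag(2), betaV = 1e10),
                             prior)
  bf <- .biv_frame(pair, transforms, traits, metadata)
  fishIds <- sort(unique(bf$frame$fish_id))
  if (length(fishIds) < 3L) stop("need at least 3 fish")
  spec <- lmmSpec(pair[1], covariates)
  X <- .lmm_design(spec, bf$frame)
  fidx <- match(bf$frame$fish_id, fishIds) - 1L
  set.seed(seed)
  res <- .gibbs_bivariate(bf$Y, X, fidx, length(fishIds), mcmc$nitt,
                          mcmc$burnin, mcmc$thin, prior$nu, prior$V,
                          prior$nu, prior$V, prior$betaV,
                          constrain == "ind", constrain == "e")
  new("BivariateDraws", traits = pair, B = res$B, U1 = res$U1, U2 = res$U2,
      SigmaInd = res$SigmaInd, SigmaE = res$SigmaE,
      deviance = as.numeric(res$deviance),
      terms = colnames(X), fishIds = fishIds,
      mcmc = c(mcmc, list(seed = seed)), constrained = constrain,
      data = list(X = X, Y = bf$Y, fish = fidx))
}

#' DIC of a bivariate fit
#'
#' Conditional-deviance DIC, as in [dicLMM()] but with the bivariate normal
#' residual likelihood.
#'
#' @param draws a [BivariateDraws-class].
#' @return the DIC with attributes `pD` and `se`.
#' @export
dicBivariate <- function(draws) {
  stopifnot(is(draws, "BivariateDraws"))
  Dbar <- mean(draws@deviance)
  X <- draws@data$X
  p <- ncol(X)
  Bhat <- cbind(colMeans(draws@B)[1:p], colMeans(draws@B)[(p + 1):(2 * p)])
  U <- cbind(colMeans(draws@U1), colMeans(draws@U2))
  Se <- matrix(c(mean(draws@SigmaE[, 1]), mean(draws@SigmaE[, 3]),
                 mean(draws@SigmaE[, 3]), mean(draws@SigmaE[, 2])), 2, 2)
  E <- draws@data$Y - X %*% Bhat - U[draws@data$fish + 1L, , drop = FALSE]
  W <- solve(Se)
  q <- rowSums((E %*% W) * E)
  Dhat <- -2 * sum(-0.5 * (2 * log(2 * pi) + determinant(Se)$modulus + q))
  out <- 2 * Dbar - as.numeric(Dhat)
  attr(out, "pD") <- Dbar - as.numeric(Dhat)
  attr(out, "se") <- sd(draws@deviance) / sqrt(length(draws@deviance))
  out
}

.corr_draws <- function(draws) {
  Si <- draws@SigmaInd; Se <- draws@SigmaE
  rInd <- Si[, 3] / sqrt(Si[, 1] * Si[, 2])
  rE <- Se[, 3] / sqrt(Se[, 1] * Se[, 2])
  rP <- (Si[, 3] + Se[, 3]) / sqrt((Si[, 1] + Se[, 1]) * (Si[, 2] + Se[, 2]))
  list(rInd = rInd, rE = rE, rP = rP)
}

#' Correlation decomposition of a bivariate fit
#'
#' Per draw: `r_ind = Sigma_ind[1,2] / sqrt(Sigma_ind[1,1] Sigma_ind[2,2])`,
#' `r_e` analogously, and the model-implied phenotypic correlation `r_P`
#' from the summed covariance matrix `Sigma_ind + Sigma_e`. When the two
#' constrained fits are supplied the delta-DIC significance flags are
#' filled in.
#'
#' @param draws unconstrained [BivariateDraws-class].
#' @param constrainedInd,constrainedE optional fits with the respective
#'   covariance forced diagonal (see [fitBivariate()]).
#' @return a [CorrelationDecomposition-class].
#' @export
correlationDecomposition <- function(draws, constrainedInd = NULL,
                                     constrainedE = NULL) {
  stopifnot(is(draws, "BivariateDraws"))
  cd <- .corr_draws(draws)
  summ <- function(x) c(mean(x), unname(quantile(x, c(0.025, 0.975))))
  dInd <- dE <- NA_real_
  sigInd <- sigE <- NA
  if (!is.null(constrainedInd)) {
    dInd <- as.numeric(dicBivariate(constrainedInd)) -
      as.numeric(dicBivariate(draws))
    sigInd <- dInd > 2
  }
  if (!is.null(constrainedE)) {
    dE <- as.numeric(dicBivariate(constrainedE)) -
      as.numeric(dicBivariate(draws))
    sigE <- dE > 2
  }
  new("CorrelationDecomposition", traits = draws@traits,
      rInd = summ(cd$rInd), rE = summ(cd$rE), rP = summ(cd$rP),
      deltaDICInd = dInd, deltaDICE = dE, sigInd = sigInd, sigE = sigE)
}

#' Delta-DIC significance of a trait pair's correlations
#'
#' Fits the unconstrained bivariate model and, separately, the two
#' covariance-constrained models (between-individual off-diagonal forced to
#' zero; residual off-diagonal forced to zero), and reports
#' `delta DIC = DIC(constrained) - DIC(unconstrained)` for each, flagged
#' significant when > 2.
#'
#' @inheritParams fitBivariate
#' @return a [CorrelationDecomposition-class] with significance flags.
#' @export
significanceDIC <- function(pair, traits, metadata, covariates = character(),
                            mcmc = list(), prior = list(), seed = 1) {
  fit <- fitBivariate(pair, traits, metadata, covariates, mcmc, prior,
                      constrain = "none", seed = seed)
  fitI <- fitBivariate(pair, traits, metadata, covariates, mcmc, prior,
                       constrain = "ind", seed = deriveSeed(seed, "cons-ind"))
  fitE <- fitBivariate(pair, traits, metadata, covariates, mcmc, prior,
                       constrain = "e", seed = deriveSeed(seed, "cons-e"))
  correlationDecomposition(fit, fitI, fitE)
}
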