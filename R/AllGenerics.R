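#' @include AllClasses.R
NULL

#' Accessors for chronotrack model objects
#'
#' @param object a chronotrack S4 object.
#' @return `transitionMatrix` the 2x2 transition matrix; `emissionRates` the
#'   per-state Poisson rates; `stationarySd` the Ornstein-Uhlenbeck
#'   stationary standard deviation sigma/sqrt(2 beta) in metres;
#'   `repeatability` the (mean, lower, upper) posterior summary of R.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

#' @rdname accessors
#' @export
setGeneric("emissionRates", function(object) standardGeneric("emissionRates"))

#' @rdname accessors
#' @export
setGeneric("stationarySd", function(object) standardGeneric("stationarySd"))

#' @rdname accessors
#' @export
setGeneric("repeatability", function(object) standardGeneric("repeatability"))

#' @rdname accessors
#' @export
setMethod("transitionMatrix", "PoissonHMM", function(object) {
  m <- object@transMat
  dimnames(m) <- list(c("active", "rest"), c("active", "rest"))
  m
})

#' @rdname accessors
#' @export
setMethod("emissionRates", "PoissonHMM", function(object)
  setNames(object@rates, c("active", "rest")))

#' @rdname accessors
#' @export
setMethod("stationarySd", "OUParams", function(object)
  object@sigma / sqrt(2 * object@beta))

#' @rdname accessors
#' @export
setMethod("repeatability", "RepeatabilityResult", function(object)
  c(mean = object@RMean, lower = object@RCI[1], upper = object@RCI[2]))

setMethod("show", "PoissonHMM", function(object) {
  cat("PoissonHMM (2 states",
      if (object@labelled) ", labelled active/rest" else "", ")\n", sep = "")
  cat("  rates: ", paste(signif(object@rates, 4), collapse = ", "),
      " per bin\n", sep = "")
  cat("  self-transition: ", paste(signif(diag(object@transMat), 4),
      collapse = ", "), "\n", sep = "")
  cat("  logLik: ", signif(object@logLik, 6), " (", object@nIter,
      " EM iterations, ", if (isTRUE(object@converged)) "converged"
      else "not converged", ")\n", sep = "")
  if (object@degenerate) cat("  flag: states not separated\n")
})

setMethod("show", "StateSequence", function(object) {
  cat("StateSequence for fish ", object@fishId, ": ",
      length(object@state), " bins of ", object@binMinutes, " min, ",
      sum(object@state == "active"), " active\n", sep = "")
})

setMethod("show", "OUParams", function(object) {
  cat("OUParams: centre (", paste(round(object@centre, 1), collapse = ", "),
      ") m, beta ", signif(object@beta, 4), " h^-1, sigma ",
      signif(object@sigma, 4), " m h^-1/2, obs sd ",
      signif(object@obsSd, 4), " m\n  stationary sd ",
      signif(stationarySd(object), 4), " m\n", sep = "")
  if (nzchar(object@note)) cat("  note: ", object@note, "\n", sep = "")
})

setMethod("show", "PosteriorDraws", function(object) {
  cat("PosteriorDraws for ", object@response,
      if (object@transform == "log") " (log scale)", ": ",
      length(object@Ve), " draws\n", sep = "")
  cat("  terms: ", paste(object@terms, collapse = ", "), "\n", sep = "")
  cat("  V_ind0 ", signif(mean(object@Vind), 4), ", V_e0 ",
      signif(mean(object@Ve), 4), " (posterior means)\n", sep = "")
})

setMethod("show", "RepeatabilityResult", function(object) {
  cat("Adjusted repeatability for ", object@response, ": ",
      sprintf("%.2f [%.2f, %.2f]", object@RMean, object@RCI[1],
              object@RCI[2]), "\n", sep = "")
  cat("  DIC ", round(object@DIC, 2), ", DICc ", round(object@DICc, 2),
      ", delta ", round(object@deltaDIC, 2),
      if (object@significant) " (significant)" else "", "\n", sep = "")
})

setMethod("show", "BivariateDraws", function(object) {
  cat("BivariateDraws for (", paste(object@traits, collapse = ", "), "): ",
      length(object@deviance), " draws",
      if (object@constrained != "none")
        paste0(" [", object@constrained, "-covariance constrained]"),
      "\n", sep = "")
})

setMethod("show", "CorrelationDecomposition", function(object) {
  fmt <- function(v) sprintf("%.2f [%.2f, %.2f]", v[1], v[2], v[3])
  cat("Correlation decomposition (", paste(object@traits, collapse = ", "),
      ")\n", sep = "")
  cat("  r_ind ", fmt(object@rInd),
      if (object@sigInd) " *" else "", "\n", sep = "")
  cat("  r_e   ", fmt(object@rE),
      if (object@sigE) " *" else "", "\n", sep = "")
  cat("  r_P   ", fmt(object@rP), "\n", sep = "")
})

setMethod("show", "PopulationTruth", function(object) {
  cat("PopulationTruth: ", object@nFish, " fish x ", object@nDays,
      " days, lambda (active, rest) = (", object@lambdaActive, ", ",
      object@lambdaRest, ") per bin\n", sep = "")
  print(round(object@traits[, c("mean", "Vind", "Ve")], 3))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset: ", nrow(object@metadata), " fish, ",
      nrow(object@detections), " detections, ",
      nrow(object@trueTraits), " true fish-days\n", sep = "")
})
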