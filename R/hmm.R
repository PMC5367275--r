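#' @include AllClasses.R utils.R
NULL

#' Construct a two-state Poisson HMM
#'
#' Builds a [PoissonHMM-class] object from explicit parameters. State order
#' is positional: index 1 is reported as "active", index 2 as "rest";
#' [labelStates()] canonicalizes a fitted model so the larger emission rate
#' sits in position 1.
#'
#' @param initProb initial state distribution (length 2, sums to 1).
#' @param transMat 2x2 row-stochastic transition matrix.
#' @param rates per-state Poisson rates per bin.
#' @param logLik,nIter,converged optional fit metadata.
#' @return a `PoissonHMM` object.
#' @export
makePoissonHMM <- function(initProb = c(0.5, 0.5),
                           transMat = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                                             byrow = TRUE),
                           rates = c(4, 0.2), logLik = NA_real_, nIter = 0L,
                           converged = NA) {
  new("PoissonHMM", initProb = as.numeric(initProb),
      transMat = matrix(as.numeric(transMat), 2, 2),
      rates = as.numeric(rates), logLik = as.numeric(logLik),
      nIter = as.integer(nIter), converged = converged,
      degenerate = FALSE, labelled = FALSE)
}

.chain_counts <- function(chain) {
  if (is.data.frame(chain)) {
    .assert_cols(chain, "count", "binned chain")
    as.integer(chain$count)
  } else as.integer(chain)
}

#' Forward-backward recursions for a Poisson HMM
#'
#' Runs the scaled forward-backward algorithm on a binned detection chain,
#' returning the exact log-likelihood and the per-bin posterior state
#' probabilities. Scaling makes underflow impossible at any chain length.
#'
#' @param chain a binned chain from [binDetections()] or an integer count
#'   vector.
#' @param model a [PoissonHMM-class].
#' @return list with `logLik` and `posterior` (bins x 2 matrix, columns
#'   `active`, `rest` in the model's state order).
#' @export
forwardBackward <- function(chain, model) {
  stopifnot(is(model, "PoissonHMM"))
  counts <- .chain_counts(chain)
  fb <- .hmm_forward_backward(counts, model@initProb, model@transMat,
                              model@rates)
  if (!is.finite(fb$loglik))
    stop("chain has zero probability under the model ",
         "(a state with rate 0 faced a positive count)")
  post <- fb$gamma
  colnames(post) <- c("active", "rest")
  list(logLik = fb$loglik, posterior = post, xi = fb$xi)
}

# Starting values for one EM restart. The first restart uses a two-group
# split of the observed counts (k-means style, one-dimensional); later
# restarts perturb randomly to escape local maxima.
.hmm_init <- function(counts, restart) {
  if (restart == 1L) {
    m <- mean(counts)
    hi <- counts[counts > m]
    lo <- counts[counts <= m]
    lam <- c(if (length(hi)) mean(hi) else m + 1, if (length(lo)) mean(lo) else m / 2)
  } else {
    mx <- max(counts, 1L)
    lam <- sort(runif(2, 0, mx + 1), decreasing = TRUE)
  }
  lam <- pmax(lam, 1e-3)
  if (abs(lam[1] - lam[2]) < 1e-3) lam <- lam + c(0.5, 0)
  selfp <- if (restart == 1L) 0.9 else runif(1, 0.7, 0.98)
  list(init = c(0.5, 0.5),
       trans = matrix(c(selfp, 1 - selfp, 1 - selfp, selfp), 2, 2,
                      byrow = TRUE),
       rates = lam)
}

#' Fit a two-state Poisson HMM by expectation-maximization
#'
#' Baum-Welch fit of one HMM to one fish's whole multi-day binned chain.
#' Several seeded restarts are run and the best log-likelihood kept; the EM
#' log-likelihood trace is checked to be non-decreasing at every step. The
#' returned model is canonicalized with [labelStates()] unless the two
#' states are not separated (near-equal rates, e.g. an all-zero chain), in
#' which case it is flagged degenerate.
#'
#' @param chain binned chain (>= 10 bins) or integer count vector.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param maxIter maximum EM iterations per restart (default 500).
#' @param restarts number of EM restarts (default 5).
#' @param seed optional RNG seed for the restart initializations.
#' @return a fitted [PoissonHMM-class]; attribute `trace` holds the winning
#'   restart's log-likelihood trace.
#' @export
fitHMM <- function(chain, tol = 1e-8, maxIter = 500L, restarts = 5L,
                   seed = NULL) {
  counts <- .chain_counts(chain)
  if (length(counts) < 10L) stop("chain must have at least 10 bins")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    ini <- .hmm_init(counts, r)
    fit <- .hmm_em(counts, ini$init, ini$trans, ini$rates, tol,
                   as.integer(maxIter))
    if (!is.finite(fit$loglik)) next
    if (any(diff(fit$trace) < -1e-6 * (abs(fit$trace[-length(fit$trace)]) + 1)))
      stop("EM log-likelihood decreased; numerical failure")
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("all EM restarts failed")
  model <- new("PoissonHMM", initProb = pmax(best$init, 0) / sum(pmax(best$init, 0)),
               transMat = best$trans, rates = best$rates,
               logLik = best$loglik, nIter = as.integer(best$n_iter),
               converged = isTRUE(best$converged), degenerate = FALSE,
               labelled = FALSE)
  if (abs(model@rates[1] - model@rates[2]) <
      1e-6 * (mean(model@rates) + 1e-6)) {
    model@degenerate <- TRUE
  } else {
    model <- labelStates(model)
  }
  attr(model, "trace") <- best$trace
  model
}

#' Canonicalize HMM state labels
#'
#' Relabels the state with the larger Poisson rate as "active" (position 1),
#' permuting the initial distribution and transition matrix consistently.
#' Idempotent; errors when the rates are equal (states indistinguishable).
#'
#' @param model a [PoissonHMM-class].
#' @return the relabelled model with `labelled = TRUE`.
#' @export
labelStates <- function(model) {
  stopifnot(is(model, "PoissonHMM"))
  if (model@rates[1] == model@rates[2])
    stop("states indistinguishable: equal emission rates")
  perm <- order(model@rates, decreasing = TRUE)
  model@rates <- model@rates[perm]
  model@initProb <- model@initProb[perm]
  model@transMat <- model@transMat[perm, perm]
  model@labelled <- TRUE
  validObject(model)
  model
}

#' Decode the behavioural state sequence
#'
#' Decodes the active/rest path for a binned chain under a fitted model.
#' The default is global decoding (Viterbi most-probable path) with ties
#' broken toward the rest state — conservative for awakening detection; the
#' alternative is local (posterior-mode) decoding for sensitivity checks.
#' Both attach the forward-backward posterior probability of activity.
#'
#' @param chain binned chain from [binDetections()].
#' @param model fitted [PoissonHMM-class] (labelled, or a symmetric model
#'   for the degenerate equal-rate case).
#' @param method "viterbi" (default) or "posterior".
#' @return a [StateSequence-class].
#' @export
decodeStates <- function(chain, model, method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(chain))
  .assert_cols(chain, c("fish_id", "bin_start", "count"), "binned chain")
  counts <- .chain_counts(chain)
  fb <- forwardBackward(counts, model)
  if (method == "viterbi") {
    path <- .hmm_viterbi(counts, model@initProb, model@transMat, model@rates)
  } else {
    path <- ifelse(fb$posterior[, 1] > 0.5, 1L, 2L)  # ties go to rest
  }
  new("StateSequence", fishId = chain$fish_id[1],
      binStart = chain$bin_start,
      binMinutes = attr(chain, "binMinutes") %||% 5,
      state = c("active", "rest")[path],
      postActive = pmin(pmax(fb$posterior[, 1], 0), 1))
}

#' Serialize an HMM to JSON
#'
#' @param model a [PoissonHMM-class].
#' @param path optional file path; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
hmmToJSON <- function(model, path = NULL) {
  x <- list(init = model@initProb, trans = model@transMat,
            rates = model@rates, logLik = model@logLik,
            converged = model@converged, degenerate = model@degenerate)
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
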