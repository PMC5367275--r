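#' @include utils.R AllClasses.R
NULL

.all_lmm_terms <- function() {
  mains <- c("sex", "lat", "lon", "year")
  inter <- combn(mains, 2, paste, collapse = ":")
  c(mains, inter)
}

#' Specify a univariate mixed model for one trait
#'
#' Describes the model fitted per trait: the response (optionally
#' log-transformed), fixed-effect terms drawn from sex, home-range-centre
#' latitude/longitude (`lat`, `lon`; mean-centred, in km) and year plus
#' their two-way interactions, and the fish random intercept (always
#' present). Interactions require both main effects (hierarchy).
#'
#' @param response trait column name in the trait table (e.g.
#'   "awakening_min", "dist_m").
#' @param fixed character vector of fixed terms; default all mains plus all
#'   two-way interactions.
#' @param transform "identity" or "log".
#' @return an object of class `LMMSpec` (a validated list).
#' @export
lmmSpec <- function(response, fixed = .all_lmm_terms(),
                    transform = c("identity", "log")) {
  transform <- match.arg(transform)
  known <- .all_lmm_terms()
  bad <- setdiff(fixed, known)
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  for (tm in grep(":", fixed, value = TRUE)) {
    mains <- strsplit(tm, ":")[[1]]
    if (!all(mains %in% fixed))
      stop("interaction ", tm, " requires both main effects")
  }
  structure(list(response = response, fixed = fixed, transform = transform),
            class = "LMMSpec")
}

# Assemble the per-row model frame: merge daily traits with per-fish
# covariates, apply the transform, drop invalid rows, mean-centre the
# continuous coordinates (in km), and order by fish and date.
.lmm_frame <- function(spec, traits, metadata) {
  .assert_cols(traits, c("fish_id", "date", spec$response), "trait table")
  .assert_cols(metadata, c("fish_id", "sex", "year", "centre_easting",
                           "centre_northing"), "metadata")
  df <- merge(traits, metadata, by = "fish_id")
  y <- df[[spec$response]]
  keep <- !is.na(y)
  if (spec$transform == "log") {
    keep <- keep & y > 0
    y <- log(y)
  }
  df <- df[keep, , drop = FALSE]
  y <- y[keep]
  ord <- order(df$fish_id, df$date)
  df <- df[ord, , drop = FALSE]
  y <- y[ord]
  frame <- data.frame(
    y = y, fish_id = df$fish_id, date = df$date,
    lat = (df$centre_northing - mean(df$centre_northing)) / 1000,
    lon = (df$centre_easting - mean(df$centre_easting)) / 1000,
    sex = factor(df$sex), year = factor(df$year),
    stringsAsFactors = FALSE)
  frame
}

.lmm_design <- function(spec, frame) {
  terms <- spec$fixed
  # factors with a single level carry no information; drop them (and their
  # interactions) rather than produce an unusable design
  for (fct in c("sex", "year")) {
    if (fct %in% names(frame) && nlevels(droplevels(frame[[fct]])) < 2L)
      terms <- terms[!grepl(fct, terms)]
  }
  fml <- if (length(terms))
    stats::as.formula(paste("~", paste(terms, collapse = " + "))) else
    stats::as.formula("~ 1")
  X <- stats::model.matrix(fml, frame)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  X
}

.default_mcmc <- function(mcmc = list()) {
  utils::modifyList(list(nitt = 13000L, burnin = 3000L, thin = 10L), mcmc)
}

.default_prior <- function(prior = list()) {
  # the cited engine's default settings: variances ~ IG(nu/2, nu V/2) with
  # nu = 0.002, V = 1; fixed effects ~ N(0, 1e10). nuScale doubles/halves nu
  # for prior-sensitivity checks.
  p <- utils::modifyList(list(nu = 0.002, V = 1, betaV = 1e10, nuScale = 1),
                         prior)
  p$nu <- p$nu * p$nuScale
  p
}

#' Fit the univariate random-intercept model by Gibbs sampling
#'
#' Bayesian linear mixed model for one trait: the requested fixed effects, a
#' fish-level random intercept, conjugate normal/inverse-gamma updates
#' (fixed effects N(0, 1e10); variances IG(nu/2, nu V/2) with the weak
#' default nu = 0.002, V = 1). Draws are retained after burn-in, thinned,
#' and split-chain potential-scale-reduction diagnostics reported.
#'
#' @param spec an [lmmSpec()].
#' @param traits daily trait table ([buildTraitTable()] layout).
#' @param metadata fish metadata ([readFishMeta()] layout).
#' @param mcmc list overriding nitt (13000), burnin (3000), thin (10).
#' @param prior list overriding nu (0.002), V (1), betaV (1e10), nuScale (1).
#' @param seed RNG seed.
#' @return a [PosteriorDraws-class].
#' @export
fitLMM <- function(spec, traits, metadata, mcmc = list(), prior = list(),
                   seed = 1) {
  stopifnot(inherits(spec, "LMMSpec"))
  mcmc <- .default_mcmc(mcmc)
  prior <- .default_prior(prior)
  frame <- .lmm_frame(spec, traits, metadata)
  tab <- table(frame$fish_id)
  if (length(tab) < 2L || all(tab < 2L))
    stop("need >= 2 fish with >= 2 days each")
  X <- .lmm_design(spec, frame)
  fishIds <- sort(unique(frame$fish_id))
  fidx <- match(frame$fish_id, fishIds) - 1L
  set.seed(seed)
  res <- .gibbs_lmm(frame$y, X, fidx, length(fishIds), mcmc$nitt,
                    mcmc$burnin, mcmc$thin, prior$nu, prior$V, prior$nu,
                    prior$V, prior$betaV, TRUE)
  colnames(res$beta) <- colnames(X)
  rhat <- c(Vind = splitRhat(res$Vind), Ve = splitRhat(res$Ve),
            setNames(apply(res$beta, 2, splitRhat),
                     paste0("beta.", colnames(X))))
  new("PosteriorDraws", beta = res$beta, u = res$u,
      Vind = pmax(as.numeric(res$Vind), 0), Ve = as.numeric(res$Ve),
      deviance = as.numeric(res$deviance), response = spec$response,
      transform = spec$transform, terms = colnames(X), fishIds = fishIds,
      mcmc = c(mcmc, list(seed = seed)), rhat = rhat,
      data = list(X = X, y = frame$y, fish = fidx, dates = frame$date,
                  fish_id = frame$fish_id))
}

#' Fit the variance-constrained (fixed-effects-only) model
#'
#' The same model as [fitLMM()] with the between-individual variance
#' constrained to zero (no random intercepts); its DIC is the reference for
#' the delta-DIC significance test of the adjusted repeatability.
#'
#' @inheritParams fitLMM
#' @return a [PosteriorDraws-class] with `Vind` identically zero.
#' @export
constrainedFit <- function(spec, traits, metadata, mcmc = list(),
                           prior = list(), seed = 1) {
  stopifnot(inherits(spec, "LMMSpec"))
  mcmc <- .default_mcmc(mcmc)
  prior <- .default_prior(prior)
  frame <- .lmm_frame(spec, traits, metadata)
  X <- .lmm_design(spec, frame)
  fishIds <- sort(unique(frame$fish_id))
  fidx <- match(frame$fish_id, fishIds) - 1L
  set.seed(seed)
  res <- .gibbs_lmm(frame$y, X, fidx, length(fishIds), mcmc$nitt,
                    mcmc$burnin, mcmc$thin, prior$nu, prior$V, prior$nu,
                    prior$V, prior$betaV, FALSE)
  colnames(res$beta) <- colnames(X)
  new("PosteriorDraws", beta = res$beta, u = res$u,
      Vind = rep(0, length(res$Ve)), Ve = as.numeric(res$Ve),
      deviance = as.numeric(res$deviance), response = spec$response,
      transform = spec$transform, terms = colnames(X), fishIds = fishIds,
      mcmc = c(mcmc, list(seed = seed)),
      rhat = c(Ve = splitRhat(res$Ve)),
      data = list(X = X, y = frame$y, fish = fidx, dates = frame$date,
                  fish_id = frame$fish_id))
}

#' Deviance information criterion of a fitted model
#'
#' Conditional-deviance DIC: `Dbar` is the posterior mean of
#' `-2 log L(y | beta, u, V_e)` over the retained draws and
#' `DIC = 2 Dbar - D(posterior means)`. This is the conditional (given the
#' random effects) variant — DIC definitions differ across software, and
#' delta-DIC comparisons in this package always use this one.
#'
#' @param draws a [PosteriorDraws-class].
#' @return the DIC, with attributes `pD` (effective parameters) and `se`
#'   (Monte-Carlo standard error of Dbar).
#' @export
dicLMM <- function(draws) {
  stopifnot(is(draws, "PosteriorDraws"))
  Dbar <- mean(draws@deviance)
  X <- draws@data$X
  mu <- as.numeric(X %*% colMeans(draws@beta))
  if (any(draws@Vind > 0)) mu <- mu + colMeans(draws@u)[draws@data$fish + 1L]
  Dhat <- -2 * sum(dnorm(draws@data$y, mu, sqrt(mean(draws@Ve)), log = TRUE))
  out <- 2 * Dbar - Dhat
  attr(out, "pD") <- Dbar - Dhat
  attr(out, "se") <- sd(draws@deviance) / sqrt(length(draws@deviance))
  out
}

#' Adjusted repeatability from posterior draws
#'
#' Computes the per-draw adjusted repeatability
#' `R = V_ind0 / (V_ind0 + V_e0)` and summarizes its posterior (mean and
#' 2.5/97.5 percentiles). When the constrained fit is supplied the DIC of
#' both models and the delta-DIC significance flag (> 2) are filled in.
#'
#' @param draws [PosteriorDraws-class] from [fitLMM()].
#' @param constrained optional [PosteriorDraws-class] from
#'   [constrainedFit()].
#' @return a [RepeatabilityResult-class].
#' @export
adjustedR <- function(draws, constrained = NULL) {
  stopifnot(is(draws, "PosteriorDraws"))
  R <- draws@Vind / (draws@Vind + draws@Ve)
  fixef <- data.frame(term = colnames(draws@beta),
                      mean = colMeans(draws@beta),
                      lower = apply(draws@beta, 2, quantile, 0.025),
                      upper = apply(draws@beta, 2, quantile, 0.975),
                      row.names = NULL)
  DIC <- DICc <- delta <- NA_real_
  sig <- NA
  if (length(draws@data)) DIC <- as.numeric(dicLMM(draws))
  if (!is.null(constrained)) {
    DICc <- as.numeric(dicLMM(constrained))
    delta <- DICc - DIC
    sig <- delta > 2
  }
  new("RepeatabilityResult", response = draws@response,
      RMean = mean(R), RCI = as.numeric(quantile(R, c(0.025, 0.975))),
      VindMean = mean(draws@Vind), VeMean = mean(draws@Ve),
      DIC = DIC, DICc = DICc, deltaDIC = delta, significant = sig,
      fixef = fixef)
}

#' Stepwise fixed-effect reduction by DIC
#'
#' Greedy bidirectional elimination over the fixed terms: at each step every
#' hierarchy-respecting single-term drop or add is evaluated, the move with
#' the lowest DIC is taken, and the search stops when no move lowers the
#' DIC. The fish random intercept is never removed. Each candidate is
#' fitted with a seed derived deterministically from its term set so DIC
#' comparisons are not dominated by Monte-Carlo noise.
#'
#' @inheritParams fitLMM
#' @return list with elements `spec` (reduced), `fit` (its
#'   [PosteriorDraws-class]), `dic`, and `trace` (search log).
#' @export
stepwiseReduce <- function(spec, traits, metadata, mcmc = list(),
                           prior = list(), seed = 1) {
  stopifnot(inherits(spec, "LMMSpec"))
  candidates <- spec$fixed
  fit_terms <- function(terms) {
    s <- lmmSpec(spec$response, terms, spec$transform)
    sd <- deriveSeed(seed, paste(sort(terms), collapse = "+"))
    f <- fitLMM(s, traits, metadata, mcmc, prior, seed = sd)
    list(spec = s, fit = f, dic = as.numeric(dicLMM(f)))
  }
  # hierarchy-respecting moves
  droppable <- function(terms) {
    ok <- logical(length(terms))
    for (i in seq_along(terms)) {
      tm <- terms[i]
      if (grepl(":", tm)) ok[i] <- TRUE
      else ok[i] <- !any(vapply(grep(":", terms, value = TRUE), function(x)
        tm %in% strsplit(x, ":")[[1]], TRUE))
    }
    terms[ok]
  }
  addable <- function(terms) {
    absent <- setdiff(candidates, terms)
    keep <- vapply(absent, function(tm) {
      if (!grepl(":", tm)) return(TRUE)
      all(strsplit(tm, ":")[[1]] %in% terms)
    }, TRUE)
    absent[keep]
  }
  current <- fit_terms(spec$fixed)
  trace <- data.frame(step = 0L, move = "start",
                      terms = paste(sort(spec$fixed), collapse = "+"),
                      dic = current$dic, stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    moves <- c(lapply(droppable(current$spec$fixed), function(tm)
                 list(move = paste("drop", tm),
                      terms = setdiff(current$spec$fixed, tm))),
               lapply(addable(current$spec$fixed), function(tm)
                 list(move = paste("add", tm),
                      terms = c(current$spec$fixed, tm))))
    if (!length(moves)) break
    fits <- lapply(moves, function(mv) tryCatch(fit_terms(mv$terms),
                                                error = function(e) NULL))
    dics <- vapply(fits, function(f) if (is.null(f)) Inf else f$dic, 0)
    if (min(dics) >= current$dic) break
    k <- which.min(dics)
    current <- fits[[k]]
    trace <- rbind(trace, data.frame(step = step, move = moves[[k]]$move,
                                     terms = paste(sort(current$spec$fixed),
                                                   collapse = "+"),
                                     dic = current$dic))
  }
  list(spec = current$spec, fit = current$fit, dic = current$dic,
       trace = trace)
}

#' Durbin-Watson statistic over within-fish residual series
#'
#' `sum of within-fish squared lag-1 differences / total sum of squares`;
#' differences never span fish boundaries. Approximately 2 under
#' independence; small values indicate positive autocorrelation.
#'
#' @param e residual vector, time-ordered within fish.
#' @param fish grouping vector aligned with `e`.
#' @return the statistic.
#' @export
dwStatistic <- function(e, fish = rep(1L, length(e))) {
  groups <- split(e, fish)
  num <- sum(vapply(groups, function(g)
    if (length(g) > 1) sum(diff(g)^2) else 0, 0))
  num / sum(e^2)
}

#' Durbin-Watson autocorrelation check for a fitted model
#'
#' Tests for positive first-order temporal autocorrelation of the scaled
#' residuals (observed minus fixed effects and fish intercept at posterior
#' means), which would inflate repeatability (pseudo-R). The statistic is
#' `sum of within-fish squared lag-1 differences / total sum of squares`
#' (differences never span fish boundaries; ~2 under independence, small
#' values = positive autocorrelation). The one-sided p-value comes from a
#' within-fish permutation null.
#'
#' @param draws a [PosteriorDraws-class] from [fitLMM()].
#' @param nPerm number of permutations (default 2000).
#' @param seed RNG seed for the permutations.
#' @return list with `statistic`, `p_value`, `alternative`.
#' @export
durbinWatson <- function(draws, nPerm = 2000L, seed = 1) {
  stopifnot(is(draws, "PosteriorDraws"))
  X <- draws@data$X
  mu <- as.numeric(X %*% colMeans(draws@beta))
  if (any(draws@Vind > 0)) mu <- mu + colMeans(draws@u)[draws@data$fish + 1L]
  e <- (draws@data$y - mu) / sqrt(mean(draws@Ve))
  fish <- draws@data$fish
  ord <- order(fish, draws@data$dates)
  e <- e[ord]; fish <- fish[ord]
  groups <- split(e, fish)
  if (!any(lengths(groups) >= 3L))
    stop("need at least one fish with >= 3 residuals")
  obs <- dwStatistic(e, fish)
  set.seed(seed)
  perm <- replicate(nPerm, {
    ep <- unlist(lapply(groups, sample), use.names = FALSE)
    fp <- rep(seq_along(groups), lengths(groups))
    dwStatistic(ep, fp)
  })
  list(statistic = obs,
       p_value = (sum(perm <= obs) + 1) / (nPerm + 1),
       alternative = "autocorrelation > 0")
}

#' Screen covariate pairs for collinearity
#'
#' Pairwise association tests among candidate covariates, flagging pairs for
#' the analyst (no automatic exclusion): continuous-continuous via the
#' linear-fit t statistic, continuous-factor via one-way ANOVA F,
#' factor-factor via chi-squared. Constant covariates and single-level
#' factors are reported as not testable.
#'
#' @param metadata fish metadata.
#' @param covariates column names to screen (default the standard set).
#' @param alpha flagging threshold on the p-value (default 0.05).
#' @return data.frame (var1, var2, test, statistic, p_value, flag).
#' @export
screenCollinearity <- function(metadata,
                               covariates = c("length", "sex", "year",
                                              "centre_easting",
                                              "centre_northing"),
                               alpha = 0.05) {
  .assert_cols(metadata, covariates, "metadata")
  pairs <- combn(covariates, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    v1 <- pairs[1, k]; v2 <- pairs[2, k]
    x <- metadata[[v1]]; y <- metadata[[v2]]
    row <- data.frame(var1 = v1, var2 = v2, test = NA_character_,
                      statistic = NA_real_, p_value = NA_real_,
                      flag = NA, stringsAsFactors = FALSE)
    testable <- function(v) {
      if (is.numeric(v)) length(unique(v)) > 1L
      else nlevels(droplevels(factor(v))) > 1L
    }
    if (!testable(x) || !testable(y)) {
      row$test <- "not testable"
      return(row)
    }
    if (is.numeric(x) && is.numeric(y)) {
      fit <- summary(lm(y ~ x))$coefficients
      row$test <- "lm-t"
      row$statistic <- fit["x", "t value"]
      row$p_value <- fit["x", "Pr(>|t|)"]
    } else if (is.numeric(x) || is.numeric(y)) {
      cont <- if (is.numeric(x)) x else y
      fct <- droplevels(factor(if (is.numeric(x)) y else x))
      a <- anova(aov(cont ~ fct))
      row$test <- "anova-F"
      row$statistic <- a$`F value`[1]
      row$p_value <- a$`Pr(>F)`[1]
    } else {
      tb <- table(droplevels(factor(x)), droplevels(factor(y)))
      ct <- suppressWarnings(stats::chisq.test(tb))
      row$test <- "chisq"
      row$statistic <- unname(ct$statistic)
      row$p_value <- ct$p.value
    }
    if (!is.finite(row$statistic)) row$p_value <- 0
    row$flag <- is.na(row$p_value) || row$p_value < alpha
    row
  })
  do.call(rbind, out)
}
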