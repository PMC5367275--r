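# Independent brute-force oracles used to validate the fast implementations.

# Exhaustive-enumeration oracle for a 2-state Poisson HMM: joint probability
# of every state path, log-likelihood by log-sum-exp, exact posteriors, and
# the most probable path. Only feasible for short chains.
enum_hmm <- function(counts, init, trans, rates) {
  T <- length(counts)
  paths <- as.matrix(expand.grid(rep(list(1:2), T)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(init[s[1]]) + dpois(counts[1], rates[s[1]], log = TRUE)
    if (T > 1) for (t in 2:T)
      lp <- lp + log(trans[s[t - 1], s[t]]) +
        dpois(counts[t], rates[s[t]], log = TRUE)
    lp
  })
  M <- max(logp)
  ll <- M + log(sum(exp(logp - M)))
  post <- sapply(seq_len(T), function(t)
    sum(exp(logp[paths[, t] == 1] - ll)))
  list(loglik = ll, postActive = post,
       viterbi = paths[which.max(logp), ],
       top2gap = sort(logp, decreasing = TRUE)[1] -
         sort(logp, decreasing = TRUE)[2])
}

# One-way ANOVA method-of-moments estimators of the between- and
# within-individual variance components on balanced data.
mom_decomp <- function(y, fish) {
  fish <- factor(fish)
  ni <- table(fish)
  n0 <- (sum(ni) - sum(ni^2) / sum(ni)) / (nlevels(fish) - 1)
  msw <- sum(tapply(y, fish, function(g) sum((g - mean(g))^2))) /
    (sum(ni) - nlevels(fish))
  gm <- mean(y)
  msb <- sum(ni * (tapply(y, fish, mean) - gm)^2) / (nlevels(fish) - 1)
  c(Vind = (msb - msw) / n0, Ve = msw)
}

# Dense multivariate-normal conditioning oracle for the OU smoother on a
# regular grid: posterior mean/sd of the latent positions given all
# observations.
dense_ou_posterior <- function(y, centre, beta, sigma, obsSd, dt) {
  T <- length(y)
  tt <- (seq_len(T) - 1) * dt
  K <- sigma^2 / (2 * beta) * exp(-beta * abs(outer(tt, tt, "-")))
  obsIdx <- which(!is.na(y))
  Ko <- K[obsIdx, obsIdx, drop = FALSE] + diag(obsSd^2, length(obsIdx))
  W <- solve(Ko, y[obsIdx] - centre)
  mean <- centre + K[, obsIdx, drop = FALSE] %*% W
  V <- K - K[, obsIdx, drop = FALSE] %*%
    solve(Ko, K[obsIdx, , drop = FALSE])
  list(mean = as.numeric(mean), sd = sqrt(pmax(diag(V), 0)))
}

# Build a StateSequence from a generator trueStates slice (one fish).
true_state_sequence <- function(trueStates, id, binMinutes = 5) {
  df <- trueStates[trueStates$fish_id == id, , drop = FALSE]
  new("StateSequence", fishId = id, binStart = df$bin_start,
      binMinutes = binMinutes, state = df$state,
      postActive = as.numeric(df$state == "active"))
}

# Small balanced Gaussian random-intercept dataset (direct simulation,
# independent of the package generator) for the mixed-model tests.
sim_lmm_data <- function(nFish, nDays, Vind, Ve, mu = 0, seed = 1,
                         betaYear = 0) {
  set.seed(seed)
  fish <- sprintf("f%03d", seq_len(nFish))
  year <- rep(c("2011", "2012"), c(floor(nFish / 2), ceiling(nFish / 2)))
  u <- rnorm(nFish, 0, sqrt(Vind))
  traits <- data.frame(
    fish_id = rep(fish, each = nDays),
    date = rep(as.Date("2012-06-01") + seq_len(nDays) - 1, nFish),
    y = rep(mu + u + betaYear * (year == "2012"), each = nDays) +
      rnorm(nFish * nDays, 0, sqrt(Ve)))
  names(traits)[3] <- "awakening_min"
  meta <- data.frame(fish_id = fish, length = 150, sex = rep(c("F", "M"),
                     length.out = nFish), year = year,
                     tag_date = as.Date("2012-05-29"),
                     centre_easting = runif(nFish, 465000, 467000),
                     centre_northing = runif(nFish, 4358000, 4360000))
  list(traits = traits, meta = meta)
}
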