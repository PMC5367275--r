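#' @include utils.R
NULL

#' Construct Ornstein-Uhlenbeck movement parameters
#'
#' @param centre home-range centre (easting, northing) in metres.
#' @param beta attraction/exploration rate, per hour.
#' @param sigma diffusion scale, m h^-1/2.
#' @param obsSd positional observation noise s.d., metres.
#' @return an [OUParams-class].
#' @export
makeOUParams <- function(centre = c(0, 0), beta = 0.2, sigma = 9.49,
                         obsSd = 5) {
  new("OUParams", centre = as.numeric(centre), beta = as.numeric(beta),
      sigma = as.numeric(sigma), obsSd = as.numeric(obsSd),
      converged = NA, note = "")
}

#' Simulate an Ornstein-Uhlenbeck movement track
#'
#' Exact discretization per axis:
#' `x[t+dt] = c + exp(-beta dt) (x[t] - c) + eps`,
#' `eps ~ N(0, sigma^2 (1 - exp(-2 beta dt)) / (2 beta))`, started at the
#' stationary distribution; observations add `N(0, obsSd^2)` noise.
#'
#' @param params an [OUParams-class].
#' @param nSteps number of positions on the grid.
#' @param dt time step in hours (default 0.25 = 15 min).
#' @param start POSIXct time of the first position.
#' @param seed optional RNG seed.
#' @return data.frame (timestamp, x_true, y_true, x_m, y_m) where `x_m, y_m`
#'   are the noisy observations.
#' @export
simulateOU <- function(params, nSteps, dt = 0.25,
                       start = as.POSIXct("2012-06-01 00:00:00", tz = "UTC"),
                       seed = NULL) {
  stopifnot(is(params, "OUParams"), dt > 0, nSteps >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- exp(-params@beta * dt)
  q <- params@sigma^2 * (1 - a^2) / (2 * params@beta)
  s0 <- params@sigma / sqrt(2 * params@beta)
  sim_axis <- function(centre) {
    x <- numeric(nSteps)
    x[1] <- centre + rnorm(1, 0, s0)
    if (nSteps > 1) {
      eps <- rnorm(nSteps - 1, 0, sqrt(q))
      for (t in 2:nSteps) x[t] <- centre + a * (x[t - 1] - centre) + eps[t - 1]
    }
    x
  }
  xt <- sim_axis(params@centre[1])
  yt <- sim_axis(params@centre[2])
  data.frame(timestamp = start + (seq_len(nSteps) - 1) * dt * 3600,
             x_true = xt, y_true = yt,
             x_m = xt + rnorm(nSteps, 0, params@obsSd),
             y_m = yt + rnorm(nSteps, 0, params@obsSd))
}

# Scalar Kalman filter for one OU axis on a regular grid; NA observations
# are treated as missing (prediction only). Returns filtered moments,
# predictions and the prediction-error log-likelihood.
.ou_filter <- function(y, centre, beta, sigma, obsSd, dt) {
  n <- length(y)
  a <- exp(-beta * dt)
  q <- sigma^2 * (1 - a^2) / (2 * beta)
  m <- numeric(n); P <- numeric(n)
  mp <- numeric(n); Pp <- numeric(n)
  ll <- 0
  mprev <- centre
  Pprev <- sigma^2 / (2 * beta)
  for (t in seq_len(n)) {
    if (t == 1L) { mp[t] <- mprev; Pp[t] <- Pprev }
    else { mp[t] <- centre + a * (mprev - centre); Pp[t] <- a^2 * Pprev + q }
    if (is.na(y[t])) {
      m[t] <- mp[t]; P[t] <- Pp[t]
    } else {
      S <- Pp[t] + obsSd^2
      ll <- ll + dnorm(y[t], mp[t], sqrt(S), log = TRUE)
      K <- Pp[t] / S
      m[t] <- mp[t] + K * (y[t] - mp[t])
      P[t] <- (1 - K) * Pp[t]
    }
    mprev <- m[t]; Pprev <- P[t]
  }
  list(m = m, P = P, mp = mp, Pp = Pp, a = a, loglik = ll)
}

.ou_smooth_axis <- function(y, centre, beta, sigma, obsSd, dt) {
  f <- .ou_filter(y, centre, beta, sigma, obsSd, dt)
  n <- length(y)
  ms <- f$m; Ps <- f$P
  if (n > 1) {
    for (t in (n - 1):1) {
      C <- if (f$Pp[t + 1] > 0) f$a * f$P[t] / f$Pp[t + 1] else 0
      ms[t] <- f$m[t] + C * (ms[t + 1] - f$mp[t + 1])
      Ps[t] <- f$P[t] + C^2 * (Ps[t + 1] - f$Pp[t + 1])
    }
  }
  list(mean = ms, sd = sqrt(pmax(Ps, 0)), loglik = f$loglik)
}

#' Kalman-smooth noisy position observations
#'
#' Linear-Gaussian forward filter plus backward (RTS) smoother per axis under
#' the OU movement model, on a regular time grid. NA observations are
#' skipped by the filter (prediction only), so irregular detection coverage
#' is supported; the exact Gaussian posterior mean and s.d. are returned at
#' every grid point.
#'
#' @param observations data.frame with columns `timestamp`, `x_m`, `y_m`
#'   (NA = missing); must be on a regular time grid.
#' @param params an [OUParams-class].
#' @return data.frame (timestamp, x, y, sd_x, sd_y) of posterior means and
#'   standard deviations.
#' @export
smoothPositions <- function(observations, params) {
  stopifnot(is(params, "OUParams"))
  .assert_cols(observations, c("timestamp", "x_m", "y_m"), "observations")
  for (col in c("x_m", "y_m")) {
    bad <- which(!is.na(observations[[col]]) & !is.finite(observations[[col]]))
    if (length(bad))
      stop(sprintf("non-finite observation in %s at index %d", col, bad[1]))
  }
  dts <- diff(as.numeric(observations$timestamp)) / 3600
  if (length(dts) && diff(range(dts)) > 1e-6)
    stop("observations must be on a regular time grid")
  dt <- if (length(dts)) dts[1] else 0.25
  sx <- .ou_smooth_axis(observations$x_m, params@centre[1], params@beta,
                        params@sigma, params@obsSd, dt)
  sy <- .ou_smooth_axis(observations$y_m, params@centre[2], params@beta,
                        params@sigma, params@obsSd, dt)
  data.frame(timestamp = observations$timestamp, x = sx$mean, y = sy$mean,
             sd_x = sx$sd, sd_y = sy$sd)
}

#' Fit OU movement parameters by maximum likelihood
#'
#' Maximizes the Kalman-filter prediction-error likelihood over the
#' home-range centre, attraction rate `beta`, diffusion `sigma` and
#' observation noise, with positivity enforced on the log scale. Bound hits
#' and non-convergence are flagged in the returned object's `note`.
#'
#' @param observations data.frame (`timestamp`, `x_m`, `y_m`) on a regular
#'   grid, >= 50 non-missing steps.
#' @param dt grid step in hours; inferred from timestamps when omitted.
#' @return an [OUParams-class] with convergence diagnostics.
#' @export
fitOU <- function(observations, dt = NULL) {
  .assert_cols(observations, c("timestamp", "x_m", "y_m"), "observations")
  ok <- complete.cases(observations[, c("x_m", "y_m")])
  if (sum(ok) < 50L) stop("need at least 50 observed steps to fit OU parameters")
  if (is.null(dt)) {
    dts <- diff(as.numeric(observations$timestamp)) / 3600
    dt <- stats::median(dts)
  }
  x <- observations$x_m; y <- observations$y_m
  # moment-based starting values
  cx <- mean(x, na.rm = TRUE); cy <- mean(y, na.rm = TRUE)
  v <- mean(c(var(x, na.rm = TRUE), var(y, na.rm = TRUE)))
  xc <- x[ok] - cx
  r1 <- suppressWarnings(stats::cor(xc[-length(xc)], xc[-1]))
  if (!is.finite(r1) || r1 <= 0.01) r1 <- 0.5
  beta0 <- min(max(-log(r1) / dt, 1e-3), 50)
  sigma0 <- sqrt(pmax(2 * beta0 * v * 0.8, 1e-4))
  obs0 <- sqrt(pmax(v * 0.1, 1e-4))
  lower <- c(cx - 1e4, cy - 1e4, log(1e-4), log(1e-3), log(1e-4))
  upper <- c(cx + 1e4, cy + 1e4, log(200), log(1e4), log(1e4))
  nll <- function(par) {
    fx <- .ou_filter(x, par[1], exp(par[3]), exp(par[4]), exp(par[5]), dt)
    fy <- .ou_filter(y, par[2], exp(par[3]), exp(par[4]), exp(par[5]), dt)
    -(fx$loglik + fy$loglik)
  }
  fit <- optim(c(cx, cy, log(beta0), log(sigma0), log(obs0)), nll,
               method = "L-BFGS-B", lower = lower, upper = upper)
  note <- character()
  if (fit$convergence != 0) note <- c(note, paste("optim code", fit$convergence))
  atBound <- which(abs(fit$par - lower) < 1e-6 | abs(fit$par - upper) < 1e-6)
  if (length(atBound))
    note <- c(note, paste("parameter(s) at bound:",
                          paste(c("cx", "cy", "beta", "sigma", "obsSd")[atBound],
                                collapse = ", ")))
  out <- new("OUParams", centre = fit$par[1:2], beta = exp(fit$par[3]),
             sigma = exp(fit$par[4]), obsSd = exp(fit$par[5]),
             converged = fit$convergence == 0,
             note = paste(note, collapse = "; "))
  attr(out, "logLik") <- -fit$value
  out
}

#' OU prediction-error log-likelihood at given parameters
#'
#' @param observations data.frame (`timestamp`, `x_m`, `y_m`).
#' @param params an [OUParams-class].
#' @param dt grid step in hours; inferred when omitted.
#' @return the log-likelihood (both axes summed).
#' @export
ouLogLik <- function(observations, params, dt = NULL) {
  if (is.null(dt)) dt <- stats::median(diff(as.numeric(observations$timestamp)) / 3600)
  fx <- .ou_filter(observations$x_m, params@centre[1], params@beta,
                   params@sigma, params@obsSd, dt)
  fy <- .ou_filter(observations$y_m, params@centre[2], params@beta,
                   params@sigma, params@obsSd, dt)
  fx$loglik + fy$loglik
}

#' Daily travelled distance
#'
#' Sums the Euclidean distances between consecutive estimated positions
#' within each local day.
#'
#' @param track data.frame with `timestamp`, `x`, `y` (and optionally
#'   `fish_id`).
#' @return data.frame (fish_id, date, dist_m, n_positions); days with fewer
#'   than two positions get NA distance.
#' @export
dailyDistance <- function(track) {
  .assert_cols(track, c("timestamp", "x", "y"), "track")
  id <- if ("fish_id" %in% names(track)) as.character(track$fish_id[1]) else NA_character_
  dates <- .local_date(track$timestamp)
  out <- lapply(split(seq_len(nrow(track)), dates), function(ix) {
    n <- length(ix)
    d <- if (n < 2L) NA_real_ else
      sum(sqrt(diff(track$x[ix])^2 + diff(track$y[ix])^2))
    data.frame(fish_id = id, date = dates[ix[1]], dist_m = d,
               n_positions = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
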