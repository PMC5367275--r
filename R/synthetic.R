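#' @include AllClasses.R io.R movement.R
NULL

.TRAITS <- c("awakening", "rest_onset", "rest_dur", "distance")

#' Construct the ground truth of a synthetic telemetry study
#'
#' Defaults mirror the source study's fitted population: per-trait means,
#' between- (V_ind) and within-individual (V_e) variances and fixed-effect
#' coefficients at the reported posterior means; Poisson detection rates of
#' 4 (active) and 0.2 (resting, buried fish near a receiver still yield
#' occasional detections) per 5-min bin; 14 fish (6 in "2011", 8 in "2012")
#' tracked 14 days; and a mean-reverting home-range movement model whose
#' default scale reproduces the study's mean daily travelled distance.
#' Trait units: awakening/rest onset in signed minutes relative to
#' sunrise/sunset; rest duration in hours and travelled distance in metres
#' (both modelled on the log scale). Continuous coordinate effects are per
#' km of mean-centred home-range coordinate.
#'
#' @param traits data.frame (rows awakening, rest_onset, rest_dur, distance;
#'   columns mean, Vind, Ve, betaLat, betaLon, betaYear, transform) to
#'   override per-trait parameters.
#' @param rhoInd,rhoE 4x4 between-/within-individual correlation matrices
#'   (default identity).
#' @param lambdaActive,lambdaRest Poisson detection rates per 5-min bin.
#' @param ou list overriding movement settings: beta (h^-1), stationarySd
#'   (m), obsSd (m), betaCV (between-fish spread of log beta), dailySdLog
#'   (day-to-day spread of log diffusion).
#' @param nFish,nDays study dimensions.
#' @param config list overriding study plumbing: startDate, rectangle
#'   (easting/northing ranges, m), sunriseBase/sunsetBase (clock times),
#'   sunDriftMin (min/day), yearSplit, distanceMode ("movement" or
#'   "gaussian"), binMinutes, deterministicPings.
#' @return a [PopulationTruth-class].
#' @export
populationTruth <- function(traits = NULL, rhoInd = diag(4), rhoE = diag(4),
                            lambdaActive = 4, lambdaRest = 0.2,
                            ou = list(), nFish = 14L, nDays = 14L,
                            config = list()) {
  base <- data.frame(
    row.names = .TRAITS,
    mean = c(85.13, 4.90, 2.42, 6.15),
    Vind = c(2138.63, 13.49, 0.01, 0.33),
    Ve = c(3230.68, 32.17, 0.01, 0.07),
    betaLat = c(-34.92, 0, -0.05, -0.28),
    betaLon = c(0, 4.41, 0, 0),
    betaYear = c(84.29, 0, 0.17, 0),
    transform = c("identity", "identity", "log", "log"),
    unit = c("min", "min", "log(h)", "log(m)"),
    stringsAsFactors = FALSE)
  if (!is.null(traits))
    for (nm in intersect(names(traits), names(base)))
      base[rownames(traits), nm] <- traits[[nm]]
  ouDef <- utils::modifyList(
    list(beta = 0.2, stationarySd = 15, obsSd = 5, betaCV = 0.2,
         dailySdLog = 0.25), ou)
  cfgDef <- utils::modifyList(
    list(startDate = "2012-06-01",
         easting = c(465000, 467000), northing = c(4358000, 4360000),
         sunriseBase = "06:30:00", sunsetBase = "20:00:00",
         sunDriftMin = 0.5, yearSplit = c("2011" = 6L, "2012" = 8L),
         distanceMode = "movement", binMinutes = 5L,
         deterministicPings = FALSE, fullyGaussianTraits = FALSE,
         predatorRate = 0, predatorBoutBins = 4L), config)
  if (is.null(config$yearSplit) && nFish != 14L) {
    n1 <- floor(nFish / 2)
    cfgDef$yearSplit <- c("2011" = n1, "2012" = as.integer(nFish - n1))
  }
  new("PopulationTruth", traits = base, rhoInd = rhoInd, rhoE = rhoE,
      lambdaActive = lambdaActive, lambdaRest = lambdaRest, ou = ouDef,
      nFish = as.integer(nFish), nDays = as.integer(nDays), config = cfgDef)
}

.check_psd <- function(R, what) {
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(what, " is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")")
}

#' Draw per-fish latent trait means and covariates
#'
#' Realizes the between-individual layer of the variance decomposition: each
#' fish's latent mean vector is drawn from a multivariate normal with
#' covariance `diag(sqrt(V_ind)) rho_ind diag(sqrt(V_ind))` around the
#' population means shifted by its covariate effects (home-range-centre
#' coordinates, year, sex is assigned but carries no effect by default).
#'
#' @param truth a [PopulationTruth-class].
#' @param seed RNG seed.
#' @return data.frame with one row per fish: covariates plus latent means
#'   `mu_awakening`, `mu_rest_onset`, `mu_rest_dur`, `mu_distance` (the
#'   log-scale traits on the log scale).
#' @export
drawIndividuals <- function(truth, seed = 1) {
  stopifnot(is(truth, "PopulationTruth"))
  .check_psd(truth@rhoInd, "rho_ind")
  .check_psd(truth@rhoE, "rho_e")
  set.seed(seed)
  cfg <- truth@config
  n <- truth@nFish
  years <- rep(names(cfg$yearSplit), cfg$yearSplit)[seq_len(n)]
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.6, 0.4))
  meta <- data.frame(
    fish_id = sprintf("fish%02d", seq_len(n)),
    length = round(150 + 30 * (sex == "M") + rnorm(n, 0, 10), 1),
    sex = sex, year = years,
    tag_date = as.Date(cfg$startDate) - 3L,
    centre_easting = round(runif(n, cfg$easting[1], cfg$easting[2]), 1),
    centre_northing = round(runif(n, cfg$northing[1], cfg$northing[2]), 1),
    stringsAsFactors = FALSE)
  tr <- truth@traits
  latKm <- (meta$centre_northing - mean(range(cfg$northing))) / 1000
  lonKm <- (meta$centre_easting - mean(range(cfg$easting))) / 1000
  yr2 <- as.numeric(meta$year == "2012")
  S <- diag(sqrt(tr$Vind)) %*% truth@rhoInd %*% diag(sqrt(tr$Vind))
  dev <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = S)
  if (n == 1L) dev <- matrix(dev, nrow = 1)
  for (k in seq_along(.TRAITS)) {
    mu <- tr$mean[k] + tr$betaLat[k] * latKm + tr$betaLon[k] * lonKm +
      tr$betaYear[k] * yr2 + dev[, k]
    meta[[paste0("mu_", .TRAITS[k])]] <- mu
  }
  meta
}

#' Build the study sun table
#'
#' @param truth a [PopulationTruth-class].
#' @param extraDays extra leading/trailing days of coverage (default 1).
#' @return data.frame (date, sunrise, sunset) with a slow linear drift
#'   (earlier sunrises, later sunsets) across the window.
#' @export
makeSunTable <- function(truth, extraDays = 1L) {
  cfg <- truth@config
  dates <- as.Date(cfg$startDate) + seq(-extraDays, truth@nDays + extraDays - 1L)
  d <- as.numeric(dates - as.Date(cfg$startDate))
  data.frame(
    date = dates,
    sunrise = .parse_time(paste(format(dates), cfg$sunriseBase)) -
      round(d * cfg$sunDriftMin * 60),
    sunset = .parse_time(paste(format(dates), cfg$sunsetBase)) +
      round(d * cfg$sunDriftMin * 60))
}

.floor_grid <- function(t, origin, binSec) {
  origin + floor((as.numeric(t) - as.numeric(origin)) / binSec) * binSec
}

#' Simulate true daily trait values
#'
#' Adds the within-individual layer: daily awakening and rest-onset values
#' are the fish's latent means plus deviations drawn with covariance
#' `diag(sqrt(V_e)) rho_e diag(sqrt(V_e))`. Rest duration is then computed
#' to be self-consistent with the realized rest onset of the previous day,
#' the awakening of the current day and the sun table (so its variance
#' components are implied, not dialled), unless the fully-Gaussian shortcut
#' (`config$fullyGaussianTraits`) is on, in which case it is drawn from its
#' own variance layer like the timing traits. The distance column is filled
#' from the Gaussian layer only in "gaussian" distance mode; in "movement"
#' mode it is left NA for [renderMovement()] to fill. Continuous clock times are
#' also snapped to the 5-min bin grid (`*_snap` columns), the resolution at
#' which states are rendered.
#'
#' @param fishMeans output of [drawIndividuals()].
#' @param truth a [PopulationTruth-class].
#' @param sunTable from [makeSunTable()] (rebuilt when omitted).
#' @param seed RNG seed.
#' @return data.frame of true daily traits, one row per fish-day.
#' @export
simulateDays <- function(fishMeans, truth, sunTable = makeSunTable(truth),
                         seed = 1) {
  stopifnot(is(truth, "PopulationTruth"))
  set.seed(seed)
  cfg <- truth@config
  tr <- truth@traits
  binSec <- cfg$binMinutes * 60
  n <- nrow(fishMeans)
  dates <- as.Date(cfg$startDate) + seq_len(truth@nDays) - 1L
  Se <- diag(sqrt(tr$Ve)) %*% truth@rhoE %*% diag(sqrt(tr$Ve))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dev <- MASS::mvrnorm(truth@nDays, mu = rep(0, 4), Sigma = Se)
    if (truth@nDays == 1L) dev <- matrix(dev, nrow = 1)
    awake <- fishMeans$mu_awakening[i] + dev[, 1]
    onset <- fishMeans$mu_rest_onset[i] + dev[, 2]
    sIdx <- match(dates, sunTable$date)
    awakeAbs <- sunTable$sunrise[sIdx] + awake * 60
    onsetAbs <- sunTable$sunset[sIdx] + onset * 60
    dayStart <- .midnight(dates)
    awakeSnapAbs <- .floor_grid(awakeAbs, dayStart, binSec)
    onsetSnapAbs <- .floor_grid(onsetAbs, dayStart, binSec) + binSec
    restDur <- if (isTRUE(cfg$fullyGaussianTraits)) {
      # fully-Gaussian shortcut: rest duration is a free trait drawn from
      # its own variance layer (no arithmetic coupling to the timing traits)
      ld <- fishMeans$mu_rest_dur[i] + dev[, 3]
      if (tr$transform[3] == "log") exp(ld) else ld
    } else {
      c(NA, as.numeric(awakeAbs[-1] - onsetAbs[-truth@nDays],
                       units = "hours"))
    }
    distm <- rep(NA_real_, truth@nDays)
    if (cfg$distanceMode == "gaussian") {
      ld <- fishMeans$mu_distance[i] + dev[, 4]
      distm <- if (tr$transform[4] == "log") exp(ld) else ld
    }
    rows[[i]] <- data.frame(
      fish_id = fishMeans$fish_id[i], date = dates,
      awakening_min = awake, onset_min = onset,
      awakening_snap_min = as.numeric(awakeSnapAbs - sunTable$sunrise[sIdx],
                                      units = "mins"),
      onset_snap_min = as.numeric(onsetSnapAbs - sunTable$sunset[sIdx],
                                  units = "mins"),
      rest_dur_h = restDur, dist_m = distm,
      awake_abs = awakeAbs, onset_abs = onsetAbs,
      awake_snap_abs = awakeSnapAbs, onset_snap_abs = onsetSnapAbs,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render detection counts and latent states from true traits
#'
#' For each fish-day, the 5-min bins between the (snapped) true awakening
#' and rest onset are labelled active and the rest resting; per-bin
#' detection counts are Poisson with the state's rate and expanded into
#' within-bin timestamps (uniform sub-second placement, or one ping per
#' minute when `deterministicPings` is set). Days whose awakening falls
#' after their rest onset are flagged, skipped and warned about. When
#' `config$predatorRate > 0`, that fraction of fish-days receives one extra
#' short rest bout (daytime burying under predator threat,
#' `config$predatorBoutBins` bins) strictly inside the active window, so
#' the day's first and last active moments — the timing traits — are
#' unchanged.
#'
#' @param trueTraits output of [simulateDays()].
#' @param sunTable the study sun table.
#' @param truth a [PopulationTruth-class].
#' @param seed RNG seed.
#' @return list with `detections` (fish_id, timestamp) and `trueStates`
#'   (fish_id, bin_start, state).
#' @export
renderDetections <- function(trueTraits, sunTable, truth, seed = 1) {
  stopifnot(is(truth, "PopulationTruth"))
  set.seed(seed)
  cfg <- truth@config
  binSec <- cfg$binMinutes * 60
  binsPerDay <- as.integer(86400 / binSec)
  det <- list(); states <- list()
  for (id in unique(trueTraits$fish_id)) {
    tt <- trueTraits[trueTraits$fish_id == id, , drop = FALSE]
    bad <- which(tt$awake_abs >= tt$onset_abs)
    if (length(bad)) {
      warning("fish ", id, ": awakening after rest onset on ",
              paste(format(tt$date[bad]), collapse = ", "), "; day(s) skipped")
    }
    for (d in seq_len(nrow(tt))) {
      day0 <- .midnight(tt$date[d])
      binStart <- day0 + (seq_len(binsPerDay) - 1L) * binSec
      active <- if (d %in% bad) rep(FALSE, binsPerDay) else
        binStart >= tt$awake_snap_abs[d] & binStart < tt$onset_snap_abs[d]
      # optional predator interruptions: short extra rest bouts inside the
      # active window (daytime burying), to stress the state decoder
      if (cfg$predatorRate > 0 && any(active) &&
          runif(1) < cfg$predatorRate) {
        actIdx <- which(active)
        if (length(actIdx) > cfg$predatorBoutBins + 2L) {
          at <- sample(actIdx[-seq_len(1)], 1)
          active[at:min(at + cfg$predatorBoutBins - 1L, max(actIdx) - 1L)] <- FALSE
        }
      }
      lam <- ifelse(active, truth@lambdaActive, truth@lambdaRest)
      if (isTRUE(cfg$deterministicPings)) {
        counts <- ifelse(active, cfg$binMinutes, 0L)
        ts <- rep(binStart, counts) +
          unlist(lapply(counts[counts > 0], function(k) (seq_len(k) - 1) * 60))
      } else {
        counts <- rpois(binsPerDay, lam)
        tot <- sum(counts)
        ts <- if (tot) rep(binStart, counts) + runif(tot, 0, binSec) else
          as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC")
      }
      if (length(ts))
        det[[length(det) + 1L]] <- data.frame(fish_id = id, timestamp = sort(ts),
                                              stringsAsFactors = FALSE)
      states[[length(states) + 1L]] <- data.frame(
        fish_id = id, bin_start = binStart,
        state = ifelse(active, "active", "rest"), stringsAsFactors = FALSE)
    }
  }
  list(detections = do.call(rbind, det), trueStates = do.call(rbind, states))
}

#' Simulate movement tracks and true daily distances
#'
#' Draws per-fish movement parameters around the population movement model
#' (log-normal spread of the attraction rate; the diffusion scale carries
#' the distance trait's between-individual variance and covariate effects,
#' plus a day-to-day log-normal activity multiplier), simulates the true
#' track at 15-min steps, adds Gaussian positional observation noise, and
#' computes each day's true travelled distance from the true positions.
#'
#' @param fishMeans output of [drawIndividuals()].
#' @param truth a [PopulationTruth-class].
#' @param seed RNG seed.
#' @return list with `positions` (noisy observations: fish_id, timestamp,
#'   x_m, y_m), `ouParams` (list of per-fish [OUParams-class]) and
#'   `trueDistance` (fish_id, date, dist_m).
#' @export
renderMovement <- function(fishMeans, truth, seed = 1) {
  stopifnot(is(truth, "PopulationTruth"))
  set.seed(seed)
  cfg <- truth@config
  ou <- truth@ou
  dt <- 0.25
  stepsPerDay <- as.integer(24 / dt)
  nSteps <- truth@nDays * stepsPerDay
  start <- .midnight(as.Date(cfg$startDate))
  sigmaPop <- ou$stationarySd * sqrt(2 * ou$beta)
  pos <- list(); dist <- list(); pars <- list()
  for (i in seq_len(nrow(fishMeans))) {
    id <- fishMeans$fish_id[i]
    betaF <- ou$beta * exp(rnorm(1, 0, ou$betaCV))
    # mu_distance carries the between-fish + covariate structure of log
    # distance; daily distance scales with the diffusion sigma, so the
    # fish's deviation from the population log-mean maps onto log sigma
    lsigF <- log(sigmaPop) +
      (fishMeans$mu_distance[i] - truth@traits["distance", "mean"])
    dayMult <- exp(rnorm(truth@nDays, 0, ou$dailySdLog))
    a <- exp(-betaF * dt)
    ctr <- c(fishMeans$centre_easting[i], fishMeans$centre_northing[i])
    x <- matrix(0, nSteps, 2)
    s0 <- exp(lsigF) / sqrt(2 * betaF)
    prev <- ctr + rnorm(2, 0, s0)
    for (t in seq_len(nSteps)) {
      dayIdx <- (t - 1) %/% stepsPerDay + 1L
      sig <- exp(lsigF) * dayMult[dayIdx]
      q <- sig^2 * (1 - a^2) / (2 * betaF)
      prev <- ctr + a * (prev - ctr) + rnorm(2, 0, sqrt(q))
      x[t, ] <- prev
    }
    times <- start + (seq_len(nSteps) - 1) * dt * 3600
    obs <- x + matrix(rnorm(2 * nSteps, 0, ou$obsSd), nSteps, 2)
    pos[[i]] <- data.frame(fish_id = id, timestamp = times,
                           x_m = obs[, 1], y_m = obs[, 2],
                           stringsAsFactors = FALSE)
    td <- dailyDistance(data.frame(fish_id = id, timestamp = times,
                                   x = x[, 1], y = x[, 2]))
    dist[[i]] <- td[, c("fish_id", "date", "dist_m")]
    pars[[id]] <- new("OUParams", centre = ctr, beta = betaF,
                      sigma = exp(lsigF), obsSd = ou$obsSd,
                      converged = NA, note = "generator truth")
  }
  list(positions = do.call(rbind, pos), ouParams = pars,
       trueDistance = do.call(rbind, dist))
}

#' Generate a complete synthetic telemetry dataset
#'
#' Runs the full generator — individuals, daily traits, detection rendering
#' and (in "movement" mode) the movement layer — and optionally writes the
#' dataset as plain-text files (detections.csv, sun_table.csv, metadata.csv,
#' positions.csv, truth.json). Generation is a pure function of
#' (truth, seed): the same inputs give byte-identical files.
#'
#' @param truth a [PopulationTruth-class] (default [populationTruth()]).
#' @param seed integer seed; stage seeds are derived deterministically.
#' @param dir optional output directory.
#' @return a [SyntheticDataset-class].
#' @export
generateDataset <- function(truth = populationTruth(), seed = 1, dir = NULL) {
  stopifnot(is(truth, "PopulationTruth"))
  fishMeans <- drawIndividuals(truth, deriveSeed(seed, "individuals"))
  sun <- makeSunTable(truth)
  tt <- simulateDays(fishMeans, truth, sun, deriveSeed(seed, "days"))
  rend <- renderDetections(tt, sun, truth, deriveSeed(seed, "detections"))
  positions <- data.frame()
  if (truth@config$distanceMode == "movement") {
    mov <- renderMovement(fishMeans, truth, deriveSeed(seed, "movement"))
    positions <- mov$positions
    key <- paste(tt$fish_id, tt$date)
    mkey <- paste(mov$trueDistance$fish_id, mov$trueDistance$date)
    tt$dist_m <- mov$trueDistance$dist_m[match(key, mkey)]
  }
  metaCols <- c("fish_id", "length", "sex", "year", "tag_date",
                "centre_easting", "centre_northing")
  ds <- new("SyntheticDataset", detections = rend$detections,
            sunTable = sun, metadata = fishMeans[, metaCols],
            positions = positions, trueStates = rend$trueStates,
            trueTraits = tt, truth = truth)
  if (!is.null(dir)) writeDataset(ds, dir)
  ds
}

#' Write a synthetic dataset to plain-text files
#'
#' @param ds a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(t) format(t, "%Y-%m-%d %H:%M:%OS3")
  det <- ds@detections
  det$timestamp <- fmt(det$timestamp)
  write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  sun <- ds@sunTable
  sun$sunrise <- format(sun$sunrise, "%Y-%m-%d %H:%M:%S")
  sun$sunset <- format(sun$sunset, "%Y-%m-%d %H:%M:%S")
  write.csv(sun, file.path(dir, "sun_table.csv"), row.names = FALSE)
  write.csv(ds@metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  if (nrow(ds@positions)) {
    pos <- ds@positions
    pos$timestamp <- format(pos$timestamp, "%Y-%m-%d %H:%M:%S")
    write.csv(pos, file.path(dir, "positions.csv"), row.names = FALSE)
  }
  tr <- ds@truth
  truthJson <- list(traits = cbind(trait = rownames(tr@traits), tr@traits),
                    rhoInd = tr@rhoInd, rhoE = tr@rhoE,
                    lambdaActive = tr@lambdaActive,
                    lambdaRest = tr@lambdaRest, ou = tr@ou,
                    nFish = tr@nFish, nDays = tr@nDays)
  writeLines(jsonlite::toJSON(truthJson, digits = NA, auto_unbox = TRUE),
             file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a generator configuration from YAML
#'
#' The YAML may override any argument of [populationTruth()]: a `traits`
#' block (per-trait mean/Vind/Ve/beta values), `rhoInd`/`rhoE`, the
#' detection rates, `ou`, `nFish`, `nDays` and `config` entries.
#'
#' @param path YAML file path.
#' @return a [PopulationTruth-class].
#' @export
readTruthConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$traits)) {
    tr <- do.call(rbind, lapply(names(y$traits), function(nm)
      data.frame(row.names = nm, as.list(y$traits[[nm]]))))
    args$traits <- tr
  }
  for (nm in c("lambdaActive", "lambdaRest", "nFish", "nDays"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  for (nm in c("rhoInd", "rhoE"))
    if (!is.null(y[[nm]])) args[[nm]] <- matrix(unlist(y[[nm]]), 4, 4)
  if (!is.null(y$ou)) args$ou <- y$ou
  if (!is.null(y$config)) args$config <- y$config
  do.call(populationTruth, args)
}
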