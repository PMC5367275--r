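gauss_truth <- function(..., config = list())
  populationTruth(..., config = utils::modifyList(
    list(distanceMode = "gaussian"), config))

test_that("zero between-individual variance gives identical latent means", {
  trt <- data.frame(row.names = c("awakening", "rest_onset", "rest_dur",
                                  "distance"),
                    Vind = c(0, 0, 0, 0), betaLat = 0, betaLon = 0,
                    betaYear = 0)
  truth <- populationTruth(traits = trt, nFish = 20L)
  fi <- drawIndividuals(truth, seed = 1)
  expect_equal(var(fi$mu_awakening), 0)
  expect_equal(unique(fi$mu_rest_onset), truth@traits["rest_onset", "mean"])
})

test_that("latent-mean spread matches the stated distribution", {
  trt <- data.frame(row.names = "awakening", Vind = 900, betaLat = 0,
                    betaYear = 0)
  truth <- populationTruth(traits = trt, nFish = 10000L)
  fi <- drawIndividuals(truth, seed = 5)
  expect_lt(abs(var(fi$mu_awakening) - 900) / 900, 0.05)
})

test_that("the year effect shifts group means by its coefficient", {
  truth <- populationTruth(nFish = 4000L,
                           config = list(yearSplit = c("2011" = 2000L,
                                                       "2012" = 2000L)))
  fi <- drawIndividuals(truth, seed = 8)
  # remove the latitude effect before comparing year groups
  resid <- fi$mu_awakening + 34.92 *
    (fi$centre_northing - mean(range(truth@config$northing))) / 1000
  diffYear <- mean(resid[fi$year == "2012"]) - mean(resid[fi$year == "2011"])
  expect_lt(abs(diffYear - 84.29), 3)
})

test_that("a non-PSD correlation matrix is rejected with a clear message", {
  R <- diag(4); R[1, 2] <- R[2, 1] <- 0.9; R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9
  expect_error(populationTruth(rhoInd = R), "positive semi-definite")
})

test_that("zero within-individual variance pins every day at the fish mean", {
  trt <- data.frame(row.names = c("awakening", "rest_onset", "rest_dur",
                                  "distance"),
                    Ve = c(1e-12, 1e-12, 1e-12, 1e-12))
  truth <- gauss_truth(traits = trt, nFish = 3L, nDays = 5L)
  fi <- drawIndividuals(truth, seed = 2)
  tt <- simulateDays(fi, truth, seed = 3)
  for (id in fi$fish_id) {
    aw <- tt$awakening_min[tt$fish_id == id]
    expect_equal(aw, rep(fi$mu_awakening[fi$fish_id == id], length(aw)),
                 tolerance = 1e-4)
  }
})

test_that("moment decomposition of a 50x50 study recovers the components", {
  trt <- data.frame(row.names = "awakening", Vind = 400, Ve = 600,
                    betaLat = 0, betaYear = 0)
  truth <- gauss_truth(traits = trt, nFish = 50L, nDays = 50L)
  ds <- generateDataset(truth, seed = 13)
  est <- mom_decomp(ds@trueTraits$awakening_min, ds@trueTraits$fish_id)
  expect_lt(abs(est["Vind"] - 400) / 400, 0.10)
  expect_lt(abs(est["Ve"] - 600) / 600, 0.10)
  # and the implied repeatability formula
  expect_equal(400 / (400 + 600), 0.4)
})

test_that("rest duration is self-consistent with onset and awakening", {
  truth <- gauss_truth(nFish = 3L, nDays = 4L)
  ds <- generateDataset(truth, seed = 11)
  tt <- ds@trueTraits
  valid <- !is.na(tt$rest_dur_h)
  lhs <- tt$rest_dur_h[valid]
  i <- which(valid)
  rhs <- as.numeric(tt$awake_abs[i] - tt$onset_abs[i - 1], units = "hours")
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("rendering honours the state-conditional Poisson rates", {
  # resting rate zero: rest bins carry no detections at all
  truth0 <- gauss_truth(nFish = 2L, nDays = 3L, lambdaRest = 0)
  ds0 <- generateDataset(truth0, seed = 4)
  det <- readDetections(ds0@detections)
  for (id in unique(det$fish_id)) {
    chain <- binDetections(det[det$fish_id == id, ])
    st <- ds0@trueStates[ds0@trueStates$fish_id == id, ]
    m <- match(chain$bin_start, st$bin_start)
    expect_true(all(chain$count[st$state[m] == "rest"] == 0L))
  }

  # active-rate mean over many active bins
  truth <- gauss_truth(nFish = 10L, nDays = 10L)
  ds <- generateDataset(truth, seed = 6)
  det <- readDetections(ds@detections)
  counts <- numeric()
  for (id in unique(det$fish_id)) {
    chain <- binDetections(det[det$fish_id == id, ])
    st <- ds@trueStates[ds@trueStates$fish_id == id, ]
    m <- match(chain$bin_start, st$bin_start)
    counts <- c(counts, chain$count[st$state[m] == "active"])
  }
  expect_gt(length(counts), 10000)
  expect_lt(abs(mean(counts) - 4) / 4, 0.02)
})

test_that("deterministic minute pings never exceed 5 per bin", {
  truth <- gauss_truth(nFish = 1L, nDays = 2L,
                       config = list(deterministicPings = TRUE))
  ds <- generateDataset(truth, seed = 2)
  chain <- binDetections(readDetections(ds@detections))
  expect_equal(max(chain$count), 5L)
})

test_that("a day with awakening after rest onset is skipped with a warning", {
  trt <- data.frame(row.names = c("awakening", "rest_onset"),
                    mean = c(900, 5), Vind = c(1, 1), Ve = c(1, 1))
  truth <- gauss_truth(traits = trt, nFish = 1L, nDays = 2L)
  fi <- drawIndividuals(truth, seed = 1)
  tt <- simulateDays(fi, truth, seed = 1)
  expect_warning(rend <- renderDetections(tt, makeSunTable(truth), truth,
                                          seed = 1),
                 "skipped")
  expect_true(all(rend$trueStates$state == "rest"))
})

test_that("predator interruptions add rest bouts without moving the traits", {
  truth <- gauss_truth(nFish = 3L, nDays = 6L,
                       config = list(predatorRate = 1))
  ds <- generateDataset(truth, seed = 19)
  st <- ds@trueStates
  nBouts <- sapply(split(st$state == "active",
                         paste(st$fish_id, as.Date(st$bin_start))), function(a) {
    r <- rle(a); sum(r$values)
  })
  expect_gt(mean(nBouts > 1), 0.5)  # most days have a split active window
  # the timing traits are untouched: first/last active moments equal truth
  seqs <- lapply(unique(st$fish_id), function(id)
    true_state_sequence(st, id))
  tab <- buildTraitTable(seqs, ds@sunTable)
  tt <- ds@trueTraits
  m <- match(paste(tab$fish_id, tab$date), paste(tt$fish_id, tt$date))
  expect_equal(tab$awakening_min, tt$awakening_snap_min[m], tolerance = 1e-9)
  expect_equal(tab$onset_min, tt$onset_snap_min[m], tolerance = 1e-9)
})

test_that("the default configuration mirrors the study dimensions", {
  truth <- populationTruth()
  expect_equal(truth@nFish, 14L)
  expect_equal(truth@nDays, 14L)
  expect_equal(unname(truth@config$yearSplit), c(6L, 8L))
  expect_equal(truth@lambdaActive, 4)
})

test_that("a minimal 1-fish 1-day dataset passes every downstream reader", {
  truth <- gauss_truth(nFish = 1L, nDays = 1L)
  ds <- generateDataset(truth, seed = 1)
  det <- readDetections(ds@detections)
  sun <- readSunTable(data.frame(date = format(ds@sunTable$date),
                                 sunrise = format(ds@sunTable$sunrise),
                                 sunset = format(ds@sunTable$sunset)))
  meta <- readFishMeta(ds@metadata)
  expect_equal(nrow(meta), 1L)
  chain <- binDetections(det)
  expect_equal(nrow(chain), 288L)
  fit <- fitHMM(chain, seed = 1)
  tab <- buildTraitTable(decodeStates(chain, fit), sun)
  expect_equal(nrow(tab), 1L)
})

test_that("generation is a pure function of truth and seed", {
  truth <- gauss_truth(nFish = 2L, nDays = 2L)
  d1 <- tempfile(); d2 <- tempfile()
  generateDataset(truth, seed = 99, dir = d1)
  generateDataset(truth, seed = 99, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  d3 <- generateDataset(truth, seed = 100)
  d4 <- generateDataset(truth, seed = 99)
  expect_false(identical(d4@detections, d3@detections))
})

test_that("a YAML configuration round-trips into a PopulationTruth", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("nFish: 5", "nDays: 3", "lambdaRest: 0.5",
               "traits:", "  awakening:", "    Vind: 111",
               "config:", "  distanceMode: gaussian"), yml)
  truth <- readTruthConfig(yml)
  expect_equal(truth@nFish, 5L)
  expect_equal(truth@lambdaRest, 0.5)
  expect_equal(truth@traits["awakening", "Vind"], 111)
  expect_equal(truth@config$distanceMode, "gaussian")
})
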