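day_view <- function(activeBins, date = "2012-06-01") {
  start <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  df <- data.frame(bin_start = start + 300 * (0:287),
                   state = rep("rest", 288))
  df$state[activeBins] <- "active"
  attr(df, "binMinutes") <- 5
  df
}

.t <- function(x) as.POSIXct(x, tz = "UTC")

test_that("awakening time is signed minutes from sunrise to first active bin", {
  # first active bin starts 08:25, sunrise 06:30 -> +115
  dv <- day_view((8 * 12 + 5 + 1):250)
  expect_equal(awakeningTime(dv, .t("2012-06-01 06:30:00")), 115)
  # pre-dawn activity: first active 06:15, sunrise 06:30 -> -15
  dv2 <- day_view((6 * 12 + 3 + 1):250)
  expect_equal(awakeningTime(dv2, .t("2012-06-01 06:30:00")), -15)
  # all-rest day is invalid
  expect_true(is.na(awakeningTime(day_view(integer()), .t("2012-06-01 06:30:00"))))
})

test_that("rest onset uses the end of the last active bin", {
  # last active bin 20:00-20:05, sunset 20:00 -> +5
  dv <- day_view(100:(20 * 12 + 1))
  expect_equal(restOnset(dv, .t("2012-06-01 20:00:00")), 5)
  # last active bin ends 19:30, sunset 20:00 -> -30
  dv2 <- day_view(100:(19.5 * 12))
  expect_equal(restOnset(dv2, .t("2012-06-01 20:00:00")), -30)
  expect_true(is.na(restOnset(day_view(integer()), .t("2012-06-01 20:00:00"))))
})

test_that("rest duration spans the previous onset to the current awakening", {
  expect_equal(restDuration(.t("2012-06-01 19:58:00"), .t("2012-06-02 08:00:00")),
               12 + 2 / 60, tolerance = 1e-12)
  expect_equal(restDuration(.t("2012-06-01 20:00:00"), .t("2012-06-02 08:00:00")),
               12)
  expect_warning(out <- restDuration(.t("2012-06-02 08:00:00"),
                                     .t("2012-06-01 20:00:00")),
                 "invalid")
  expect_true(is.na(out))
})

test_that("trait table matches the generator truth when fed the true states", {
  truth <- populationTruth(nFish = 3L, nDays = 5L,
                           config = list(distanceMode = "gaussian"))
  ds <- generateDataset(truth, seed = 31)
  seqs <- lapply(unique(ds@trueStates$fish_id), function(id)
    true_state_sequence(ds@trueStates, id))
  tab <- buildTraitTable(seqs, ds@sunTable)
  tt <- ds@trueTraits
  key <- paste(tab$fish_id, tab$date)
  tkey <- paste(tt$fish_id, tt$date)
  m <- match(key, tkey)
  # snapped truth is recovered exactly
  expect_equal(tab$awakening_min, tt$awakening_snap_min[m], tolerance = 1e-9)
  expect_equal(tab$onset_min, tt$onset_snap_min[m], tolerance = 1e-9)
  # and continuous truth to within the bin width
  expect_true(all(abs(tab$awakening_min - tt$awakening_min[m]) <= 5 + 1e-9))
  expect_true(all(abs(tab$onset_min - tt$onset_min[m]) <= 5 + 1e-9))
  # first tracked day has no previous onset
  firstDay <- tab$date == min(tab$date)
  expect_true(all(is.na(tab$rest_dur_h[firstDay])))
  expect_true(all(!is.na(tab$rest_dur_h[!firstDay])))
  # rest duration equals its absolute-clock identity on every valid row
  for (i in which(!is.na(tab$rest_dur_h))) {
    j <- which(tab$fish_id == tab$fish_id[i] & tab$date == tab$date[i] - 1)
    sunPrev <- ds@sunTable[match(tab$date[j], ds@sunTable$date), ]
    sunCur <- ds@sunTable[match(tab$date[i], ds@sunTable$date), ]
    lhs <- tab$rest_dur_h[i]
    rhs <- as.numeric((sunCur$sunrise + tab$awakening_min[i] * 60) -
                      (sunPrev$sunset + tab$onset_min[j] * 60),
                      units = "hours")
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("trait table boundary contracts hold", {
  expect_equal(nrow(buildTraitTable(list(), data.frame())), 0L)
  truth <- populationTruth(nFish = 2L, nDays = 2L,
                           config = list(distanceMode = "gaussian"))
  ds <- generateDataset(truth, seed = 3)
  seqs <- lapply(unique(ds@trueStates$fish_id), function(id)
    true_state_sequence(ds@trueStates, id))
  tracks <- data.frame(fish_id = "someoneelse", date = as.Date("2012-06-01"),
                       dist_m = 1)
  expect_error(buildTraitTable(seqs, ds@sunTable, tracks),
               "fish sets differ")
})

test_that("the default study scale yields one row per fish-day", {
  truth <- populationTruth(config = list(distanceMode = "gaussian"))
  ds <- generateDataset(truth, seed = 17)
  expect_equal(truth@nFish, 14L)
  expect_equal(truth@nDays, 14L)
  seqs <- lapply(unique(ds@trueStates$fish_id), function(id)
    true_state_sequence(ds@trueStates, id))
  tab <- buildTraitTable(seqs, ds@sunTable)
  expect_equal(nrow(tab), 14L * 14L)
  summ <- traitSummary(tab)
  expect_true(all(is.finite(summ$mean[summ$trait != "dist_m"])))
})

test_that("the minimum-bout filter removes isolated active bins when enabled", {
  dv <- day_view(c(100, 150:170))
  ss <- new("StateSequence", fishId = "a", binStart = dv$bin_start,
            binMinutes = 5, state = dv$state,
            postActive = as.numeric(dv$state == "active"))
  sun <- data.frame(date = as.Date("2012-06-01"),
                    sunrise = .t("2012-06-01 06:30:00"),
                    sunset = .t("2012-06-01 20:00:00"))
  t1 <- buildTraitTable(ss, sun)                 # kept as decoded
  t2 <- buildTraitTable(ss, sun, minBout = 3L)   # isolated bin dropped
  expect_lt(t1$awakening_min, t2$awakening_min)
})
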