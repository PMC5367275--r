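biv_mcmc <- list(nitt = 13000L, burnin = 3000L, thin = 10L)

# Balanced two-trait dataset with known covariance structure, simulated
# directly (independent of the package generator).
sim_biv_data <- function(nFish, nDays, Vind1, Vind2, rInd, Ve1, Ve2, rE,
                         seed = 1) {
  set.seed(seed)
  Si <- matrix(c(Vind1, rInd * sqrt(Vind1 * Vind2),
                 rInd * sqrt(Vind1 * Vind2), Vind2), 2, 2)
  Se <- matrix(c(Ve1, rE * sqrt(Ve1 * Ve2), rE * sqrt(Ve1 * Ve2), Ve2), 2, 2)
  fish <- sprintf("f%03d", seq_len(nFish))
  U <- MASS::mvrnorm(nFish, c(0, 0), Si)
  E <- MASS::mvrnorm(nFish * nDays, c(0, 0), Se)
  traits <- data.frame(
    fish_id = rep(fish, each = nDays),
    date = rep(as.Date("2012-06-01") + seq_len(nDays) - 1, nFish),
    awakening_min = 100 + rep(U[, 1], each = nDays) + E[, 1],
    onset_min = 5 + rep(U[, 2], each = nDays) + E[, 2])
  meta <- data.frame(fish_id = fish, length = 150,
                     sex = rep(c("F", "M"), length.out = nFish),
                     year = rep(c("2011", "2012"), length.out = nFish),
                     tag_date = as.Date("2012-05-29"),
                     centre_easting = runif(nFish, 465000, 467000),
                     centre_northing = runif(nFish, 4358000, 4360000))
  list(traits = traits, meta = meta)
}

test_that("correlation summaries are exact on constructed draws", {
  draws <- new("BivariateDraws", traits = c("a", "b"),
               B = matrix(0, 3, 2), U1 = matrix(0, 3, 1),
               U2 = matrix(0, 3, 1),
               SigmaInd = matrix(rep(c(1, 1, 0.5), each = 3), 3, 3),
               SigmaE = matrix(rep(c(2, 2, 0), each = 3), 3, 3),
               deviance = rep(0, 3), terms = "(Intercept)", fishIds = "f",
               mcmc = list(), constrained = "none", data = list())
  cd <- correlationDecomposition(draws)
  expect_equal(cd@rInd[1], 0.5)
  expect_equal(cd@rE[1], 0)
  # r_P from the summed covariance: 0.5 / sqrt(3 * 3)
  expect_equal(cd@rP[1], 0.5 / 3, tolerance = 1e-12)
})

test_that("r_P decomposes exactly into the weighted r_ind and r_e identity", {
  d <- sim_biv_data(15, 10, 100, 50, 0.4, 100, 80, -0.3, seed = 2)
  fit <- fitBivariate(c("awakening_min", "onset_min"), d$traits, d$meta,
                      mcmc = biv_mcmc, seed = 3)
  Si <- fit@SigmaInd; Se <- fit@SigmaE
  rInd <- Si[, 3] / sqrt(Si[, 1] * Si[, 2])
  rE <- Se[, 3] / sqrt(Se[, 1] * Se[, 2])
  rP <- (Si[, 3] + Se[, 3]) / sqrt((Si[, 1] + Se[, 1]) * (Si[, 2] + Se[, 2]))
  R1 <- Si[, 1] / (Si[, 1] + Se[, 1])
  R2 <- Si[, 2] / (Si[, 2] + Se[, 2])
  expect_equal(rP, rInd * sqrt(R1 * R2) + rE * sqrt((1 - R1) * (1 - R2)),
               tolerance = 1e-12)
})

test_that("the sampler recovers simulated between-individual correlation", {
  d <- sim_biv_data(40, 20, 100, 60, 0.6, 120, 90, 0.1, seed = 5)
  fit <- fitBivariate(c("awakening_min", "onset_min"), d$traits, d$meta,
                      mcmc = biv_mcmc, seed = 6)
  cd <- correlationDecomposition(fit)
  expect_lt(abs(cd@rInd[1] - 0.6), 0.15)
  expect_lt(abs(cd@rE[1] - 0.1), 0.05)
})

test_that("independent traits give credible intervals covering zero", {
  covers <- sapply(1:5, function(s) {
    d <- sim_biv_data(20, 12, 80, 80, 0, 100, 100, 0, seed = 300 + s)
    fit <- fitBivariate(c("awakening_min", "onset_min"), d$traits, d$meta,
                        mcmc = biv_mcmc, seed = s)
    cd <- correlationDecomposition(fit)
    c(cd@rInd[2] < 0 & cd@rInd[3] > 0, cd@rE[2] < 0 & cd@rE[3] > 0)
  })
  expect_gte(sum(covers[1, ]), 4L)
  expect_gte(sum(covers[2, ]), 4L)
})

test_that("constrained fits are diagonal and positive definite in every draw", {
  d <- sim_biv_data(10, 8, 50, 50, 0.5, 60, 60, -0.4, seed = 9)
  for (con in c("ind", "e")) {
    fit <- fitBivariate(c("awakening_min", "onset_min"), d$traits, d$meta,
                        mcmc = biv_mcmc, constrain = con, seed = 11)
    S <- if (con == "ind") fit@SigmaInd else fit@SigmaE
    expect_true(all(S[, 3] == 0))
    expect_true(all(S[, 1] > 0 & S[, 2] > 0))
    expect_true(validObject(fit))
  }
})

test_that("sampling is deterministic given the seed and needs 3 fish", {
  d <- sim_biv_data(6, 6, 50, 50, 0.2, 60, 60, 0, seed = 13)
  f1 <- fitBivariate(c("awakening_min", "onset_min"), d$traits, d$meta,
                     mcmc = biv_mcmc, seed = 21)
  f2 <- fitBivariate(c("awakening_min", "onset_min"), d$traits, d$meta,
                     mcmc = biv_mcmc, seed = 21)
  expect_identical(f1@SigmaInd, f2@SigmaInd)
  d2 <- d
  d2$traits <- d2$traits[d2$traits$fish_id %in% c("f001", "f002"), ]
  d2$meta <- d2$meta[1:2, ]
  expect_error(fitBivariate(c("awakening_min", "onset_min"), d2$traits,
                            d2$meta, mcmc = biv_mcmc), "at least 3 fish")
})

test_that("with vanishing between-individual variance r_P approaches r_e", {
  d <- sim_biv_data(25, 20, 0.01, 0.01, 0, 100, 100, -0.5, seed = 31)
  fit <- fitBivariate(c("awakening_min", "onset_min"), d$traits, d$meta,
                      mcmc = biv_mcmc, seed = 32)
  cd <- correlationDecomposition(fit)
  expect_lt(abs(cd@rP[1] - cd@rE[1]), 0.05)
})

test_that("delta-DIC flags a strong residual correlation and not a null one", {
  d <- sim_biv_data(15, 14, 60, 60, 0, 100, 100, -0.6, seed = 41)
  cd <- significanceDIC(c("awakening_min", "onset_min"), d$traits, d$meta,
                        mcmc = biv_mcmc, seed = 42)
  expect_true(cd@sigE)
  expect_equal(cd@deltaDICE > 2, cd@sigE)
})
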