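fast_mcmc <- list(nitt = 6000L, burnin = 1000L, thin = 5L)

test_that("model specs enforce term hierarchy", {
  expect_error(lmmSpec("awakening_min", c("sex:year")), "both main effects")
  expect_error(lmmSpec("awakening_min", "habitat"), "unknown term")
  s <- lmmSpec("dist_m", c("lat", "year", "lat:year"), transform = "log")
  expect_s3_class(s, "LMMSpec")
})

test_that("per-fish intercepts match exact conjugate shrinkage", {
  d <- sim_lmm_data(8, 12, Vind = 50, Ve = 30, mu = 5, seed = 21)
  fit <- fitLMM(lmmSpec("awakening_min", character()), d$traits, d$meta,
                mcmc = list(nitt = 42000L, burnin = 2000L, thin = 10L),
                prior = list(nu = 2e8, V = 1), seed = 2)
  # with nu enormous and V = 1 both variances are pinned at ~1
  expect_equal(mean(fit@Ve), 1, tolerance = 0.01)
  expect_equal(mean(fit@Vind), 1, tolerance = 0.01)
  # exact linear-Gaussian posterior of (beta, u) at the pinned variances
  y <- fit@data$y
  q <- length(fit@fishIds)
  Z <- outer(fit@data$fish, 0:(q - 1), "==") * 1
  W <- cbind(1, Z)
  prec <- crossprod(W) / 1 + diag(c(1e-10, rep(1, q)))
  Vpost <- solve(prec)
  mpost <- as.numeric(Vpost %*% crossprod(W, y))
  for (j in seq_len(q)) {
    expect_equal(mean(fit@u[, j]), mpost[j + 1], tolerance = 0.06)
    expect_equal(sd(fit@u[, j]), sqrt(Vpost[j + 1, j + 1]), tolerance = 0.08)
  }
  expect_equal(mean(fit@beta[, 1]), mpost[1], tolerance = 0.06)
})

test_that("posterior repeatability recovers the simulated truth", {
  d <- sim_lmm_data(30, 20, Vind = 400, Ve = 600, mu = 100, seed = 31)
  fit <- fitLMM(lmmSpec("awakening_min", character()), d$traits, d$meta,
                seed = 7)
  rr <- adjustedR(fit)
  expect_gt(rr@RMean, 0.3)
  expect_lt(rr@RMean, 0.5)
  # agree with the method-of-moments oracle
  mom <- mom_decomp(d$traits$awakening_min, d$traits$fish_id)
  expect_lt(abs(mean(fit@Vind) - mom["Vind"]) / mom["Vind"], 0.15)
  expect_lt(abs(mean(fit@Ve) - mom["Ve"]) / mom["Ve"], 0.15)
})

test_that("posterior variance components agree with REML (lme4 cross-check)", {
  skip_if_not_installed("lme4")
  d <- sim_lmm_data(40, 25, Vind = 300, Ve = 500, mu = 50, seed = 41)
  fit <- fitLMM(lmmSpec("awakening_min", character()), d$traits, d$meta,
                seed = 3)
  lf <- lme4::lmer(awakening_min ~ 1 + (1 | fish_id), data = d$traits)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_lt(abs(mean(fit@Vind) - vc$vcov[1]) / vc$vcov[1], 0.15)
  expect_lt(abs(mean(fit@Ve) - vc$vcov[2]) / vc$vcov[2], 0.15)
})

test_that("sampling is deterministic given the seed", {
  d <- sim_lmm_data(6, 8, Vind = 100, Ve = 100, seed = 5)
  f1 <- fitLMM(lmmSpec("awakening_min", c("year")), d$traits, d$meta,
               fast_mcmc, seed = 77)
  f2 <- fitLMM(lmmSpec("awakening_min", c("year")), d$traits, d$meta,
               fast_mcmc, seed = 77)
  expect_identical(f1@Vind, f2@Vind)
  expect_identical(f1@beta, f2@beta)
})

test_that("repeatability is invariant to shifting the coordinates", {
  d <- sim_lmm_data(10, 10, Vind = 200, Ve = 200, seed = 6)
  f1 <- fitLMM(lmmSpec("awakening_min", c("lat", "lon")), d$traits, d$meta,
               fast_mcmc, seed = 9)
  meta2 <- d$meta
  meta2$centre_easting <- meta2$centre_easting + 5000
  meta2$centre_northing <- meta2$centre_northing + 12345
  f2 <- fitLMM(lmmSpec("awakening_min", c("lat", "lon")), d$traits, meta2,
               fast_mcmc, seed = 9)
  expect_identical(f1@Vind, f2@Vind)  # mean-centring absorbs the shift
})

test_that("adjusted R reproduces hand-checkable values", {
  mk <- function(Vind, Ve) new("PosteriorDraws",
    beta = matrix(0, length(Ve), 1, dimnames = list(NULL, "(Intercept)")),
    u = matrix(0, length(Ve), 1), Vind = Vind, Ve = Ve,
    deviance = rep(0, length(Ve)), response = "x", transform = "identity",
    terms = "(Intercept)", fishIds = "f1", mcmc = list(), rhat = NA_real_,
    data = list())
  # posterior-mean variance components of the published awakening model
  expect_equal(round(adjustedR(mk(2138.63, 3230.68))@RMean, 2), 0.40)
  expect_equal(adjustedR(mk(c(0, 0), c(1, 2)))@RMean, 0)
  expect_equal(adjustedR(mk(c(3, 5), c(3, 5)))@RMean, 0.5)
})

test_that("DIC is the plug-in deviance for a degenerate posterior", {
  set.seed(8)
  y <- rnorm(12); fish <- rep(0:2, each = 4)
  X <- matrix(1, 12, 1, dimnames = list(NULL, "(Intercept)"))
  dev1 <- -2 * sum(dnorm(y, 0.3 + c(0.1, -0.2, 0)[fish + 1], sqrt(2),
                         log = TRUE))
  draws <- new("PosteriorDraws",
    beta = matrix(0.3, 3, 1, dimnames = list(NULL, "(Intercept)")),
    u = matrix(rep(c(0.1, -0.2, 0), each = 3), 3, 3),
    Vind = rep(1, 3), Ve = rep(2, 3), deviance = rep(dev1, 3),
    response = "x", transform = "identity", terms = "(Intercept)",
    fishIds = c("a", "b", "c"), mcmc = list(), rhat = NA_real_,
    data = list(X = X, y = y, fish = fish))
  dic <- dicLMM(draws)
  expect_equal(attr(dic, "pD"), 0, tolerance = 1e-10)
  expect_equal(as.numeric(dic), dev1, tolerance = 1e-10)
})

test_that("a pure-noise fixed effect increases the DIC", {
  deltas <- sapply(1:7, function(s) {
    d <- sim_lmm_data(12, 10, Vind = 100, Ve = 100, seed = 100 + s)
    f0 <- fitLMM(lmmSpec("awakening_min", character()), d$traits, d$meta,
                 fast_mcmc, seed = s)
    f1 <- fitLMM(lmmSpec("awakening_min", "lat"), d$traits, d$meta,
                 fast_mcmc, seed = s)  # lat is pure noise here
    as.numeric(dicLMM(f1)) - as.numeric(dicLMM(f0))
  })
  expect_gt(median(deltas), 0)
})

test_that("delta DIC follows the constrained-minus-unconstrained convention", {
  d <- sim_lmm_data(20, 15, Vind = 400, Ve = 100, seed = 55)
  fit <- fitLMM(lmmSpec("awakening_min", character()), d$traits, d$meta,
                fast_mcmc, seed = 1)
  cons <- constrainedFit(lmmSpec("awakening_min", character()), d$traits,
                         d$meta, fast_mcmc, seed = 2)
  expect_true(all(cons@Vind == 0))
  rr <- adjustedR(fit, cons)
  expect_equal(rr@deltaDIC, rr@DICc - rr@DIC)
  expect_true(rr@significant)  # strong simulated repeatability
})

test_that("stepwise reduction keeps the real effect and respects hierarchy", {
  yearKept <- 0L
  for (s in 1:5) {
    d <- sim_lmm_data(16, 12, Vind = 100, Ve = 100, seed = 200 + s,
                      betaYear = 30)
    red <- stepwiseReduce(lmmSpec("awakening_min"), d$traits, d$meta,
                          fast_mcmc, seed = s)
    if ("year" %in% red$spec$fixed) yearKept <- yearKept + 1L
    # hierarchy: a retained interaction implies both mains retained
    for (tm in grep(":", red$spec$fixed, value = TRUE))
      expect_true(all(strsplit(tm, ":")[[1]] %in% red$spec$fixed))
    # every accepted move lowered the DIC
    expect_true(all(diff(red$trace$dic) < 0))
  }
  expect_gte(yearKept, 4L)
})

test_that("stepwise returns the full model when no move improves the DIC", {
  d <- sim_lmm_data(10, 8, Vind = 400, Ve = 50, seed = 71, betaYear = 100)
  red <- stepwiseReduce(lmmSpec("awakening_min", "year"), d$traits, d$meta,
                        fast_mcmc, seed = 2)
  # the only candidate moves from {year} are dropping it or adding mains;
  # with a huge year effect the drop is never taken
  expect_true("year" %in% red$spec$fixed)
})

test_that("Durbin-Watson hand computations are exact", {
  expect_equal(dwStatistic(c(1, 1, 1, 1)), 0)
  expect_equal(dwStatistic(c(1, -1, 1, -1)), 3)  # 12 / 4
  # differences never span fish boundaries
  expect_equal(dwStatistic(c(1, 1, 1, 1), c(1, 1, 2, 2)), 0)
  expect_equal(dwStatistic(c(1, -1, 1, -1), c(1, 1, 2, 2)), 2)
})

test_that("Durbin-Watson is centred near 2 for independent residuals", {
  set.seed(99)
  dws <- replicate(20, dwStatistic(rnorm(500), rep(1:10, each = 50)))
  expect_lt(abs(mean(dws) - 2), 0.1)
})

test_that("the fitted-model Durbin-Watson check runs and is one-sided", {
  d <- sim_lmm_data(8, 12, Vind = 100, Ve = 100, seed = 77)
  fit <- fitLMM(lmmSpec("awakening_min", character()), d$traits, d$meta,
                fast_mcmc, seed = 3)
  dw <- durbinWatson(fit, nPerm = 300, seed = 4)
  expect_true(dw$statistic > 0 && dw$statistic < 4)
  expect_true(dw$p_value > 0 && dw$p_value <= 1)
  expect_match(dw$alternative, "> 0")
})

test_that("collinearity screening flags and classifies correctly", {
  set.seed(12)
  n <- 60
  meta <- data.frame(length = rnorm(n, 150, 10), sex = rep(c("F", "M"), n / 2),
                     year = factor(rep("2012", n)),
                     centre_easting = rnorm(n), centre_northing = rnorm(n))
  meta$length <- meta$length + 30 * (meta$sex == "M")   # strong sex-length link
  meta$centre_easting <- meta$centre_northing * 2       # perfectly collinear
  # base R warns about the perfect fit; the screen handles it gracefully
  rep_ <- suppressWarnings(screenCollinearity(meta))
  row_ls <- rep_[rep_$var1 == "length" & rep_$var2 == "sex", ]
  expect_equal(row_ls$test, "anova-F")
  expect_true(row_ls$flag)
  row_en <- rep_[rep_$var1 == "centre_easting" & rep_$var2 == "centre_northing", ]
  expect_true(row_en$flag)   # infinite t handled gracefully
  row_y <- rep_[rep_$var2 == "year" | rep_$var1 == "year", ][1, ]
  expect_equal(row_y$test, "not testable")
})

test_that("collinearity screening holds its nominal false-flag rate", {
  set.seed(13)
  n <- 200
  meta <- as.data.frame(matrix(rnorm(n * 20), n, 20))
  names(meta) <- paste0("v", 1:20)
  rep_ <- screenCollinearity(meta, covariates = names(meta))
  expect_equal(nrow(rep_), choose(20, 2))
  rate <- mean(rep_$flag)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})
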