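exp_series <- function(mu = 0.6, x0 = 1e4, tt = c(0, 2, 4, 6), reps = 1,
                       species = "a") {
  do.call(rbind, lapply(seq_len(reps), function(r) {
    data.frame(species = species, time_h = tt, replicate = r,
               count = x0 * exp(mu * tt))
  }))
}

test_that("mu_max is exact on clean exponentials", {
  est <- muMax(exp_series(mu = 0.6))
  expect_equal(est$muMax, 0.6, tolerance = 1e-12)
  expect_equal(est$rSquared, 1, tolerance = 1e-12)
  expect_false(est$noGrowth)
  expect_equal(unname(est$perReplicate[1]), 0.6, tolerance = 1e-12)
})

test_that("a constant series is flagged as no growth", {
  d <- data.frame(species = "a", time_h = 0:5, replicate = 1, count = 1e6)
  est <- muMax(d)
  expect_true(est$noGrowth)
  expect_equal(est$muMax, 0)
})

test_that("the window scan finds the exponential phase of a curve", {
  # lag, exponential, stationary
  tt <- 0:12
  x <- c(rep(1e4, 3), 1e4 * exp(0.5 * (3:8 - 3)), rep(1e4 * exp(2.5), 4))
  d <- data.frame(species = "a", time_h = tt, replicate = 1, count = x)
  est <- muMax(d)
  expect_equal(est$muMax, 0.5, tolerance = 1e-9)
  expect_true(est$window[1] >= 3 && est$window[2] <= 8)
})

test_that("windowed mu_max recovers the planted rate under noise", {
  # triplicate counts every 2 h through the exponential phase, CV 0.1
  mu <- 0.6
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    tt <- seq(0, 8, 2)
    cv <- 0.1
    sdlog <- sqrt(log(1 + cv^2))
    d <- do.call(rbind, lapply(1:3, function(r) {
      data.frame(species = "a", time_h = tt, replicate = r,
                 count = 1e4 * exp(mu * tt) *
                   rlnorm(length(tt), -sdlog^2 / 2, sdlog))
    }))
    muMax(d, minPoints = 4)$muMax
  }, numeric(1))
  expect_true(all(abs(errs / mu - 1) < 0.10))
})

test_that("mu_max and fold increase are scale invariant", {
  d <- exp_series(mu = 0.4, tt = seq(0, 48, 8))
  d2 <- d
  d2$count <- d2$count * 1e3
  expect_equal(muMax(d2)$muMax, muMax(d)$muMax, tolerance = 1e-12)
  expect_equal(foldIncrease(d2), foldIncrease(d), tolerance = 1e-12)
})

test_that("fold increase is the endpoint mean ratio", {
  d <- data.frame(species = "a", time_h = rep(c(0, 48), each = 2),
                  replicate = rep(1:2, 2),
                  count = c(1e7, 1e7, 1e9, 1e9))
  expect_equal(foldIncrease(d), 100)
  d1 <- data.frame(species = "a", time_h = c(0, 48), replicate = 1,
                   count = c(5e6, 5e6))
  expect_equal(foldIncrease(d1), 1)
})

test_that("fold increase matches exp(integral mu dt) on exact curves", {
  # exponential at 0.3/h for 10 h, then flat to 48 h
  tt <- c(0, 5, 10, 24, 48)
  x <- 1e5 * exp(0.3 * pmin(tt, 10))
  d <- data.frame(species = "a", time_h = tt, replicate = 1, count = x)
  expect_equal(foldIncrease(d), exp(0.3 * 10), tolerance = 1e-12)
})

test_that("relative abundances average per replicate and sum to one", {
  d <- expand.grid(species = c("a", "b", "c"), replicate = 1:3)
  d$time_h <- 24
  d$count <- c(8, 1, 1, 6, 3, 1, 8, 1, 1)
  ra <- relativeAbundance(d, 24)
  expect_equal(sum(ra$fraction), 1, tolerance = 1e-12)
  expect_equal(ra$fraction[ra$species == "a"], mean(c(0.8, 0.6, 0.8)),
               tolerance = 1e-12)
  expect_true(all(ra$se >= 0))
  # single species: 100%
  d1 <- data.frame(species = "a", time_h = 0, replicate = 1, count = 42)
  expect_equal(relativeAbundance(d1, 0)$fraction, 1)
})

test_that("the stabilised ratio maps to the published percentages", {
  d <- data.frame(species = c("GM17", "YR343", "AP49"), time_h = 48,
                  replicate = 1, count = c(1.0, 0.126, 0.013))
  ra <- relativeAbundance(d, 48)
  pct <- round(100 * ra$fraction[match(c("GM17", "YR343", "AP49"),
                                       ra$species)], 2)
  expect_equal(pct, c(87.80, 11.06, 1.14))
})

test_that("null-model productivity flags net negative interactions", {
  mono <- matrix(c(10, 11, 9, 4, 5, 4.5, 2, 2.2, 1.8), 3, 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), NULL))
  even <- nullModelProductivity(mono, communityYield = colMeans(mono) * 3 / 3)
  expect_equal(even$ratio, 1, tolerance = 1e-12)
  low <- nullModelProductivity(mono, communityYield = c(3, 3.2, 2.9))
  expect_lt(low$ratio, 1)
  expect_true(low$netNegative)
  expect_true(low$pValue < 0.05)
  w <- nullModelProductivity(mono, communityYield = c(9, 10, 9.5),
                             initialFractions = c(a = 1, b = 0, c = 0))
  expect_equal(w$expected, 10, tolerance = 1e-12)
})

test_that("competing dFBA species underperform the null model", {
  # two species competing for one shared substrate with a rate-yield
  # trade-off: the fast, wasteful strain wins the pool, so the realised
  # community yield falls below the null (weighted monoculture) model
  fast <- speciesConfig(chain_model(yield = 0.03), limitingUptakeRate = 10,
                        initialBiomass = 1e-5)
  slow_model <- chain_model(yield = 0.09)
  slow_model@speciesId <- "slow"
  slow <- speciesConfig(slow_model, limitingUptakeRate = 2,
                        initialBiomass = 1e-5)
  cfg <- list(fast = fast, slow = slow)
  fresh <- mediumState(c(glc_e = 0.05), limitingIds = "glc_e",
                       volumeML = 10)
  tr <- transferSpec(cycleHours = 48, nPassages = 1, timestep = 0.1)
  mono_yield <- vapply(names(cfg), function(s) {
    sum(biomass(finalState(runSerialTransfer(cfg[s], tr, fresh)[[1]])))
  }, numeric(1))
  co_yield <- sum(biomass(finalState(
    runSerialTransfer(cfg, tr, fresh)[[1]])))
  cmp <- nullModelProductivity(matrix(mono_yield, ncol = 1,
                                      dimnames = list(names(cfg), NULL)),
                               communityYield = co_yield)
  expect_lt(cmp$ratio, 1)
  expect_true(cmp$netNegative)
})
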