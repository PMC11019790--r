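stable_competition <- function(seed) {
  set.seed(seed)
  n <- 3
  K <- 10^runif(1, 7, 9)
  A <- matrix(-runif(n * n, 0.02, 0.15) / K, n, n)
  diag(A) <- -runif(n, 0.3, 0.6) / K
  r <- runif(n, 0.2, 0.6)
  glvParams(r, A, paste0("sp", 1:n))
}

glv_series <- function(params, x0s, span = 12, npts = 20) {
  do.call(rbind, lapply(seq_along(x0s), function(k) {
    tr <- simulateGLV(params, x0s[[k]], seq(0, span, length.out = npts))
    do.call(rbind, lapply(params@speciesIds, function(s) {
      data.frame(species = s, time_h = tr$time, replicate = 1,
                 passage = k, count = tr[[s]])
    }))
  }))
}

test_that("a single self-limited species follows the logistic closed form", {
  r <- 0.5
  K <- 1e8
  p <- glvParams(r = c(a = r), A = matrix(-r / K, 1, 1))
  x0 <- 1e5
  tt <- seq(0, 48, 0.5)
  sim <- simulateGLV(p, c(a = x0), tt)
  closed <- K * x0 * exp(r * tt) / (K + x0 * (exp(r * tt) - 1))
  expect_equal(sim$a, closed, tolerance = 1e-6)
})

test_that("zero interactions give pure exponential growth", {
  p <- glvParams(r = c(a = 0.3, b = 0.1), A = matrix(0, 2, 2))
  tt <- seq(0, 10, 1)
  sim <- simulateGLV(p, c(a = 1e3, b = 1e4), tt)
  expect_equal(sim$a, 1e3 * exp(0.3 * tt), tolerance = 1e-7)
  expect_equal(sim$b, 1e4 * exp(0.1 * tt), tolerance = 1e-7)
})

test_that("stable three-species systems settle at -A^{-1} r", {
  p <- stable_competition(11)
  xeq <- solve(-p@A, p@r)
  sim <- simulateGLV(p, xeq * c(0.5, 2, 0.8), seq(0, 500, 10))
  expect_equal(unlist(sim[nrow(sim), -1], use.names = FALSE),
               unname(xeq), tolerance = 1e-5)
})

test_that("unbounded systems abort with a finite-time diagnostic", {
  p <- glvParams(r = c(a = 1), A = matrix(0, 1, 1))
  expect_error(simulateGLV(p, c(a = 1e6), seq(0, 100, 1),
                           blowupLimit = 1e6), "blew up")
  expect_error(simulateGLV(p, c(a = -1), 0:5), "positive")
})

test_that("noiseless multi-inoculum data recover r and A within 5%", {
  p <- stable_competition(7)
  K <- -1 / max(diag(p@A))
  x0s <- list(c(1, 1, 1) * K / 100, c(50, 1, 1) * K / 100,
              c(1, 60, 2) * K / 100, c(2, 1, 40) * K / 100)
  fit <- fitGLV(glv_series(p, x0s), ridgePenalty = 0)
  expect_equal(unname(fit@r), unname(p@r), tolerance = 0.05)
  expect_true(all(abs(fit@A / p@A - 1) < 0.05))
})

test_that("single-species logistic data yield negative self-limitation", {
  p <- glvParams(r = c(a = 0.5), A = matrix(-0.5 / 1e8, 1, 1))
  tr <- simulateGLV(p, c(a = 1e6), seq(0, 20, 1))
  ser <- data.frame(species = "a", time_h = tr$time, replicate = 1,
                    count = tr$a)
  fit <- fitGLV(ser, ridgePenalty = 0)
  expect_lt(fit@A[1, 1], 0)
})

test_that("fits are invariant to abundance-unit rescaling", {
  p <- stable_competition(3)
  K <- -1 / max(diag(p@A))
  x0s <- list(c(1, 2, 1) * K / 100, c(30, 1, 2) * K / 100,
              c(1, 40, 1) * K / 100, c(3, 1, 50) * K / 100)
  ser <- glv_series(p, x0s)
  fit1 <- fitGLV(ser, ridgePenalty = 1e-3)
  ser2 <- ser
  ser2$count <- ser2$count * 1000
  fit2 <- fitGLV(ser2, ridgePenalty = 1e-3)
  expect_equal(fit2@r, fit1@r, tolerance = 1e-6)
  expect_equal(fit2@A * 1000, fit1@A, tolerance = 1e-6)
  expect_identical(sign(fit2@A), sign(fit1@A))
})

test_that("underdetermined fits demand regularisation", {
  p <- stable_competition(5)
  tr <- simulateGLV(p, rep(1e6, 3), seq(0, 2, 1))  # one interior point
  ser <- do.call(rbind, lapply(p@speciesIds, function(s) {
    data.frame(species = s, time_h = tr$time, replicate = 1, count = tr[[s]])
  }))
  expect_error(fitGLV(ser, ridgePenalty = 0), "ridge")
  expect_s4_class(fitGLV(ser, ridgePenalty = 1e-3), "GLVParams")
})

test_that("interaction signs classify and pool correctly", {
  A <- matrix(c(-1, -0.2, -0.3,
                -0.1, -1, -0.4,
                 0.2,  0.3, -1), 3, 3, byrow = TRUE)
  p <- glvParams(c(0.1, 0.1, 0.1), A, c("a", "b", "c"))
  s <- interactionSigns(p)
  expect_equal(unname(fractionNegative(s)), 4 / 6)
  expect_equal(s@signs["a", "b"], "-")
  expect_equal(s@signs["c", "a"], "+")
  all_neg <- glvParams(c(0.1, 0.1), matrix(-1, 2, 2), c("a", "b"))
  expect_equal(unname(fractionNegative(interactionSigns(all_neg))), 1.0)
  # all couplings under threshold: flagged, no fraction
  null_p <- glvParams(c(0.1, 0.1), diag(c(-1, -1)), c("a", "b"))
  s0 <- interactionSigns(null_p, threshold = 10)
  expect_true(s0@allBelowThreshold)
  expect_true(is.na(fractionNegative(s0)))
})

test_that("sign recovery holds across 20 random stable systems", {
  for (seed in 1:20) {
    p <- stable_competition(seed + 40)
    K <- -1 / max(diag(p@A))
    x0s <- list(c(1, 1, 1) * K / 100, c(30, 1, 1) * K / 100,
                c(1, 30, 1) * K / 100, c(1, 1, 30) * K / 100)
    fit <- fitGLV(glv_series(p, x0s), ridgePenalty = 0)
    thr <- 1e-6 * max(abs(fit@A))
    strong <- abs(p@A) > 10 * thr
    expect_identical(sign(fit@A)[strong], sign(p@A)[strong],
                     info = paste("seed", seed + 40))
  }
})

test_that("planted negative fractions survive the full pipeline, pooled", {
  # 8 synthetic inoculum-ratio datasets from systems with a known mixture
  # of negative and positive couplings
  fits <- list()
  n_neg_planted <- 0
  n_off <- 0
  for (k in 1:8) {
    set.seed(900 + k)
    K <- 1e8
    A <- matrix(-runif(9, 0.05, 0.15) / K, 3, 3)
    diag(A) <- -runif(3, 0.4, 0.6) / K
    # flip a random off-diagonal pair positive in half the datasets
    if (k %% 2 == 0) {
      A[1, 2] <- abs(A[1, 2])
      A[3, 2] <- abs(A[3, 2])
    }
    p <- glvParams(runif(3, 0.2, 0.5), A, c("a", "b", "c"))
    x0s <- list(c(1, 1, 1) * 1e6, c(30, 1, 1) * 1e6,
                c(1, 30, 1) * 1e6, c(1, 1, 30) * 1e6)
    fits[[k]] <- fitGLV(glv_series(p, x0s), ridgePenalty = 0)
    off <- row(A) != col(A)
    n_neg_planted <- n_neg_planted + sum(A[off] < 0)
    n_off <- n_off + sum(off)
  }
  pooled <- interactionSigns(fits)
  expect_equal(pooled@nNonzero, n_off)
  expect_equal(unname(fractionNegative(pooled)), n_neg_planted / n_off)
})
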