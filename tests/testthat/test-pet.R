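test_that("input function assembly interpolates whole blood and applies the mean ratio", {
  # constant whole blood, unit ratios
  s <- data.frame(time_min = c(1, 10, 40), wholeblood = rep(10, 3),
                  plasma = rep(10, 3))
  aif <- assembleInputFunction(s, seq(0.25, 45, 0.5))
  expect_true(all(abs(plasmaActivity(aif) - 10) < 1e-12))
  expect_true(!is.unsorted(plasmaIntegral(aif)))

  # linear interpolation: midpoint of (0, 0) and (10, 20) is 10
  s2 <- data.frame(time_min = c(0, 10), wholeblood = c(0, 20),
                   plasma = c(0, 20))
  aif2 <- assembleInputFunction(s2, c(2.5, 5, 7.5))
  expect_equal(plasmaActivity(aif2), c(5, 10, 15))

  # ratios {1.1, 0.9} average to 1.0: cp equals interpolated whole blood
  s3 <- data.frame(time_min = c(2, 8), wholeblood = c(10, 20),
                   plasma = c(11, 18))  # ratios 1.1 and 0.9
  aif3 <- assembleInputFunction(s3, c(2, 5, 8))
  expect_equal(plasmaActivity(aif3), c(10, 15, 20))

  expect_error(assembleInputFunction(s3[1, ], 1:10), "at least 2")
  bad <- data.frame(time_min = c(5, 2), wholeblood = c(1, 1),
                    plasma = c(1, 1))
  expect_error(assembleInputFunction(bad, 1:10), "increasing")
})

test_that("baseline regressor averages included gray matter voxels", {
  arr <- array(0, c(4, 4, 2, 5))
  vals <- seq_len(prod(4, 4, 2))
  for (f in 1:5) arr[, , , f] <- array(vals * f, c(4, 4, 2))
  pet <- FrameSeries(arr, tr = 30)
  gm <- array(TRUE, c(4, 4, 2))

  # exclusion empty: plain mean over gray matter
  expect_equal(buildBaselineRegressor(pet, gm), mean(vals) * (1:5))

  # checkerboard exclusion equals brute-force mean over the rest
  excl <- array(rep(c(TRUE, FALSE), length.out = 32), c(4, 4, 2))
  reg <- buildBaselineRegressor(pet, gm, excl)
  expect_equal(reg, sapply(1:5, function(f) mean(arr[, , , f][!excl])))

  # uniform image: regressor constant at that value
  petU <- FrameSeries(array(7, c(4, 4, 2, 5)), tr = 30)
  expect_equal(buildBaselineRegressor(petU, gm), rep(7, 5))

  expect_error(buildBaselineRegressor(pet, gm, gm), "no voxels")
})

test_that("fPET GLM separates baseline from task ramps", {
  n <- 104
  tt <- 0.5 * (seq_len(n) - 0.5)
  baseline <- 20 + 2 * tt          # any non-constant baseline course
  des <- fpetDesign(tt, baseline, petTaskBlocks())

  # ramps are piecewise linear, non-decreasing, non-constant
  expect_true(all(diff(des$X[, "easy"]) >= 0))
  expect_true(all(diff(des$X[, "hard"]) >= 0))
  expect_gt(stats::sd(des$X[, "easy"]), 0)

  # TAC = 2 x baseline: baseline beta 2, task betas 0
  fit <- fitFpetGlm(matrix(2 * baseline, ncol = 1), des)
  expect_equal(unname(fit$beta["baseline", 1]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$taskBeta[, 1]), c(0, 0), tolerance = 1e-8)

  # known ramp amplitudes recovered within 2% noise-free
  tac <- 1.5 * baseline + 0.3 * des$X[, "easy"] + 0.7 * des$X[, "hard"]
  fit2 <- fitFpetGlm(matrix(tac, ncol = 1), des)
  expect_equal(unname(fit2$taskBeta["easy", 1]), 0.3, tolerance = 0.02)
  expect_equal(unname(fit2$taskBeta["hard", 1]), 0.7, tolerance = 0.02)

  # constant-zero TAC: all betas 0
  fit3 <- fitFpetGlm(matrix(0, n, 1), des)
  expect_true(all(abs(fit3$beta) < 1e-12))

  # rank-deficient design rejected
  desBad <- des
  desBad$X <- cbind(des$X, dup = des$X[, "easy"])
  expect_error(fitFpetGlm(matrix(tac, ncol = 1), desBad), "rank")
})

test_that("low-pass moving average leaves constants unchanged", {
  expect_equal(lowpassTac(rep(3.5, 50)), rep(3.5, 50))
  y <- sin(seq(0, 10, length.out = 100))
  expect_lt(stats::sd(lowpassTac(y, 20)), stats::sd(y))
})

test_that("Patlak analysis recovers slope and intercept on exact lines", {
  aif <- constantAif()
  tac <- 0.02 * plasmaIntegral(aif) + 0.05 * plasmaActivity(aif)
  fit <- patlakKi(tac, aif)
  expect_equal(fit$ki, 0.02, tolerance = 1e-10)
  expect_equal(fit$v0, 0.05, tolerance = 1e-10)

  fit0 <- patlakKi(rep(0, length(plasmaActivity(aif))), aif)
  expect_equal(fit0$ki, 0, tolerance = 1e-12)
  expect_equal(fit0$v0, 0, tolerance = 1e-12)

  # matrix input matches per-column fits
  tacs <- cbind(tac, 2 * tac)
  fitM <- patlakKi(tacs, aif)
  expect_equal(fitM$ki, c(0.02, 0.04), tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(patlakKi(tac, aif, tStarMin = 51), "fewer than 3")
})

test_that("Patlak slope approximates the 2-tissue irreversible influx", {
  # oracle: integrate the 2TC-irreversible model dC1 = K1 Cp - (k2+k3) C1,
  # dC2 = k3 C1; tissue = C1 + C2. Expected Ki = K1 k3 / (k2 + k3).
  K1 <- 0.1; k2 <- 0.15; k3 <- 0.05
  aif <- constantAif(cp0 = 30)
  cpFun <- stats::approxfun(c(0, aif@frameTimesMin),
                            c(aif@cp[1], aif@cp), rule = 2)
  rhs <- function(t, y, p) {
    list(c(K1 * cpFun(t) - (k2 + k3) * y[1], k3 * y[1]))
  }
  sol <- deSolve::ode(c(0, 0), c(0, aif@frameTimesMin), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  tissue <- rowSums(sol[-1, 2:3])
  fit <- patlakKi(tissue, aif, tStarMin = 15)
  expect_equal(fit$ki, K1 * k3 / (k2 + k3), tolerance = 0.05)
})

test_that("CMRGlu conversion follows the influx equation and is bilinear", {
  expect_equal(cmrgluFromKi(0, 5.45), 0)
  expect_equal(cmrgluFromKi(1, 1, lc = 1), 100)
  expect_equal(cmrgluFromKi(0.0178, 5.45), 0.0178 * 5.45 / 0.89 * 100,
               tolerance = 1e-12)
  expect_equal(cmrgluFromKi(0.0178, 5.45), 10.9, tolerance = 0.01)
  # linear in both arguments
  ki <- runif(5)
  expect_equal(cmrgluFromKi(2 * ki, 5.45), 2 * cmrgluFromKi(ki, 5.45))
  expect_equal(cmrgluFromKi(ki, 2 * 5.45), 2 * cmrgluFromKi(ki, 5.45))
  expect_error(cmrgluFromKi(0.02, 5.45, lc = 0), "positive")
})

test_that("condition-specific influx adds the ramp-rate contribution", {
  aif <- constantAif(cp0 = 40)
  taskFrames <- 30:60
  # beta of 0.2 kBq/ml per 0.5-min frame over cp 40 adds 0.2/(0.5*40)
  expect_equal(conditionKi(0.02, 0.2, aif, taskFrames, frameLenMin = 0.5),
               0.02 + 0.2 / (0.5 * 40))
  expect_equal(conditionKi(0.02, 0, aif, taskFrames), 0.02)
})
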