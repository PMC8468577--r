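test_that("the release window is a closed 20-60 interval with original order", {
  p <- DissolutionProfile(1:5 * 10, c(10, 25, 40, 55, 70))
  w <- releaseWindow(p)
  expect_equal(profileReleased(w), c(25, 40, 55))
  pb <- DissolutionProfile(1:4 * 10, c(15, 20, 60, 75))
  expect_equal(profileReleased(releaseWindow(pb)), c(20, 60))
  below <- DissolutionProfile(1:5 * 10, c(1, 3, 6, 10, 15))
  expect_true(inherits(releaseWindow(below), "emptyWindow"))
})

test_that("fewer than 4 window points yields an exclusion, not an error", {
  p3 <- DissolutionProfile(1:5 * 10, c(10, 25, 40, 55, 70))
  exH <- fitHiguchi(p3)
  expect_true(isExcluded(exH))
  expect_match(exH$reason, "3 data points")
  expect_true(isExcluded(fitKorsmeyerPeppas(p3)))
  below <- DissolutionProfile(1:5 * 10, c(1, 3, 6, 10, 15))
  expect_true(isExcluded(fitHiguchi(below)))
})

test_that("exact model data are recovered perfectly", {
  t <- seq(10, 700, 10)
  hg <- fitHiguchi(DissolutionProfile(t, 2.5 * sqrt(t)))
  expect_equal(hg@slope, 2.5, tolerance = 1e-10)
  expect_equal(hg@intercept, 0, tolerance = 1e-8)
  expect_equal(hg@adjR2, 1, tolerance = 1e-10)
  kp <- fitKorsmeyerPeppas(DissolutionProfile(t, 5 * t^0.45))
  expect_equal(kp@slope, 0.45, tolerance = 1e-10)
  expect_equal(kp@intercept, log10(5), tolerance = 1e-10)
  expect_equal(kp@r2, 1, tolerance = 1e-10)
  # square-root data seen through the power-law lens: n = 1/2
  kp2 <- fitKorsmeyerPeppas(DissolutionProfile(t, 2.5 * sqrt(t)))
  expect_equal(kp2@slope, 0.5, tolerance = 1e-10)
})

test_that("the power-law exponent is invariant to the time unit", {
  t <- seq(10, 700, 10)
  q <- 4 * t^0.62
  kpMin <- fitKorsmeyerPeppas(DissolutionProfile(t, q))
  kpHr <- fitKorsmeyerPeppas(DissolutionProfile(t / 60, q))
  expect_equal(kpMin@slope, kpHr@slope, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(kpMin@intercept, kpHr@intercept)))
})

test_that("noisy power-law profiles recover the exponent on average", {
  nFit <- numeric(30)
  for (i in 1:30) {
    p <- synthProfile("power_law", k = 5, n = 0.45, noiseSd = 0.5,
                      seed = 100 + i)
    nFit[i] <- fitKorsmeyerPeppas(p)@slope
  }
  expect_lt(abs(mean(nFit) - 0.45), 0.02)
})

test_that("experimental-plot coefficients are consistent with minutes/percent units", {
  # a Higuchi line with slope ~1.79 %/sqrt(min) and intercept ~1.09 %
  # predicts ~49 % released at 12 h; the magnitude confirms the unit
  # convention used throughout (internal consistency, not a reproduction)
  q720 <- 1.7869 * sqrt(720) + 1.0926
  expect_gt(q720, 45)
  expect_lt(q720, 53)
})

test_that("mechanism classification brackets the release exponent", {
  expect_equal(classifyMechanism(0.45), "fickian")
  expect_equal(classifyMechanism(0.46), "fickian")   # within tol of 0.45
  expect_equal(classifyMechanism(0.48, tol = 0.03), "fickian")
  expect_equal(classifyMechanism(0.75), "anomalous")
  expect_equal(classifyMechanism(0.60), "anomalous")
  expect_equal(classifyMechanism(1.0), "case_ii")
  expect_equal(classifyMechanism(0.89), "case_ii")
  expect_equal(classifyMechanism(0.5, tol = 0.1), "fickian")
})

test_that("adjusted R^2 follows the simple-regression closed form", {
  fit <- new("KineticFit", model = "higuchi", slope = 1, intercept = 0,
             r2 = 0, adjR2 = NA_real_, nPoints = 10L, rss = 1,
             x = as.numeric(1:10), y = as.numeric(1:10))
  expect_equal(adjustedR2(fit), -1 / 8, tolerance = 1e-12)
  set.seed(81)
  for (i in 1:10) {
    x <- sqrt(seq(30, 330, 30))
    y <- 2 + 1.5 * x + rnorm(length(x), 0, 0.8)
    f <- voxdiss:::.olsFit("higuchi", x, y)
    expect_equal(f@adjR2, summary(lm(y ~ x))$adj.r.squared,
                 tolerance = 1e-10)
    expect_equal(f@r2, summary(lm(y ~ x))$r.squared, tolerance = 1e-10)
  }
})

test_that("a fit compared with itself gives t = 0, p = 1", {
  set.seed(82)
  t <- seq(30, 330, 30)
  p <- DissolutionProfile(t, 2 + 2.2 * sqrt(t) + rnorm(length(t), 0, 0.4))
  fit <- fitHiguchi(p, lo = 0, hi = 100)
  cmp <- compareRegressions(fit, fit)
  expect_equal(cmp@tSlope, 0)
  expect_equal(cmp@pSlope, 1)
  expect_equal(cmp@pIntercept, 1)
  expect_equal(cmp@dfSlope, 2L * fit@nPoints - 4L)
})

test_that("clearly different slopes reject and suppress the intercept test", {
  set.seed(83)
  x <- sqrt(seq(30, 330, 30))
  mk <- function(b) voxdiss:::.olsFit(
    "higuchi", x, 1 + b * x + rnorm(length(x), 0, 0.2))
  fA <- mk(1.0); fB <- mk(3.0)
  cmp <- compareRegressions(fA, fB)
  expect_lt(cmp@pSlope, 0.05)
  expect_true(is.na(cmp@tIntercept))
  expect_true(is.na(cmp@pIntercept))
})

test_that("the slope test has power against a 5-sigma slope shift", {
  set.seed(84)
  x <- sqrt(seq(30, 330, 30))
  n <- length(x)
  sdRes <- 0.5
  seSlope <- sdRes * sqrt(2 / sum((x - mean(x))^2))  # SE of b1 - b2
  shift <- 5 * seSlope
  rejections <- 0L
  reps <- 200
  for (i in seq_len(reps)) {
    fA <- voxdiss:::.olsFit("higuchi", x,
                            1 + 2 * x + rnorm(n, 0, sdRes))
    fB <- voxdiss:::.olsFit("higuchi", x,
                            1 + (2 + shift) * x + rnorm(n, 0, sdRes))
    if (compareRegressions(fA, fB)@pSlope < 0.05)
      rejections <- rejections + 1L
  }
  expect_gt(rejections / reps, 0.9)
})

test_that("degenerate regressors are rejected", {
  expect_error(voxdiss:::.olsFit("higuchi", rep(2, 5), 1:5),
               "degenerate")
  p <- DissolutionProfile(c(5, 10), c(30, 40))
  expect_true(isExcluded(fitHiguchi(p)))   # too few, not degenerate
})

test_that("nonpositive window values break the log-log fit loudly", {
  # released == 0 inside a widened window
  p <- DissolutionProfile(1:6 * 10, c(0, 25, 30, 40, 50, 55))
  expect_error(fitKorsmeyerPeppas(p, lo = 0, hi = 60), "positive")
})
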