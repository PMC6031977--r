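# a fit whose value and trend at chosen dates are known analytically:
# rising sine crosses its mean going up at x = 0, falls at x = 0.5
risingAt <- function(level, amp = 0.1) {
  x <- (0:23) / 12
  fitTrigonometric(x, level + amp * sin(2 * pi * x))
}

test_that("the threshold-plus-trend rule table matches its specification", {
  up <- risingAt(0.30)
  expect_equal(warningLevel(classifyWarning(up, at = 0)), "ELEVATED")
  expect_equal(warningLevel(classifyWarning(up, at = 0.5)), "REDUCED")
  low <- risingAt(0.20)
  expect_equal(warningLevel(classifyWarning(low, at = 0.5)), "UNLIKELY")
  expect_equal(warningLevel(classifyWarning(low, at = 0)), "REDUCED")
})

test_that("boundary conventions: 0.28 counts as reached, 1e7 as a bloom", {
  atThreshold <- risingAt(0.28)
  wa <- classifyWarning(atThreshold, at = 0, threshold = 0.28)
  expect_equal(warningLevel(wa), "ELEVATED")
  expect_equal(wa@trendSign, 1)
  model <- new("MixedModelReport", response = "c_total",
               fixedEffects = data.frame(), randomInterceptSd = 0,
               residSd = 0, nObs = 10L, nGroups = 2L,
               transformApplied = c(fv_fm_bc = FALSE),
               singularFallback = FALSE,
               predictor = function(v) 1e7 + 0 * v, lagDays = 40)
  out <- predictBloom(model, 0.3)
  expect_true(out$bloomForecast)
  model@predictor <- function(v) 1.5e7 + 0 * v
  expect_true(predictBloom(model, 0.3)$bloomForecast)
  model@predictor <- function(v) 0 * v
  expect_false(predictBloom(model, 0.3)$bloomForecast)
  model@predictor <- NULL
  expect_error(predictBloom(model, 0.3), "predictor")
})

test_that("the rule is monotone in value and trend", {
  levels <- c(UNLIKELY = 1, REDUCED = 2, ELEVATED = 3)
  for (value in seq(0.1, 0.5, by = 0.05)) {
    upFit <- risingAt(value)
    lvlUp <- levels[warningLevel(classifyWarning(upFit, 0))]
    lvlDown <- levels[warningLevel(classifyWarning(upFit, 0.5))]
    expect_gte(lvlUp, lvlDown)   # flipping trend + to - never raises
  }
  for (at in c(0, 0.5)) {
    got <- sapply(seq(0.1, 0.5, by = 0.05),
                  function(v) levels[warningLevel(classifyWarning(risingAt(v), at))])
    expect_true(all(diff(got) >= 0))  # raising value never lowers the level
  }
})

test_that("peak forecasting is analytic and adds the estimated lead", {
  x <- (0:23) / 12
  pure <- fitTrigonometric(x, sin(2 * pi * x))
  fp <- forecastPeak(pure, lag = 40)
  # analytic peak of sin(2*pi*x) nearest the window start is x = 0.25
  expect_equal(fp$peakX %% 1, 0.25, tolerance = 1e-6)
  expect_equal(fp$forecastX - fp$peakX, 40 / 365, tolerance = 1e-9)
  # grid-search oracle: maximum over a daily grid within 1 day
  grid <- seq(0, 23 / 12, by = 1 / 365)
  oracle <- grid[which.max(evaluateFit(pure, grid))]
  expect_lte(abs(fp$peakX - oracle) * 365, 1)
  # uncertainty window from the across-site SD travels through
  est <- new("LagEstimate", perSiteLags = c(S1 = 38, S2 = 42), meanLag = 40,
             sdLag = 5, ci95 = c(33, 47), bestCorr = 0.9, gridDays = 1,
             maxLagDays = 183, seriesNames = c("fv_fm_bc", "c_total"))
  fp2 <- forecastPeak(pure, est)
  expect_equal(fp2$windowDays, 5)
  expect_equal(fp2$forecastX - fp2$peakX, 40 / 365, tolerance = 1e-9)
  flat <- fitTrigonometric(x, 0.3 + 0.01 * x)
  expect_error(forecastPeak(flat, 40), "amplitude")
})

test_that("peak forecast in calendar dates: peak day 180 + 40-day lead", {
  dates <- seq(as.Date("2014-01-01"), by = "month", length.out = 24)
  # phase chosen so the curve peaks 180 days after the origin
  phi <- pi / 2 - 2 * pi * 180 / 365
  x <- (0:23) / 12
  fit <- fitTrigonometric(dates, 0.3 + 0.1 * sin(2 * pi * x + phi))
  est <- new("LagEstimate", perSiteLags = c(a = 40), meanLag = 40, sdLag = 5,
             ci95 = c(NA_real_, NA_real_), bestCorr = 1, gridDays = 1,
             maxLagDays = 183, seriesNames = c("a", "b"))
  fp <- forecastPeak(fit, est)
  expect_equal(as.numeric(fp$forecastDate - as.Date("2014-01-01")), 220,
               tolerance = 1)
  expect_equal(fp$windowDays, 5)
})

test_that("assessBloomRisk composes rule, forecast and prediction", {
  x <- (0:23) / 12
  dates <- seq(as.Date("2013-06-01"), by = "month", length.out = 24)
  fit <- fitTrigonometric(dates, 0.28 + 0.1 * sin(2 * pi * x))
  model <- new("MixedModelReport", response = "c_total",
               fixedEffects = data.frame(), randomInterceptSd = 0,
               residSd = 0, nObs = 10L, nGroups = 2L,
               transformApplied = c(fv_fm_bc = FALSE),
               singularFallback = FALSE,
               predictor = function(v) 4e7 * v, lagDays = 40)
  wa <- assessBloomRisk(fit, at = dates[2], lag = 40, densityModel = model)
  expect_s4_class(wa, "WarningAssessment")
  expect_false(is.na(wa@forecastPeakDate))
  expect_equal(wa@predictedDensity, 4e7 * wa@fvFmNow, tolerance = 1e-9)
  expect_identical(wa@bloomForecast, wa@predictedDensity >= 1e7)
  expect_true(length(wa@ruleTrace) >= 4)
})
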