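test_that("driver model recovers a known sqrt-temperature slope", {
  rec <- makeDriverRecords(slope = 2, siteSd = 0.5, seed = 2)
  rep <- fitDriverModel(rec, "chl_a", "water_temp")
  fe <- fixedEffects(rep)
  slope <- fe[fe$term == "water_temp", ]
  expect_lte(abs(slope$estimate - 2), 3 * slope$se)
  expect_lt(slope$p, 0.001)
  expect_identical(rep@nObs, 168L)
  expect_identical(rep@nGroups, 7L)
  expect_gt(rep@randomInterceptSd, 0)
  expect_true(rep@transformApplied[["water_temp"]])
})

test_that("null predictors are not flagged: calibration over replicates", {
  hits <- 0L
  for (i in 1:40) {
    rec <- makeDriverRecords(slope = 0, siteSd = 0.3, seed = 100 + i)
    rep <- suppressWarnings(fitDriverModel(rec, "chl_a", "water_temp"))
    fe <- fixedEffects(rep)
    slope <- fe[fe$term == "water_temp", ]
    if (abs(slope$estimate) > 3 * slope$se) hits <- hits + 1L
  }
  expect_lte(hits, 2L)   # |estimate| < 3 SE in at least 95% of replicates
})

test_that("zero site variance falls back to OLS and matches it to 1e-6", {
  rec <- makeDriverRecords(slope = 1.5, siteSd = 0, seed = 3)
  expect_warning(rep <- fitDriverModel(rec, "chl_a", "water_temp"),
                 "singular")
  expect_true(rep@singularFallback)
  expect_equal(rep@randomInterceptSd, 0)
  ols <- lm(chl_a ~ sqrt(water_temp), data = rec)
  fe <- fixedEffects(rep)
  expect_equal(fe$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("negative values under the sqrt transform name the variable", {
  rec <- makeDriverRecords(seed = 4)
  rec$water_temp[5] <- -2
  expect_error(fitDriverModel(rec, "chl_a", "water_temp"), "water_temp")
  # opting out of the transform accepts the same data
  expect_s4_class(suppressWarnings(
    fitDriverModel(rec, "chl_a", "water_temp", sqrtTransform = FALSE)),
    "MixedModelReport")
})

test_that("density model recovers the lagged fluorescence slope", {
  set.seed(6)
  cf <- erhaiSeasonalCoefficients()
  dates <- seq(as.Date("2013-06-01"), by = "month", length.out = 24)
  x <- (0:23) / 12
  b <- cf["fv_fm_bc", ]
  rec <- do.call(rbind, lapply(1:7, function(i) {
    fv <- b[1] + b[3] * sin(2 * pi * x) + b[4] * cos(2 * pi * x)
    fvLag <- b[1] + b[3] * sin(2 * pi * (x - 40 / 365)) +
      b[4] * cos(2 * pi * (x - 40 / 365))
    data.frame(site_id = sprintf("S%d", i), date = dates,
               fv_fm_bc = pmin(pmax(fv + rnorm(24, 0, 0.01), 0), 1),
               c_total = 1e6 + 4e7 * fvLag + rnorm(1, 0, 5e5) +
                 rnorm(24, 0, 1e6))
  }))
  rec$c_total <- pmax(rec$c_total, 0)
  rep <- fitCfparDensityModel(rec, "c_total", "fv_fm_bc", lagDays = 40,
                              logResponse = FALSE)
  fe <- fixedEffects(rep)
  slope <- fe[fe$term == "cf_lagged", ]
  expect_lte(abs(slope$estimate - 4e7), 3 * slope$se)
  # trained predictor maps fluorescence to density on the response scale
  pred <- rep@predictor(0.35)
  expect_gt(pred, 0)
})

test_that("proportional series at zero lag give the smallest attainable p", {
  dates <- seq(as.Date("2013-06-01"), by = "month", length.out = 24)
  x <- (0:23) / 12
  fv <- 0.3 + 0.15 * sin(2 * pi * x)
  rec <- do.call(rbind, lapply(1:2, function(i)
    data.frame(site_id = c("A", "B")[i], date = dates, fv_fm_bc = fv,
               c_total = 2e7 * fv + i * 1e5)))
  rep <- suppressWarnings(
    fitCfparDensityModel(rec, "c_total", "fv_fm_bc", lagDays = 0,
                         logResponse = FALSE))
  fe <- fixedEffects(rep)
  expect_lt(fe$p[fe$term == "cf_lagged"], 1e-12)
})

test_that("a lag misspecified by half a period flips the slope sign", {
  dates <- seq(as.Date("2013-06-01"), by = "month", length.out = 24)
  x <- (0:23) / 12
  fv <- 0.3 + 0.15 * sin(2 * pi * x)
  dens <- 1e7 + 4e7 * (fv - 0.3)        # in phase at lag 0
  rec <- do.call(rbind, lapply(1:2, function(i)
    data.frame(site_id = c("A", "B")[i], date = dates, fv_fm_bc = fv,
               c_total = pmax(dens + i * 1e5, 0))))
  rep <- suppressWarnings(
    fitCfparDensityModel(rec, "c_total", "fv_fm_bc", lagDays = 182.5,
                         logResponse = FALSE))
  fe <- fixedEffects(rep)
  expect_lte(fe$estimate[fe$term == "cf_lagged"], 0)
})

test_that("impossible shifts and short windows error out", {
  rec <- makeDriverRecords(seed = 5)
  rec$fv_fm_bc <- 0.3
  rec$c_total <- 1e6
  expect_error(fitCfparDensityModel(rec, lagDays = -1), "lagDays")
  expect_error(suppressWarnings(
    fitCfparDensityModel(rec, lagDays = 10 * 365)), "window too short")
})
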