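test_that("default design yields 168 records with valid composition", {
  rec <- generateDataset(syntheticConfig())
  expect_identical(nrow(rec), 168L)
  expect_identical(length(unique(rec$site_id)), 7L)
  expect_identical(length(unique(rec$date)), 24L)
  ok <- !is.na(rec$c_total)
  expect_true(all(rec$c_microcystis[ok] <= rec$c_cyano[ok] + 1e-9))
  expect_true(all(rec$c_cyano[ok] <= rec$c_total[ok] + 1e-9))
  expect_true(all(rec$c_total >= 0))
  yields <- unlist(rec[, c("fv_fm_tc", "fv_fm_bc", "df_fm_tc", "df_fm_bc")])
  expect_true(all(yields >= 0 & yields <= 1))
})

test_that("dataset-wide composition reproduces the configured shares", {
  rec <- generateDataset(syntheticConfig(seed = 99L))
  expect_equal(mean(rec$c_cyano / rec$c_total), 0.5, tolerance = 0.05)
  expect_equal(mean(rec$c_microcystis / rec$c_cyano), 0.78, tolerance = 0.05)
})

test_that("the generator is a deterministic function of its seed", {
  a <- generateDataset(syntheticConfig(seed = 5L))
  b <- generateDataset(syntheticConfig(seed = 5L))
  c <- generateDataset(syntheticConfig(seed = 6L))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$c_total, c$c_total)))
})

test_that("noise-free generation refits to the generating coefficients", {
  cfg <- syntheticConfig(noiseCv = 0, siteEffectSd = c(water_temp = 0),
                         seed = 1L)
  rec <- generateDataset(cfg)
  pooled <- monthlySiteMean(rec)
  for (v in c("fv_fm_tc", "fv_fm_bc", "df_fm_tc", "df_fm_bc")) {
    fit <- fitTrigonometric(pooled$date, pooled[[v]], response = v)
    truth <- cfg@coeffs[v, ]
    expect_lt(max(abs(coef(fit) - truth)), 1e-8)
  }
})

test_that("with default noise, refits recover seasonal amplitude within 2 SE", {
  cfg <- syntheticConfig(seed = 31L)
  rec <- generateDataset(cfg)
  pooled <- monthlySiteMean(rec)
  for (v in c("fv_fm_bc", "df_fm_bc")) {
    fit <- fitTrigonometric(pooled$date, pooled[[v]], response = v)
    expect_lte(abs(coef(fit)[["beta2"]] - cfg@coeffs[v, "beta2"]),
               2 * fit@se[3], label = v)
  }
})

test_that("end to end: the pipeline recovers the injected lead from records", {
  cfg <- syntheticConfig(leadDays = 40, seed = 12L)
  rec <- generateDataset(cfg)
  sites <- unique(rec$site_id)
  fitsA <- lapply(sites, function(s) {
    sub <- rec[rec$site_id == s, ]
    fitTrigonometric(sub$date, sub$fv_fm_bc, response = "fv_fm_bc")
  })
  fitsB <- lapply(sites, function(s) {
    sub <- rec[rec$site_id == s, ]
    fitTrigonometric(sub$date, sub$c_total, response = "c_total")
  })
  names(fitsA) <- names(fitsB) <- sites
  est <- siteLagDistribution(fitsA, fitsB)
  expect_lte(abs(meanLag(est) - 40), max(sdLag(est), 2))
  expect_gt(est@bestCorr, 0.5)
})

test_that("paired generator injects the exact lead when noise-free", {
  cf <- erhaiSeasonalCoefficients()
  pair <- generateLaggedPair(cf["fv_fm_bc", ], cf["c_total", ], leadDays = 38,
                             noiseCv = 0, seed = 1)
  est <- pairLagEstimate(pair)
  expect_equal(meanLag(est), 38, tolerance = 1e-9)
  expect_equal(sdLag(est), 0)
  # reproducibility contract
  p2 <- generateLaggedPair(cf["fv_fm_bc", ], cf["c_total", ], leadDays = 38,
                           noiseCv = 0, seed = 1)
  expect_identical(pair, p2)
})

test_that("configuration validity guards the generator", {
  expect_error(syntheticConfig(nMonths = 6L), "nMonths")
  expect_error(syntheticConfig(composition = c(1.5, 0.7)), "composition")
  expect_error(syntheticConfig(noiseCv = -0.1), "noiseCv")
})
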