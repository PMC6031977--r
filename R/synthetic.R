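#' @include records.R seasonal.R lag.R
NULL

#' Published seasonal-fit coefficients for the monitored variables
#'
#' The reference harmonic coefficients (beta0, beta1, beta2, beta3; x in
#' fractional years) reported for the 24-month Lake Erhai campaign: the four
#' chlorophyll-fluorescence quantum yields (total and blue channel) and the
#' three cell densities (total phytoplankton, cyanobacteria, Microcystis, in
#' cells/L). These rows drive the noise-free round-trip checks and the
#' paired lag scenarios.
#'
#' @return numeric matrix, one row per variable, columns
#'   \code{beta0..beta3}.
#' @export
erhaiSeasonalCoefficients <- function() {
  m <- rbind(
    fv_fm_tc      = c(0.53,    0.00,      0.04,    -0.01),
    fv_fm_bc      = c(0.27,    0.00,      0.16,     0.04),
    df_fm_tc      = c(0.34,    0.00,      0.07,    -0.01),
    df_fm_bc      = c(0.15,    0.00,      0.16,     0.00),
    c_total       = c(22742,   770943,  9190585, -2975061),
    c_cyano       = c(1360317, 336873,  5917219, -2095533),
    c_microcystis = c(541413,  330612,  5211725, -2068081)
  )
  colnames(m) <- c("beta0", "beta1", "beta2", "beta3")
  m
}

#' Published lead times between Fv/Fm (BC) / dF/Fm' (BC) and the densities
#'
#' Mean +/- SD cross-correlation leads (days) of the blue-channel quantum
#' yields over the cell densities, as reported for the field campaign. Used
#' as injected truths in the recovery scenarios.
#'
#' @return data.frame with columns cfpar, density, lead_days, sd_days.
#' @export
erhaiLeadTimes <- function() {
  data.frame(
    cfpar   = c("fv_fm_bc", "fv_fm_bc", "fv_fm_bc",
                "df_fm_bc", "df_fm_bc", "df_fm_bc"),
    density = rep(c("c_total", "c_cyano", "c_microcystis"), 2L),
    lead_days = c(38.9, 37.8, 39.1, 0.2, 0.1, 0.5),
    sd_days   = c(5.3,  5.6,  5.5,  0.9, 0.6, 1.3),
    stringsAsFactors = FALSE
  )
}

# harmonic mean curve at fractional years x
.harmonicMean <- function(beta, x) {
  beta[1L] + beta[2L] * x + beta[3L] * sin(2 * pi * x) + beta[4L] * cos(2 * pi * x)
}

# seasonal phase (radians) of a coefficient row: s = A sin(2*pi*x + phi)
.seasonalPhase <- function(beta) atan2(beta[4L], beta[3L])
.seasonalAmplitude <- function(beta) sqrt(beta[3L]^2 + beta[4L]^2)

.defaultGeneratorCoeffs <- function() {
  ref <- erhaiSeasonalCoefficients()
  # density intercept lifted to the seasonal amplitude so generated cell
  # densities stay non-negative (the fitted field intercepts sit far below
  # the amplitude, which a count variable cannot realise)
  ct <- ref["c_total", ]
  ct[1L] <- .seasonalAmplitude(ct) * 1.05
  yields <- ref[c("fv_fm_tc", "fv_fm_bc", "df_fm_tc", "df_fm_bc"), ]
  # same adjustment for any yield whose reference curve dips below zero
  # (the blue-channel effective yield): a quantum yield cannot go negative
  for (i in seq_len(nrow(yields)))
    yields[i, 1L] <- max(yields[i, 1L], .seasonalAmplitude(yields[i, ]) + 0.005)
  rbind(
    water_temp          = c(18.0,  0,    7.0,  -3.0),
    light_attenuation_k = c(0.83,  0,    0.60, -0.25),
    chl_a               = c(13.33, 0,    9.0,  -4.0),
    yields,
    c_total             = ct
  )
}

#' Create a synthetic-dataset configuration
#'
#' Defaults emulate the published 7-site x 24-month monthly campaign:
#' quantum-yield coefficients straight from the reference seasonal fits,
#' realistic highland-lake physicochemistry (mean temperature 18 degC with
#' an annual swing to ~25.7, light attenuation around 0.83, chlorophyll a
#' around 13.3 ug/L), a 40-day injected lead of blue-channel Fv/Fm over the
#' densities, 10% observation noise, and the published composition
#' (cyanobacteria 50% of total density, Microcystis 78% of cyanobacteria).
#'
#' @param nSites,nMonths sampling design.
#' @param coeffs harmonic coefficient matrix (rows: variables, columns
#'   beta0..beta3); defaults described above.
#' @param leadDays injected lead of Fv/Fm (BC) over the density series.
#' @param noiseCv per-variable coefficient of variation (scalar recycled, or
#'   named vector overriding single variables).
#' @param siteEffectSd per-variable site-random-intercept SD (named vector;
#'   sensible defaults per variable).
#' @param composition cyanobacteria fraction of total density and
#'   Microcystis fraction of cyanobacteria.
#' @param startDate first month of the series.
#' @param seed integer seed.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nSites = 7L, nMonths = 24L, coeffs = NULL,
                            leadDays = 40, noiseCv = 0.1,
                            siteEffectSd = NULL,
                            composition = c(cyano = 0.5, microcystis = 0.78),
                            startDate = as.Date("2013-06-01"),
                            seed = 20130601L) {
  if (is.null(coeffs)) coeffs <- .defaultGeneratorCoeffs()
  vars <- rownames(coeffs)
  if (length(noiseCv) == 1L && is.null(names(noiseCv)))
    noiseCv <- stats::setNames(rep(noiseCv, length(vars)), vars)
  else {
    base <- stats::setNames(rep(0.1, length(vars)), vars)
    base[names(noiseCv)] <- noiseCv
    noiseCv <- base
  }
  if (is.null(siteEffectSd)) {
    siteEffectSd <- stats::setNames(numeric(length(vars)), vars)
    defaults <- c(water_temp = 0.3, light_attenuation_k = 0.05, chl_a = 1.5,
                  fv_fm_tc = 0.01, fv_fm_bc = 0.01, df_fm_tc = 0.01,
                  df_fm_bc = 0.01, c_total = 3e5)
    hit <- intersect(names(defaults), vars)
    siteEffectSd[hit] <- defaults[hit]
  } else {
    base <- stats::setNames(numeric(length(vars)), vars)
    base[names(siteEffectSd)] <- siteEffectSd
    siteEffectSd <- base
  }
  new("SyntheticConfig",
      nSites = as.integer(nSites), nMonths = as.integer(nMonths),
      coeffs = coeffs, leadDays = leadDays, noiseCv = noiseCv,
      siteEffectSd = siteEffectSd, composition = composition,
      startDate = as.Date(startDate), seed = as.integer(seed))
}

#' Generate a synthetic multi-site monthly monitoring dataset
#'
#' Emulates the monthly lake-monitoring design: for each site and month
#' every variable follows its harmonic mean structure at
#' \code{x = month / 12}, plus a per-site random intercept and observation
#' noise. The cell-density seasonal component is phase-delayed by
#' \code{leadDays / 365} years relative to the blue-channel Fv/Fm series
#' (the warning predictor), so the injected lead is exactly the configured
#' value; the linear trend is left unshifted. Noise is multiplicative
#' log-normal for strictly positive variables (densities, temperature,
#' attenuation, chlorophyll, nutrients) and additive Gaussian clipped to
#' [0, 1] for the quantum yields. Cyanobacteria and Microcystis densities
#' are built from the total by composition fractions (with small clamped
#' jitter), which enforces c_microcystis <= c_cyano <= c_total by
#' construction. Randomness is split deterministically into per-site
#' substreams (\code{seed + 1000 * site index}).
#'
#' @param config a [SyntheticConfig-class].
#' @return a validated data.frame of monitoring records
#'   (\code{nSites * nMonths} rows, canonical columns).
#' @seealso [syntheticConfig()], [generateLaggedPair()]
#' @export
generateDataset <- function(config = syntheticConfig()) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  cf <- config@coeffs
  vars <- rownames(cf)
  nM <- config@nMonths
  x <- (seq_len(nM) - 1L) / 12
  dates <- config@startDate
  dates <- seq(dates, by = "month", length.out = nM)
  phiRef <- .seasonalPhase(cf["fv_fm_bc", ])
  ell <- config@leadDays / 365
  lognoise <- function(mu, cv, n) {
    if (cv <= 0) return(mu)
    sdlog <- sqrt(log(1 + cv^2))
    mu * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  }
  nutrients <- c(tp = 0.035, tn = 0.65, dtp = 0.018, dip = 0.006,
                 no3 = 0.22, nh4 = 0.11, do = 7.4, cond = 265, secchi = 1.9)
  out <- vector("list", config@nSites)
  for (i in seq_len(config@nSites)) {
    set.seed(config@seed + 1000L * i)
    rec <- data.frame(site_id = sprintf("S%d", i), date = dates,
                      stringsAsFactors = FALSE)
    siteInt <- stats::rnorm(length(vars), 0, config@siteEffectSd[vars])
    names(siteInt) <- vars
    for (v in setdiff(vars, "c_total")) {
      mu <- .harmonicMean(cf[v, ], x) + siteInt[v]
      cv <- config@noiseCv[v]
      if (v %in% .yieldCols) {
        val <- mu + stats::rnorm(nM, 0, cv * cf[v, 1L])
        rec[[v]] <- pmin(pmax(val, 0), 1)
      } else {
        rec[[v]] <- lognoise(pmax(mu, 1e-6), cv, nM)
      }
    }
    bt <- cf["c_total", ]
    A <- .seasonalAmplitude(bt)
    muCt <- bt[1L] + bt[2L] * x + A * sin(2 * pi * x + phiRef - 2 * pi * ell)
    ct <- lognoise(pmax(muCt, 1e3), config@noiseCv["c_total"], nM) +
      pmax(siteInt["c_total"], -bt[1L] / 2)
    ct <- pmax(ct, 0)
    shareC <- pmin(pmax(stats::rnorm(nM, config@composition[1L], 0.05), 0), 1)
    shareM <- pmin(pmax(stats::rnorm(nM, config@composition[2L], 0.05), 0), 1)
    rec$c_total <- ct
    rec$c_cyano <- shareC * ct
    rec$c_microcystis <- shareM * rec$c_cyano
    rec$ph <- stats::rnorm(nM, 8.6, 0.15)
    for (nv in names(nutrients))
      rec[[nv]] <- lognoise(rep(nutrients[[nv]], nM), 0.1, nM)
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  res <- res[, intersect(recordColumns(), names(res))]
  validateRecords(res)
  res
}

#' Generate paired lagged harmonic series across sites
#'
#' Builds the scenario the lead-recovery checks use: for each site, a
#' predictor series from one harmonic coefficient row and a response series
#' whose seasonal phase trails the predictor by exactly \code{leadDays}
#' (amplitude and trend from the response row, phase tied to the
#' predictor's), sampled monthly with additive Gaussian noise of standard
#' deviation \code{noiseCv} times the RMS of each centred seasonal
#' component. One seed per site keeps the substreams independent and
#' reproducible.
#'
#' @param coefA,coefB harmonic coefficient rows (beta0..beta3) for the
#'   predictor and the response.
#' @param leadDays injected lead of the predictor over the response (days).
#' @param nSites,nMonths design.
#' @param noiseCv noise level as a fraction of each series' seasonal RMS.
#' @param siteSeeds integer vector of per-site seeds; defaults to
#'   \code{seed, seed + 1, ...}.
#' @param seed first site seed when \code{siteSeeds} is not given.
#' @param daysPerYear fixed year length.
#' @return data.frame with columns site_id, x (fractional years),
#'   predictor, response.
#' @export
generateLaggedPair <- function(coefA, coefB, leadDays, nSites = 7L,
                               nMonths = 24L, noiseCv = 0.1,
                               siteSeeds = NULL, seed = 1L,
                               daysPerYear = 365) {
  if (is.null(siteSeeds)) siteSeeds <- seed + seq_len(nSites) - 1L
  stopifnot(length(siteSeeds) == nSites)
  x <- (seq_len(nMonths) - 1L) / 12
  phiA <- .seasonalPhase(coefA)
  aA <- .seasonalAmplitude(coefA)
  aB <- .seasonalAmplitude(coefB)
  ell <- leadDays / daysPerYear
  muA <- coefA[1L] + coefA[2L] * x + aA * sin(2 * pi * x + phiA)
  muB <- coefB[1L] + coefB[2L] * x + aB * sin(2 * pi * x + phiA - 2 * pi * ell)
  out <- lapply(seq_len(nSites), function(i) {
    set.seed(siteSeeds[i])
    data.frame(site_id = sprintf("S%d", i), x = x,
               predictor = muA + stats::rnorm(nMonths, 0, noiseCv * aA / sqrt(2)),
               response  = muB + stats::rnorm(nMonths, 0, noiseCv * aB / sqrt(2)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Estimate the predictor-over-response lead from a paired-series table
#'
#' Runs the lag pipeline on [generateLaggedPair()] output (or any table with
#' site_id, x, predictor, response): fits the trigonometric regression to
#' both series per site, then estimates the across-site lead distribution by
#' daily-grid cross-correlation of the fitted curves.
#'
#' @param pair data.frame with columns site_id, x, predictor, response.
#' @param config an [AnalysisConfig-class].
#' @return a [LagEstimate-class] (positive mean: the predictor leads).
#' @export
pairLagEstimate <- function(pair, config = analysisConfig()) {
  stopifnot(all(c("site_id", "x", "predictor", "response") %in% names(pair)))
  sites <- unique(pair$site_id)
  fitsA <- lapply(sites, function(s) {
    sub <- pair[pair$site_id == s, ]
    fitTrigonometric(sub$x, sub$predictor, response = "predictor")
  })
  fitsB <- lapply(sites, function(s) {
    sub <- pair[pair$site_id == s, ]
    fitTrigonometric(sub$x, sub$response, response = "response")
  })
  names(fitsA) <- names(fitsB) <- sites
  siteLagDistribution(fitsA, fitsB, config = config)
}

#' Generate irradiance-depth profiles
#'
#' Beer-Lambert profiles I(z) = I_s exp(-k z) at the standard sampling
#' depths, with optional log-normal noise on the subsurface readings, for
#' exercising the attenuation estimators.
#'
#' @param kTrue true attenuation coefficient (1/m), > 0.
#' @param depths depths (m), surface first.
#' @param nProfiles number of profiles.
#' @param surface surface PAR (umol photons / m^2 / s).
#' @param noiseSd SD of the log-normal depth noise (log scale).
#' @param seed optional seed.
#' @return list of data.frames with columns depth, irradiance.
#' @export
generateIrradianceProfiles <- function(kTrue, depths = c(0, 0.5, 1, 1.5, 2),
                                       nProfiles = 1L, surface = 1500,
                                       noiseSd = 0, seed = NULL) {
  if (kTrue <= 0) stop("kTrue must be positive")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nProfiles), function(i) {
    irr <- surface * exp(-kTrue * depths)
    if (noiseSd > 0) {
      sub <- depths > 0
      irr[sub] <- irr[sub] * exp(stats::rnorm(sum(sub), 0, noiseSd))
    }
    data.frame(depth = depths, irradiance = irr)
  })
}
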