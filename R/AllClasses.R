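#' @import methods
NULL

setClassUnion("functionOrNULL", c("function", "NULL"))

#' Fitted trigonometric seasonal regression
#'
#' Holds the ordinary-least-squares fit of a monthly series to the harmonic
#' model \eqn{y = \beta_0 + \beta_1 x + \beta_2 \sin(2\pi x) + \beta_3
#' \cos(2\pi x) + \epsilon}, where \eqn{x} is time in fractional years since
#' \code{timeOrigin} (one harmonic, annual period). The slots mirror the
#' columns a seasonal-regression report table carries: the four coefficients
#' with standard errors and t-based p-values, adjusted R-squared, the overall
#' F statistic on (3, n - 4) degrees of freedom with its p-value, and the
#' residual standard deviation.
#'
#' @slot response name of the fitted variable (may be \code{NA}).
#' @slot coefficients named numeric, \code{beta0..beta3}.
#' @slot se,pvalues standard errors and p-values for the four coefficients.
#' @slot adjR2 adjusted R-squared.
#' @slot fStat overall F statistic.
#' @slot df numerator and denominator degrees of freedom, \code{c(3, n - 4)}.
#' @slot modelP p-value of the overall F test.
#' @slot residSd residual standard deviation (response units).
#' @slot timeOrigin calendar date mapped to x = 0 (\code{NA} when the fit was
#'   supplied numeric time directly).
#' @slot n number of non-missing points used.
#'
#' @seealso [fitTrigonometric()], [evaluateFit()], [fitDerivative()]
#' @export
setClass("SeasonalFit",
  representation(
    response     = "character",
    coefficients = "numeric",
    se           = "numeric",
    pvalues      = "numeric",
    adjR2        = "numeric",
    fStat        = "numeric",
    df           = "numeric",
    modelP       = "numeric",
    residSd      = "numeric",
    timeOrigin   = "Date",
    n            = "integer"
  )
)

setValidity("SeasonalFit", function(object) {
  msg <- character()
  if (length(object@coefficients) != 4L)
    msg <- c(msg, "coefficients must have length 4 (beta0..beta3)")
  if (length(object@se) != 4L || length(object@pvalues) != 4L)
    msg <- c(msg, "se and pvalues must have length 4")
  if (length(object@df) != 2L || object@df[1L] != 3)
    msg <- c(msg, "df must be c(3, n - 4)")
  if (!is.na(object@n) && object@df[2L] != object@n - 4L)
    msg <- c(msg, "denominator df must equal n - 4")
  if (!is.na(object@adjR2) && object@adjR2 > 1 + 1e-12)
    msg <- c(msg, "adjusted R-squared cannot exceed 1")
  if (!is.na(object@residSd) && object@residSd < 0)
    msg <- c(msg, "residual SD must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Cross-correlation lead/lag estimate between two fitted seasonal curves
#'
#' Per-site lags in days (positive values mean the first series leads the
#' second), summarised across sites by mean, standard deviation and a
#' normal-approximation 95% confidence interval. \code{bestCorr} is the mean
#' across sites of the Pearson correlation between the gridded curves at the
#' (rounded) mean lag.
#'
#' @slot perSiteLags named numeric vector of per-site lags (days).
#' @slot meanLag,sdLag across-site mean and SD of the lag (days); \code{sdLag}
#'   is \code{NA} with fewer than two sites.
#' @slot ci95 normal-approximation 95% CI for the mean lag, \code{c(low, high)}.
#' @slot bestCorr mean Pearson correlation at the mean lag.
#' @slot gridDays,maxLagDays grid resolution and search half-window (days).
#' @slot seriesNames names of the two series, first one leading when positive.
#'
#' @seealso [crossCorrelationLag()], [siteLagDistribution()]
#' @export
setClass("LagEstimate",
  representation(
    perSiteLags = "numeric",
    meanLag     = "numeric",
    sdLag       = "numeric",
    ci95        = "numeric",
    bestCorr    = "numeric",
    gridDays    = "numeric",
    maxLagDays  = "numeric",
    seriesNames = "character"
  )
)

setValidity("LagEstimate", function(object) {
  msg <- character()
  if (any(abs(object@perSiteLags) > object@maxLagDays + 1e-9, na.rm = TRUE))
    msg <- c(msg, "per-site lags must lie within the configured maximum lag")
  if (!is.na(object@bestCorr) && abs(object@bestCorr) > 1 + 1e-12)
    msg <- c(msg, "bestCorr must lie in [-1, 1]")
  if (!is.na(object@sdLag) && object@sdLag < 0)
    msg <- c(msg, "sdLag must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Bloom warning assessment
#'
#' Output of the decision layer: the warning level implied by the current
#' blue-channel Fv/Fm value and its trend, the forecast date window for the
#' density peak, and (when a density predictor is supplied) the predicted
#' cell density and bloom flag.
#'
#' Levels: \code{ELEVATED} (value at/above threshold, rising trend),
#' \code{REDUCED} (above threshold but falling, or below threshold but rising
#' - the "watch" state), \code{UNLIKELY} (below threshold and falling).
#'
#' @slot level one of \code{"ELEVATED"}, \code{"REDUCED"}, \code{"UNLIKELY"}.
#' @slot fvFmNow fitted Fv/Fm (BC) value at the assessment date.
#' @slot trendSign sign of the fitted-curve derivative: +1, -1 or 0.
#' @slot assessmentDate date the rule was evaluated at.
#' @slot forecastPeakDate forecast date of the density peak (\code{NA} when no
#'   peak forecast was requested).
#' @slot peakWindowDays half-width of the peak forecast window (days, the
#'   across-site SD of the lead).
#' @slot predictedDensity predicted cell density (cells/L) or \code{NA}.
#' @slot bloomForecast \code{TRUE} when the predicted density reaches the
#'   bloom threshold (>= convention).
#' @slot ruleTrace character vector recording which rule conditions fired.
#'
#' @seealso [classifyWarning()], [forecastPeak()], [predictBloom()]
#' @export
setClass("WarningAssessment",
  representation(
    level            = "character",
    fvFmNow          = "numeric",
    trendSign        = "numeric",
    assessmentDate   = "Date",
    forecastPeakDate = "Date",
    peakWindowDays   = "numeric",
    predictedDensity = "numeric",
    bloomForecast    = "logical",
    ruleTrace        = "character"
  )
)

setValidity("WarningAssessment", function(object) {
  msg <- character()
  if (!object@level %in% c("ELEVATED", "REDUCED", "UNLIKELY"))
    msg <- c(msg, "level must be ELEVATED, REDUCED or UNLIKELY")
  if (!object@trendSign %in% c(-1, 0, 1))
    msg <- c(msg, "trendSign must be -1, 0 or +1")
  if (!is.na(object@predictedDensity) && object@predictedDensity < 0)
    msg <- c(msg, "predicted density must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Linear mixed-model report
#'
#' Summary of a Gaussian linear mixed model with a per-site random intercept:
#' fixed-effect table (estimate, SE, t, Wald p with df = n_obs - n_fixed),
#' the random-intercept SD, and bookkeeping on which predictors were
#' square-root transformed. For density-prediction models the trained
#' predictor function (fluorescence value -> cells/L) is carried in
#' \code{predictor} and the lag applied to the predictor series in
#' \code{lagDays}.
#'
#' @slot response response variable name.
#' @slot fixedEffects data.frame with columns term, estimate, se, t, p.
#' @slot randomInterceptSd SD of the site random intercept (response units).
#' @slot residSd residual SD.
#' @slot nObs,nGroups observation and group counts.
#' @slot transformApplied named logical: which predictors were sqrt-transformed.
#' @slot singularFallback \code{TRUE} if the random effect was dropped after a
#'   singular fit and the model refit with fixed effects only.
#' @slot predictor optional function mapping a fluorescence value to a
#'   predicted density (cells/L).
#' @slot lagDays lag (days) applied to the predictor series, or \code{NA}.
#'
#' @seealso [fitDriverModel()], [fitCfparDensityModel()]
#' @export
setClass("MixedModelReport",
  representation(
    response          = "character",
    fixedEffects      = "data.frame",
    randomInterceptSd = "numeric",
    residSd           = "numeric",
    nObs              = "integer",
    nGroups           = "integer",
    transformApplied  = "logical",
    singularFallback  = "logical",
    predictor         = "functionOrNULL",
    lagDays           = "numeric"
  )
)

setValidity("MixedModelReport", function(object) {
  msg <- character()
  if (object@nGroups > object@nObs)
    msg <- c(msg, "nGroups cannot exceed nObs")
  if (!is.na(object@randomInterceptSd) && object@randomInterceptSd < 0)
    msg <- c(msg, "randomInterceptSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Analysis configuration
#'
#' Tunable constants shared by the pipeline stages. Defaults follow the
#' published early-warning calibration for Lake Erhai: a warning threshold of
#' 0.28 on blue-channel Fv/Fm, a bloom definition of 1e7 cells/L, a ~40-day
#' lead, 9999 re-randomisation replicates, a daily cross-correlation grid
#' searched over +/-183 days, and a 0.05 significance level.
#'
#' @slot timeUnit time convention; only \code{"fractional_year"} is supported.
#' @slot daysPerYear fixed year length for month/day conversion (365).
#' @slot permReps permutation replicates for the re-randomisation test.
#' @slot ccfGridDays,ccfMaxLagDays cross-correlation grid step and half-window.
#' @slot warnThreshold Fv/Fm (BC) warning threshold (dimensionless).
#' @slot bloomThreshold bloom definition (cells/L).
#' @slot leadDays nominal forecast lead (days).
#' @slot alpha significance level.
#' @slot seed integer seed (\code{NA} for unseeded).
#'
#' @seealso [analysisConfig()]
#' @export
setClass("AnalysisConfig",
  representation(
    timeUnit       = "character",
    daysPerYear    = "numeric",
    permReps       = "integer",
    ccfGridDays    = "numeric",
    ccfMaxLagDays  = "numeric",
    warnThreshold  = "numeric",
    bloomThreshold = "numeric",
    leadDays       = "numeric",
    alpha          = "numeric",
    seed           = "integer"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (!identical(object@timeUnit, "fractional_year"))
    msg <- c(msg, "timeUnit must be 'fractional_year'")
  if (object@permReps < 1L) msg <- c(msg, "permReps must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  thr <- c(object@ccfGridDays, object@ccfMaxLagDays, object@warnThreshold,
           object@bloomThreshold)
  if (any(thr <= 0)) msg <- c(msg, "grid, max lag and thresholds must be > 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic-dataset configuration
#'
#' Parameters of the multi-site monthly generator: per-variable harmonic
#' coefficients (rows of \code{coeffs}: beta0, beta1, beta2, beta3), the lead
#' (days) injected between the blue-channel Fv/Fm series and the cell-density
#' series, per-variable noise levels (as coefficients of variation) and
#' site-random-intercept SDs, the composition fractions (cyanobacteria share
#' of total density, Microcystis share of cyanobacteria), and the sampling
#' design (number of sites, months, series start date, seed).
#'
#' @slot nSites,nMonths sampling design (defaults 7 sites x 24 months).
#' @slot coeffs numeric matrix, one row per variable, columns beta0..beta3.
#' @slot leadDays injected lead of Fv/Fm (BC) over the densities (days).
#' @slot noiseCv named numeric, per-variable coefficient of variation.
#' @slot siteEffectSd named numeric, per-variable site-intercept SD.
#' @slot composition numeric: cyanobacteria fraction of total and Microcystis
#'   fraction of cyanobacteria.
#' @slot startDate first month of the series.
#' @slot seed integer seed.
#'
#' @seealso [syntheticConfig()], [generateDataset()]
#' @export
setClass("SyntheticConfig",
  representation(
    nSites       = "integer",
    nMonths      = "integer",
    coeffs       = "matrix",
    leadDays     = "numeric",
    noiseCv      = "numeric",
    siteEffectSd = "numeric",
    composition  = "numeric",
    startDate    = "Date",
    seed         = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nMonths < 12L) msg <- c(msg, "nMonths must be >= 12")
  if (object@nSites < 1L) msg <- c(msg, "nSites must be >= 1")
  if (ncol(object@coeffs) != 4L)
    msg <- c(msg, "coeffs must have 4 columns (beta0..beta3)")
  if (any(object@composition < 0 | object@composition > 1))
    msg <- c(msg, "composition fractions must lie in [0, 1]")
  if (any(object@noiseCv < 0)) msg <- c(msg, "noiseCv must be >= 0")
  if (any(object@siteEffectSd < 0)) msg <- c(msg, "siteEffectSd must be >= 0")
  if (length(msg)) msg else TRUE
})
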