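#' @include seasonal.R lag.R
NULL

#' Classify the bloom warning level from the fitted Fv/Fm (BC) curve
#'
#' Applies the threshold-plus-trend rule to the fitted blue-channel Fv/Fm
#' curve at a given date. The value is the fitted curve itself and the trend
#' is the sign of its analytic derivative (not a finite difference of noisy
#' observations). Rule table, with theta the warning threshold:
#' \itemize{
#'   \item value >= theta, trend rising: \code{ELEVATED} - bloom likelihood
#'     increases when Fv/Fm reaches the threshold and the trend keeps upward;
#'   \item value >= theta, trend falling: \code{REDUCED} - a falling trend
#'     lowers the likelihood even above the threshold;
#'   \item value < theta, trend falling: \code{UNLIKELY};
#'   \item value < theta, trend rising: \code{REDUCED} (watch state - the
#'     conservative reading between the two extremes).
#' }
#' A value exactly at the threshold counts as reached; a zero trend is
#' treated as not-rising and maps to \code{REDUCED} in both value branches.
#' Dates outside the fitted window (plus one month) attach an extrapolation
#' note to the rule trace.
#'
#' @param fit [SeasonalFit-class] for Fv/Fm (BC).
#' @param at assessment time: a \code{Date} or numeric fractional years
#'   since the fit's origin.
#' @param threshold warning threshold on Fv/Fm (BC); default 0.28.
#' @param daysPerYear fixed year length.
#' @return a [WarningAssessment-class] (peak/density slots unset).
#' @export
classifyWarning <- function(fit, at, threshold = 0.28, daysPerYear = 365) {
  if (threshold <= 0) stop("threshold must be positive")
  x <- .toFractionalYears(at, fit@timeOrigin, daysPerYear)
  if (length(x) != 1L) stop("classify one date at a time")
  value <- as.numeric(evaluateFit(fit, x))
  trend <- sign(as.numeric(fitDerivative(fit, x)))
  reached <- value >= threshold                 # boundary: 0.28 counts
  level <- if (reached && trend > 0) "ELEVATED"
           else if (!reached && trend < 0) "UNLIKELY"
           else "REDUCED"
  trace <- c(
    sprintf("Fv/Fm = %.4f %s threshold %.4g", value,
            if (reached) ">=" else "<", threshold),
    sprintf("trend %s", c("falling", "flat", "rising")[trend + 2]),
    sprintf("level %s", level)
  )
  span <- .defaultWindow(fit)
  if (x < span[1L] - 1 / 12 || x > span[2L] + 1 / 12)
    trace <- c(trace, "extrapolation: assessment date outside fitted window")
  when <- if (inherits(at, "Date")) at else if (!is.na(fit@timeOrigin))
    fit@timeOrigin + round(x * daysPerYear) else as.Date(NA)
  new("WarningAssessment",
      level = level, fvFmNow = value, trendSign = trend,
      assessmentDate = when, forecastPeakDate = as.Date(NA),
      peakWindowDays = NA_real_, predictedDensity = NA_real_,
      bloomForecast = NA, ruleTrace = trace)
}

#' Forecast the density-peak date from the Fv/Fm (BC) peak plus the lead
#'
#' Locates the fitted Fv/Fm curve's peak inside the window - the point where
#' the analytic derivative crosses zero downward, refined by root finding,
#' taking the highest such peak when the window spans several seasons - and
#' adds the estimated lead to forecast when the cell-density peak should
#' follow. The across-site SD of the lead gives the +/- uncertainty window.
#'
#' @param fit [SeasonalFit-class] for Fv/Fm (BC); must have nonzero seasonal
#'   amplitude.
#' @param lag a [LagEstimate-class], or a numeric lead in days (uncertainty
#'   window then \code{NA}).
#' @param window search window, as in [crossCorrelationLag()]; defaults to
#'   the fitted span.
#' @param daysPerYear fixed year length.
#' @return list with \code{peakX}, \code{peakValue}, \code{peakDate},
#'   \code{forecastX}, \code{forecastDate}, \code{windowDays} (dates are
#'   \code{NA} when the fit has no calendar origin; \code{*X} are fractional
#'   years since the origin).
#' @export
forecastPeak <- function(fit, lag, window = NULL, daysPerYear = 365) {
  b <- fit@coefficients
  if (sqrt(b[3L]^2 + b[4L]^2) < 1e-12)
    stop("no seasonal peak: fitted seasonal amplitude is zero")
  leadDays <- if (is(lag, "LagEstimate")) lag@meanLag else as.numeric(lag)
  sdDays <- if (is(lag, "LagEstimate")) lag@sdLag else NA_real_
  w <- .resolveWindow(window, fit, daysPerYear)
  xg <- seq(w[1L], w[2L], by = 1 / daysPerYear)
  g <- fitDerivative(fit, xg)
  down <- which(g[-length(g)] > 0 & g[-1L] <= 0)   # + to - crossings
  if (!length(down))
    stop("no seasonal peak inside the window")
  peaks <- vapply(down, function(i) {
    stats::uniroot(function(z) fitDerivative(fit, z),
                   lower = xg[i], upper = xg[i + 1L],
                   tol = 1e-10 / daysPerYear)$root
  }, numeric(1))
  vals <- evaluateFit(fit, peaks)
  peakX <- peaks[which.max(vals)]
  forecastX <- peakX + leadDays / daysPerYear
  toDate <- function(x) if (is.na(fit@timeOrigin)) as.Date(NA) else
    fit@timeOrigin + round(x * daysPerYear)
  list(peakX = unname(peakX), peakValue = unname(max(vals)),
       peakDate = toDate(peakX), forecastX = unname(forecastX),
       forecastDate = toDate(forecastX), windowDays = sdDays)
}

#' Predict cell density from Fv/Fm and flag a bloom
#'
#' Runs the trained density predictor (from [fitCfparDensityModel()]) on a
#' current Fv/Fm value and flags a bloom when the predicted density reaches
#' the threshold (a prediction exactly at the threshold counts as a bloom).
#'
#' @param model [MixedModelReport-class] carrying a trained predictor.
#' @param fvFm current Fv/Fm (BC) value(s), in [0, 1].
#' @param bloomThreshold bloom definition (cells/L); default 1e7.
#' @param assessment optional [WarningAssessment-class] to update in place.
#' @return the updated [WarningAssessment-class] when one is supplied;
#'   otherwise a list with \code{predictedDensity} and \code{bloomForecast}.
#' @export
predictBloom <- function(model, fvFm, bloomThreshold = 1e7,
                         assessment = NULL) {
  if (is.null(model@predictor))
    stop("no trained density predictor: fit one with fitCfparDensityModel()")
  if (any(fvFm < 0 | fvFm > 1, na.rm = TRUE))
    stop("fvFm values must lie in [0, 1]")
  predicted <- model@predictor(fvFm)
  bloom <- predicted >= bloomThreshold           # boundary: 1e7 is a bloom
  if (is.null(assessment))
    return(list(predictedDensity = predicted, bloomForecast = bloom))
  stopifnot(is(assessment, "WarningAssessment"), length(predicted) == 1L)
  assessment@predictedDensity <- as.numeric(predicted)
  assessment@bloomForecast <- bloom
  assessment@ruleTrace <- c(assessment@ruleTrace,
    sprintf("predicted density %.3g cells/L %s bloom threshold %.3g",
            predicted, if (bloom) ">=" else "<", bloomThreshold))
  assessment
}

#' One-call bloom risk assessment
#'
#' Convenience wrapper chaining [classifyWarning()], [forecastPeak()] and
#' [predictBloom()]: classify the warning level at a date, forecast the
#' density-peak window from the estimated lead, and predict the density the
#' current Fv/Fm value implies.
#'
#' @param fit [SeasonalFit-class] for Fv/Fm (BC).
#' @param at assessment date (or fractional years).
#' @param config an [AnalysisConfig-class]; supplies the warning and bloom
#'   thresholds.
#' @param lag optional [LagEstimate-class] (or numeric days) for the peak
#'   forecast.
#' @param densityModel optional trained [MixedModelReport-class].
#' @return a [WarningAssessment-class].
#' @export
assessBloomRisk <- function(fit, at, config = analysisConfig(), lag = NULL,
                            densityModel = NULL) {
  wa <- classifyWarning(fit, at, threshold = config@warnThreshold,
                        daysPerYear = config@daysPerYear)
  if (!is.null(lag)) {
    # search the year ahead of the assessment date: the next seasonal peak
    # is the one an early warning is about
    xAt <- .toFractionalYears(at, fit@timeOrigin, config@daysPerYear)
    fp <- forecastPeak(fit, lag, window = c(xAt, xAt + 1),
                       daysPerYear = config@daysPerYear)
    wa@forecastPeakDate <- fp$forecastDate
    wa@peakWindowDays <- fp$windowDays
    wa@ruleTrace <- c(wa@ruleTrace,
      sprintf("Fv/Fm peak at %s; density peak forecast %s +/- %s days",
              format(fp$peakDate), format(fp$forecastDate),
              format(fp$windowDays)))
  }
  if (!is.null(densityModel))
    wa <- predictBloom(densityModel, wa@fvFmNow,
                       bloomThreshold = config@bloomThreshold,
                       assessment = wa)
  wa
}
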