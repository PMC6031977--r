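#' @include AllClasses.R
NULL

#' Evaluate a fitted seasonal curve
#'
#' @param fit a [SeasonalFit-class] object.
#' @param at times to evaluate at: numeric fractional years since the fit's
#'   time origin, or \code{Date}s (converted at 365 days per year).
#' @return numeric vector of fitted values (response units).
#' @export
setGeneric("evaluateFit", function(fit, at) standardGeneric("evaluateFit"))

#' Analytic derivative of a fitted seasonal curve
#'
#' @inheritParams evaluateFit
#' @return numeric vector of rates, in response units per year.
#' @export
setGeneric("fitDerivative", function(fit, at) standardGeneric("fitDerivative"))

#' @rdname accessors
#' @export
setGeneric("adjR2", function(object) standardGeneric("adjR2"))

#' @rdname accessors
#' @export
setGeneric("modelPvalue", function(object) standardGeneric("modelPvalue"))

#' @rdname accessors
#' @export
setGeneric("fStatistic", function(object) standardGeneric("fStatistic"))

#' @rdname accessors
#' @export
setGeneric("perSiteLags", function(object) standardGeneric("perSiteLags"))

#' @rdname accessors
#' @export
setGeneric("meanLag", function(object) standardGeneric("meanLag"))

#' @rdname accessors
#' @export
setGeneric("sdLag", function(object) standardGeneric("sdLag"))

#' @rdname accessors
#' @export
setGeneric("warningLevel", function(object) standardGeneric("warningLevel"))

#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))

#' Accessors for bloomwarn result objects
#'
#' Small read-only accessors: \code{adjR2}, \code{fStatistic} (with its df as
#' an attribute), \code{modelPvalue} and \code{coef} for [SeasonalFit-class];
#' \code{perSiteLags}, \code{meanLag}, \code{sdLag} for [LagEstimate-class];
#' \code{warningLevel} for [WarningAssessment-class]; \code{fixedEffects} for
#' [MixedModelReport-class].
#'
#' @param object a bloomwarn result object.
#' @name accessors
NULL

#' @rdname accessors
#' @param ... ignored.
#' @export
setMethod("coef", "SeasonalFit", function(object, ...) object@coefficients)

#' @rdname accessors
#' @export
setMethod("adjR2", "SeasonalFit", function(object) object@adjR2)

#' @rdname accessors
#' @export
setMethod("fStatistic", "SeasonalFit", function(object) {
  structure(object@fStat, df = object@df)
})

#' @rdname accessors
#' @export
setMethod("modelPvalue", "SeasonalFit", function(object) object@modelP)

#' @rdname accessors
#' @export
setMethod("nobs", "SeasonalFit", function(object, ...) object@n)

#' @rdname accessors
#' @export
setMethod("perSiteLags", "LagEstimate", function(object) object@perSiteLags)

#' @rdname accessors
#' @export
setMethod("meanLag", "LagEstimate", function(object) object@meanLag)

#' @rdname accessors
#' @export
setMethod("sdLag", "LagEstimate", function(object) object@sdLag)

#' @rdname accessors
#' @export
setMethod("warningLevel", "WarningAssessment", function(object) object@level)

#' @rdname accessors
#' @export
setMethod("fixedEffects", "MixedModelReport", function(object) object@fixedEffects)

setMethod("show", "SeasonalFit", function(object) {
  cat("SeasonalFit", if (!is.na(object@response)) sprintf("(%s)", object@response),
      "\n")
  tab <- data.frame(
    estimate = object@coefficients,
    se = object@se,
    p = signif(object@pvalues, 3),
    row.names = c("beta0 (intercept)", "beta1 (trend/yr)",
                  "beta2 (sin 2*pi*x)", "beta3 (cos 2*pi*x)")
  )
  print(tab)
  cat(sprintf("adj R2 = %.3f, F(%d,%d) = %.3f, p = %.4g, resid SD = %.4g, n = %d\n",
              object@adjR2, object@df[1L], object@df[2L], object@fStat,
              object@modelP, object@residSd, object@n))
  if (!is.na(object@timeOrigin))
    cat("time origin (x = 0):", format(object@timeOrigin), "\n")
})

setMethod("show", "LagEstimate", function(object) {
  cat(sprintf("LagEstimate: %s leads %s\n",
              object@seriesNames[1L], object@seriesNames[2L]))
  cat(sprintf("  mean lag %.1f +/- %.1f days (95%% CI %.1f to %.1f), grid %g d\n",
              object@meanLag, object@sdLag, object@ci95[1L], object@ci95[2L],
              object@gridDays))
  cat(sprintf("  correlation at mean lag: %.3f; %d site(s):\n",
              object@bestCorr, length(object@perSiteLags)))
  print(object@perSiteLags)
})

setMethod("show", "WarningAssessment", function(object) {
  cat(sprintf("WarningAssessment [%s] at %s\n", object@level,
              format(object@assessmentDate)))
  cat(sprintf("  Fv/Fm (BC) = %.3f, trend %s\n", object@fvFmNow,
              c(`-1` = "falling", `0` = "flat", `1` = "rising")[
                as.character(object@trendSign)]))
  if (!is.na(object@forecastPeakDate))
    cat(sprintf("  forecast density peak: %s +/- %.1f days\n",
                format(object@forecastPeakDate), object@peakWindowDays))
  if (!is.na(object@predictedDensity))
    cat(sprintf("  predicted density: %.3g cells/L (bloom: %s)\n",
                object@predictedDensity, object@bloomForecast))
  for (tr in object@ruleTrace) cat("  -", tr, "\n")
})

setMethod("show", "MixedModelReport", function(object) {
  cat("MixedModelReport:", object@response, "\n")
  print(object@fixedEffects, digits = 4)
  cat(sprintf("  site random-intercept SD = %.4g, resid SD = %.4g, n = %d obs / %d sites\n",
              object@randomInterceptSd, object@residSd, object@nObs,
              object@nGroups))
  if (object@singularFallback)
    cat("  NOTE: singular random-effect fit; fixed-effects-only fallback used\n")
  if (!is.na(object@lagDays))
    cat(sprintf("  predictor lag: %g days\n", object@lagDays))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: %d sites x %d months from %s, lead %g days, seed %s\n",
              object@nSites, object@nMonths, format(object@startDate),
              object@leadDays,
              if (is.na(object@seed)) "unset" else object@seed))
  cat("variables:", paste(rownames(object@coeffs), collapse = ", "), "\n")
})

setMethod("show", "AnalysisConfig", function(object) {
  cat(sprintf(paste0("AnalysisConfig: warn >= %g (Fv/Fm BC), bloom >= %g cells/L, ",
                     "lead %g d,\n  CCF grid %g d in +/-%g d, %d permutation reps, ",
                     "alpha %g\n"),
              object@warnThreshold, object@bloomThreshold, object@leadDays,
              object@ccfGridDays, object@ccfMaxLagDays, object@permReps,
              object@alpha))
})
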