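#' @include records.R seasonal.R
NULL

# Wald fixed-effect table with df = n_obs - n_fixed
.waldTable <- function(est, se, nObs) {
  df <- nObs - length(est)
  t <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             t = unname(t), p = unname(2 * stats::pt(-abs(t), df)),
             row.names = NULL, stringsAsFactors = FALSE)
}

.lmmReport <- function(formulaFixed, data, response, transformApplied,
                       predictor = NULL, lagDays = NA_real_) {
  nObs <- nrow(data)
  nGroups <- length(unique(data$site_id))
  if (nGroups < 2L) stop("need at least 2 sites for a site random intercept")
  full <- stats::update(formulaFixed, . ~ . + (1 | site_id))
  fit <- suppressMessages(lme4::lmer(full, data = data, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("singular random-effect fit; falling back to fixed effects only")
    ols <- stats::lm(formulaFixed, data = data)
    sm <- summary(ols)$coefficients
    est <- sm[, 1L]; se <- sm[, 2L]
    reSd <- 0
    residSd <- summary(ols)$sigma
  } else {
    sm <- summary(fit)$coefficients
    est <- sm[, 1L]; se <- sm[, 2L]
    vc <- as.data.frame(lme4::VarCorr(fit))
    reSd <- vc$sdcor[vc$grp == "site_id"]
    residSd <- vc$sdcor[vc$grp == "Residual"]
  }
  new("MixedModelReport",
      response = response,
      fixedEffects = .waldTable(est, se, nObs),
      randomInterceptSd = reSd, residSd = residSd,
      nObs = as.integer(nObs), nGroups = as.integer(nGroups),
      transformApplied = transformApplied,
      singularFallback = singular,
      predictor = predictor, lagDays = lagDays)
}

#' Screen environmental drivers with a site-random-intercept mixed model
#'
#' Gaussian linear mixed model of a response (typically chlorophyll a) on a
#' set of environmental predictors (temperature, light attenuation,
#' nutrients, ...), with sampling site as a random intercept to absorb
#' between-site differences and avoid pseudoreplication. Predictors are
#' square-root transformed by default, the usual normalising transform for
#' these right-skewed field variables; negative values under the transform
#' raise an error naming the variable. Fixed-effect p-values are Wald tests
#' with df = n_obs - n_fixed.
#'
#' @param records data.frame of monitoring records (see [recordColumns()]).
#' @param response response column name.
#' @param predictors character vector of predictor column names.
#' @param sqrtTransform logical scalar, or named logical per predictor:
#'   apply sqrt to that predictor.
#' @return a [MixedModelReport-class].
#' @export
fitDriverModel <- function(records, response, predictors,
                           sqrtTransform = TRUE) {
  validateRecords(records)
  need <- c("site_id", response, predictors)
  if (length(miss <- setdiff(need, names(records))))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (length(sqrtTransform) == 1L)
    sqrtTransform <- stats::setNames(rep(sqrtTransform, length(predictors)),
                                     predictors)
  dat <- records[, need]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  for (p in predictors) {
    if (isTRUE(sqrtTransform[[p]])) {
      if (any(dat[[p]] < 0))
        stop("negative values in '", p, "' cannot be square-root transformed")
      dat[[p]] <- sqrt(dat[[p]])
    }
  }
  names(dat)[names(dat) == response] <- ".y"
  fml <- stats::as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
  .lmmReport(fml, dat, response, sqrtTransform[predictors])
}

#' Regress cell density on a lagged fluorescence parameter
#'
#' Tests whether a chlorophyll-fluorescence parameter predicts an algal cell
#' density measured \code{lagDays} later. For each site the fluorescence
#' series is smoothed with the trigonometric seasonal fit and the fitted
#' curve is evaluated \code{lagDays} earlier than each density observation;
#' the density (log10-transformed by default, since cells/L span orders of
#' magnitude) is then regressed on that lagged value with a site random
#' intercept. Observations whose shifted time falls before the fitted window
#' are dropped; an error is raised if too few remain.
#'
#' The returned report carries a trained \code{predictor} function mapping a
#' fluorescence value to a predicted density in cells/L (back-transformed
#' when \code{logResponse} is \code{TRUE}), for use by the warning engine.
#'
#' @param records data.frame of monitoring records.
#' @param density density column: \code{"c_total"}, \code{"c_cyano"} or
#'   \code{"c_microcystis"}.
#' @param cfpar fluorescence column: one of \code{"fv_fm_tc"},
#'   \code{"fv_fm_bc"}, \code{"df_fm_tc"}, \code{"df_fm_bc"}.
#' @param lagDays non-negative lag applied to the fluorescence curve (days).
#' @param logResponse regress log10(density) rather than density.
#' @param daysPerYear fixed year length.
#' @return a [MixedModelReport-class] with a \code{predictor} function.
#' @export
fitCfparDensityModel <- function(records, density = "c_total",
                                 cfpar = "fv_fm_bc", lagDays = 40,
                                 logResponse = TRUE, daysPerYear = 365) {
  validateRecords(records)
  if (lagDays < 0) stop("lagDays must be >= 0")
  need <- c("site_id", "date", density, cfpar)
  if (length(miss <- setdiff(need, names(records))))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  records$date <- .floorMonth(records$date)
  rows <- list()
  for (s in unique(records$site_id)) {
    sub <- records[records$site_id == s, ]
    ok <- !is.na(sub[[cfpar]])
    if (sum(ok) < 5L) next
    cfFit <- fitTrigonometric(sub$date[ok], sub[[cfpar]][ok], response = cfpar)
    x <- .monthsBetween(sub$date, cfFit@timeOrigin) / 12
    xShift <- x - lagDays / daysPerYear
    keep <- xShift >= -1e-9 & !is.na(sub[[density]])
    if (!any(keep)) next
    rows[[s]] <- data.frame(site_id = s,
                            cf_lagged = evaluateFit(cfFit, xShift[keep]),
                            dens = sub[[density]][keep],
                            stringsAsFactors = FALSE)
  }
  dat <- do.call(rbind, rows)
  if (is.null(dat) || nrow(dat) < 10L)
    stop("window too short after shifting by ", lagDays, " days")
  if (logResponse) {
    pos <- dat$dens > 0
    if (!all(pos)) {
      warning(sum(!pos), " non-positive densities dropped before log10")
      dat <- dat[pos, , drop = FALSE]
    }
    dat$.y <- log10(dat$dens)
  } else dat$.y <- dat$dens
  rep0 <- .lmmReport(.y ~ cf_lagged, dat, response = density,
                     transformApplied = stats::setNames(FALSE, cfpar),
                     lagDays = lagDays)
  fe <- rep0@fixedEffects
  a <- fe$estimate[fe$term == "(Intercept)"]
  b <- fe$estimate[fe$term == "cf_lagged"]
  rep0@predictor <- if (logResponse) {
    function(cfValue) 10^(a + b * cfValue)
  } else {
    function(cfValue) pmax(a + b * cfValue, 0)
  }
  rep0
}
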