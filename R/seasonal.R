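#' @include AllClasses.R AllGenerics.R
NULL

# months elapsed between two dates at month resolution
.monthsBetween <- function(date, origin) {
  d <- as.POSIXlt(date); o <- as.POSIXlt(origin)
  (d$year - o$year) * 12L + (d$mon - o$mon)
}

# convert dates (or numeric fractional years) to x, years since origin
.toFractionalYears <- function(at, origin, daysPerYear = 365) {
  if (is.numeric(at)) return(at)
  if (inherits(at, "Date")) {
    if (is.na(origin))
      stop("fit has no time origin; supply numeric fractional years instead")
    return(as.numeric(at - origin) / daysPerYear)
  }
  stop("'at' must be numeric (fractional years) or Date")
}

.harmonicDesign <- function(x) {
  cbind(1, x, sin(2 * pi * x), cos(2 * pi * x))
}

#' Fit the trigonometric seasonal regression
#'
#' Ordinary least squares of a monthly series on
#' \eqn{[1, x, \sin(2\pi x), \cos(2\pi x)]}: a stochastic local trend
#' (intercept and slope) plus one annual harmonic. Time is converted to
#' fractional years, \code{x = (months since timeOrigin) / 12}, so that the
#' seasonal period is one year; with 24 monthly points the overall F test
#' carries (3, 20) degrees of freedom.
#'
#' @param dates observation times: \code{Date}s at month resolution, or
#'   numeric fractional years used as-is.
#' @param values response values (same length); missing pairs are dropped.
#' @param timeOrigin date mapped to x = 0; defaults to the earliest date.
#'   Ignored when \code{dates} is numeric.
#' @param response optional variable name carried into the report.
#' @return a [SeasonalFit-class] with coefficients, SEs, t-based p-values,
#'   adjusted R-squared, overall F(3, n - 4) and its p-value, residual SD.
#' @examples
#' x <- (0:23) / 12
#' y <- 0.27 + 0.16 * sin(2 * pi * x) + 0.04 * cos(2 * pi * x)
#' coef(fitTrigonometric(x, y))
#' @export
fitTrigonometric <- function(dates, values, timeOrigin = NULL,
                             response = NA_character_) {
  if (length(dates) != length(values))
    stop("dates and values must have the same length")
  keep <- !is.na(values) & !is.na(dates)
  dates <- dates[keep]; values <- values[keep]
  if (length(values) < 5L)
    stop("insufficient data: need at least 5 non-missing points, got ",
         length(values))
  if (inherits(dates, "Date")) {
    origin <- if (is.null(timeOrigin)) min(dates) else as.Date(timeOrigin)
    origin <- .floorMonth(origin)
    x <- .monthsBetween(.floorMonth(dates), origin) / 12
  } else {
    origin <- as.Date(NA)
    x <- as.numeric(dates)
  }
  X <- .harmonicDesign(x)
  if (qr(X)$rank < 4L)
    stop("singular design: time points do not identify trend and seasonal terms")
  df <- data.frame(y = values, x = x, s = sin(2 * pi * x), c = cos(2 * pi * x))
  fit <- stats::lm(y ~ x + s + c, data = df)
  # noise-free round trips legitimately fit perfectly; the stock lm warning
  # about that is noise here
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  ct <- sm$coefficients
  # a numerically perfect fit leaves summary() p-values NaN; keep them NA
  n <- length(values)
  fstat <- sm$fstatistic
  if (is.null(fstat)) fstat <- c(value = NA_real_, numdf = 3, dendf = n - 4)
  modelP <- if (is.na(fstat[1L])) NA_real_ else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  new("SeasonalFit",
      response     = response,
      coefficients = stats::setNames(unname(ct[, 1L]),
                                     c("beta0", "beta1", "beta2", "beta3")),
      se           = unname(ct[, 2L]),
      pvalues      = unname(ct[, 4L]),
      adjR2        = sm$adj.r.squared,
      fStat        = unname(fstat[1L]),
      df           = c(3, n - 4),
      modelP       = unname(modelP),
      residSd      = sm$sigma,
      timeOrigin   = origin,
      n            = as.integer(n))
}

#' @describeIn evaluateFit fitted value
#'   \eqn{\beta_0 + \beta_1 x + \beta_2 \sin(2\pi x) + \beta_3 \cos(2\pi x)}
#'   at the requested times.
#' @export
setMethod("evaluateFit", "SeasonalFit", function(fit, at) {
  x <- .toFractionalYears(at, fit@timeOrigin)
  b <- unname(fit@coefficients)
  b[1L] + b[2L] * x + b[3L] * sin(2 * pi * x) + b[4L] * cos(2 * pi * x)
})

#' @describeIn fitDerivative analytic rate
#'   \eqn{\beta_1 + 2\pi[\beta_2 \cos(2\pi x) - \beta_3 \sin(2\pi x)]}.
#' @export
setMethod("fitDerivative", "SeasonalFit", function(fit, at) {
  x <- .toFractionalYears(at, fit@timeOrigin)
  b <- unname(fit@coefficients)
  b[2L] + 2 * pi * (b[3L] * cos(2 * pi * x) - b[4L] * sin(2 * pi * x))
})

#' Re-randomisation (permutation) test of the seasonal model
#'
#' Permutes the response against time, refits the harmonic model, and
#' compares the overall F statistic of each permuted fit with the observed
#' one. The p-value uses the add-one estimator,
#' \code{p = (1 + #(F_perm >= F_obs)) / (reps + 1)}, so it can never be
#' exactly zero; with a noise-free seasonal signal and 999 replicates the
#' minimum attainable p is 1/1000. A constant response carries no evidence
#' and returns p = 1 with a warning.
#'
#' @inheritParams fitTrigonometric
#' @param reps number of permutation replicates (default 9999).
#' @param seed optional integer seed for the permutations.
#' @return the permutation p-value, with the observed F statistic attached
#'   as attribute \code{"fObs"}.
#' @export
rerandomizationTest <- function(dates, values, reps = 9999L, seed = NULL) {
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1")
  keep <- !is.na(values) & !is.na(dates)
  dates <- dates[keep]; values <- values[keep]
  n <- length(values)
  if (n < 5L) stop("insufficient data for the permutation test")
  if (stats::var(values) == 0) {
    warning("constant response: permutation test is uninformative, p = 1")
    return(structure(1, fObs = NA_real_))
  }
  if (inherits(dates, "Date")) {
    origin <- .floorMonth(min(dates))
    x <- .monthsBetween(.floorMonth(dates), origin) / 12
  } else x <- as.numeric(dates)
  X <- .harmonicDesign(x)
  if (qr(X)$rank < 4L) stop("singular design")
  Q <- qr.Q(qr(X))                      # orthonormal basis, intercept included
  tss <- sum((values - mean(values))^2)
  meanAdj <- n * mean(values)^2
  fOf <- function(qty) {
    ess <- colSums(qty^2) - meanAdj
    r2 <- pmin(pmax(ess / tss, 0), 1)
    (r2 / 3) / ((1 - r2) / (n - 4))
  }
  fObs <- fOf(crossprod(Q, matrix(values)))
  if (length(seed) == 1L && is.na(seed)) seed <- NULL
  if (!is.null(seed)) {
    oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
    set.seed(seed)
  }
  perms <- matrix(0, n, reps)
  for (j in seq_len(reps)) perms[, j] <- values[sample.int(n)]
  fPerm <- fOf(crossprod(Q, perms))
  p <- (1 + sum(fPerm >= fObs - 1e-12)) / (reps + 1)
  structure(p, fObs = unname(fObs))
}
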