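#' @include seasonal.R
NULL

# Pearson correlation between curve a at t and curve b at t + lag, on a
# fractional-year grid; the workhorse for the lag search.
.corAtLag <- function(fitA, fitB, tGrid, lagYears) {
  a <- evaluateFit(fitA, tGrid)
  b <- evaluateFit(fitB, tGrid + lagYears)
  flat <- function(v) stats::sd(v) <= 1e-10 * max(1, abs(mean(v)))
  if (flat(a) || flat(b))
    stop("undefined correlation: a fitted curve is constant over the window")
  stats::cor(a, b)
}

.defaultWindow <- function(fit) c(0, (fit@n - 1) / 12)   # fitted span

# default CCF window: the largest whole number of years inside the fitted
# span. A fractional-period window makes the correlation of two annual
# harmonics peak slightly off their true phase difference (partial-period
# end effects shift the argmax by up to ~1 day); whole periods are exact.
.ccfWindow <- function(fit) c(0, max(1, floor((fit@n - 1) / 12)))

.resolveWindow <- function(window, fitA, daysPerYear,
                           default = .defaultWindow) {
  if (is.null(window)) return(default(fitA))
  w <- .toFractionalYears(window, fitA@timeOrigin, daysPerYear)
  if (length(w) != 2L || w[2L] <= w[1L]) stop("window must be (start, end)")
  w
}

#' Cross-correlation lag between two fitted seasonal curves
#'
#' Evaluates both fitted curves on a fine time grid over the window and
#' returns the lag (days) maximising the Pearson correlation of the first
#' curve at time t with the second at t + lag, searched over
#' +/- \code{maxLagDays}. A positive lag means the first series leads the
#' second by that many days. Ties are broken toward the smallest absolute
#' lag. Because the curves are analytic, sub-monthly lags are resolved at
#' the grid step (default 1 day).
#'
#' @param fitA,fitB [SeasonalFit-class] objects; \code{fitA} is the
#'   (candidate) leading series.
#' @param window evaluation window covering at least one full year: numeric
#'   \code{c(start, end)} in fractional years since \code{fitA}'s origin, or
#'   a pair of \code{Date}s. Defaults to the largest whole number of years
#'   inside \code{fitA}'s fitted span (whole seasonal periods keep the
#'   correlation peak free of partial-period end effects).
#' @param maxLagDays search half-window (days).
#' @param gridDays grid step (days).
#' @param daysPerYear fixed year length for the day/year conversion.
#' @return lag in days (positive: \code{fitA} leads), with the correlation
#'   at that lag attached as attribute \code{"correlation"}.
#' @examples
#' x <- (0:23) / 12
#' a <- fitTrigonometric(x, sin(2 * pi * x))
#' b <- fitTrigonometric(x, sin(2 * pi * (x - 40 / 365)))
#' crossCorrelationLag(a, b)  # ~40
#' @export
crossCorrelationLag <- function(fitA, fitB, window = NULL, maxLagDays = 183,
                                gridDays = 1, daysPerYear = 365) {
  w <- .resolveWindow(window, fitA, daysPerYear, default = .ccfWindow)
  if (diff(w) < 1 - 1e-9)
    stop("window must cover at least one full year")
  tGrid <- seq(w[1L], w[2L], by = gridDays / daysPerYear)
  lags <- seq(-maxLagDays, maxLagDays, by = gridDays)
  cors <- vapply(lags, function(d) .corAtLag(fitA, fitB, tGrid, d / daysPerYear),
                 numeric(1))
  top <- which(cors >= max(cors) - 1e-12)
  best <- top[which.min(abs(lags[top]))]
  structure(lags[best], correlation = cors[best])
}

#' Across-site lead/lag distribution
#'
#' Runs [crossCorrelationLag()] for every site's pair of fitted curves and
#' summarises the per-site lags: mean, standard deviation, and a
#' normal-approximation 95% confidence interval for the mean
#' (mean +/- 1.96 sd / sqrt(n_sites)). \code{bestCorr} is the across-site
#' mean Pearson correlation at the mean lag. With a single site the SD and
#' CI are reported missing, with a warning.
#'
#' @param fitsA,fitsB named lists of [SeasonalFit-class] objects, one per
#'   site; names must agree (\code{fitsA} is the candidate leading series).
#' @param config an [AnalysisConfig-class]; supplies the grid step and
#'   search half-window.
#' @param window evaluation window, as in [crossCorrelationLag()].
#' @return a [LagEstimate-class].
#' @export
siteLagDistribution <- function(fitsA, fitsB, config = analysisConfig(),
                                window = NULL) {
  if (is.null(names(fitsA)) || is.null(names(fitsB)))
    stop("per-site fit lists must be named by site")
  if (!setequal(names(fitsA), names(fitsB)))
    stop("the two fit lists must cover the same sites")
  sites <- names(fitsA)
  lags <- vapply(sites, function(s) {
    as.numeric(crossCorrelationLag(fitsA[[s]], fitsB[[s]], window = window,
                                   maxLagDays = config@ccfMaxLagDays,
                                   gridDays = config@ccfGridDays,
                                   daysPerYear = config@daysPerYear))
  }, numeric(1))
  m <- mean(lags)
  if (length(lags) < 2L) {
    warning("single site: lag SD is undefined")
    s <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    s <- stats::sd(lags)
    half <- stats::qnorm(1 - config@alpha / 2) * s / sqrt(length(lags))
    ci <- c(m - half, m + half)
  }
  corAtMean <- mean(vapply(sites, function(st) {
    w <- .resolveWindow(window, fitsA[[st]], config@daysPerYear,
                        default = .ccfWindow)
    tGrid <- seq(w[1L], w[2L], by = config@ccfGridDays / config@daysPerYear)
    .corAtLag(fitsA[[st]], fitsB[[st]], tGrid, m / config@daysPerYear)
  }, numeric(1)))
  nmA <- fitsA[[1L]]@response; nmB <- fitsB[[1L]]@response
  new("LagEstimate",
      perSiteLags = lags, meanLag = m, sdLag = s, ci95 = ci,
      bestCorr = corAtMean, gridDays = config@ccfGridDays,
      maxLagDays = config@ccfMaxLagDays,
      seriesNames = c(if (is.na(nmA)) "series A" else nmA,
                      if (is.na(nmB)) "series B" else nmB))
}
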