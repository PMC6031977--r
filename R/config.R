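#' Create an analysis configuration
#'
#' Constructor for [AnalysisConfig-class]. Defaults are the published
#' early-warning calibration: Fv/Fm (BC) warning threshold 0.28, bloom
#' threshold 1e7 cells/L, nominal 40-day lead, 9999 re-randomisation
#' replicates, daily cross-correlation grid searched over +/-183 days,
#' alpha = 0.05, 365-day year.
#'
#' @param permReps permutation replicates for [rerandomizationTest()].
#' @param ccfGridDays cross-correlation grid step (days).
#' @param ccfMaxLagDays cross-correlation search half-window (days).
#' @param warnThreshold Fv/Fm (BC) warning threshold.
#' @param bloomThreshold bloom density definition (cells/L).
#' @param leadDays nominal forecast lead (days).
#' @param alpha significance level.
#' @param seed optional integer seed.
#' @param daysPerYear fixed year length for month/day conversion.
#' @return an [AnalysisConfig-class] object.
#' @examples
#' analysisConfig()
#' analysisConfig(warnThreshold = 0.30, permReps = 999)
#' @export
analysisConfig <- function(permReps = 9999L, ccfGridDays = 1, ccfMaxLagDays = 183,
                           warnThreshold = 0.28, bloomThreshold = 1e7,
                           leadDays = 40, alpha = 0.05, seed = NA_integer_,
                           daysPerYear = 365) {
  new("AnalysisConfig",
      timeUnit = "fractional_year", daysPerYear = daysPerYear,
      permReps = as.integer(permReps), ccfGridDays = ccfGridDays,
      ccfMaxLagDays = ccfMaxLagDays, warnThreshold = warnThreshold,
      bloomThreshold = bloomThreshold, leadDays = leadDays, alpha = alpha,
      seed = as.integer(seed))
}

#' Read an analysis configuration from YAML
#'
#' The YAML keys mirror the [analysisConfig()] arguments (snake_case accepted:
#' \code{perm_reps}, \code{ccf_grid_days}, \code{ccf_max_lag_days},
#' \code{warn_threshold}, \code{bloom_threshold}, \code{lead_days},
#' \code{alpha}, \code{seed}, \code{days_per_year}). Unknown keys raise an
#' error rather than being silently dropped.
#'
#' @param path path to a YAML file.
#' @return an [AnalysisConfig-class] object.
#' @export
readAnalysisConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  canon <- c(perm_reps = "permReps", ccf_grid_days = "ccfGridDays",
             ccf_max_lag_days = "ccfMaxLagDays", warn_threshold = "warnThreshold",
             bloom_threshold = "bloomThreshold", lead_days = "leadDays",
             alpha = "alpha", seed = "seed", days_per_year = "daysPerYear")
  nm <- names(raw)
  mapped <- ifelse(nm %in% names(canon), canon[nm], nm)
  known <- c(unname(canon), "timeUnit", "time_unit")
  if (any(bad <- !mapped %in% known))
    stop("unknown configuration key(s): ", paste(nm[bad], collapse = ", "))
  args <- stats::setNames(raw, mapped)
  args <- args[!mapped %in% c("timeUnit", "time_unit")]
  # YAML 1.1 reads "1.0e7" (no signed exponent) as a string; be forgiving
  args <- lapply(args, function(v)
    if (is.character(v) && !is.na(suppressWarnings(as.numeric(v))))
      as.numeric(v) else v)
  do.call(analysisConfig, args)
}
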