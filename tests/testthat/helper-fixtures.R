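# shared fixtures: all synthetic, built in code at test time

# noise-free monthly series from the harmonic model, x = month/12
makeSeasonalSeries <- function(beta, nMonths = 24L) {
  x <- (seq_len(nMonths) - 1L) / 12
  list(x = x,
       y = beta[1] + beta[2] * x + beta[3] * sin(2 * pi * x) +
         beta[4] * cos(2 * pi * x))
}

# independent brute-force cross-correlation oracle: explicit harmonic
# evaluation (no package code) and plain cor() over every grid lag
bruteForceLag <- function(betaA, betaB, spanYears = 1,
                          maxLagDays = 183, gridDays = 1) {
  curve <- function(beta, x)
    beta[1] + beta[2] * x + beta[3] * sin(2 * pi * x) + beta[4] * cos(2 * pi * x)
  t <- seq(0, spanYears, by = gridDays / 365)
  lags <- seq(-maxLagDays, maxLagDays, by = gridDays)
  cors <- sapply(lags, function(d) cor(curve(betaA, t), curve(betaB, t + d / 365)))
  top <- which(cors >= max(cors) - 1e-12)
  lags[top[which.min(abs(lags[top]))]]
}

# records table for mixed-model recovery tests: known fixed effect for
# sqrt(water_temp), known site-intercept SD. With siteSd = 0 the sites are
# exact replicates, so the between-site variance component is identically
# zero and the mixed fit must degenerate to OLS.
makeDriverRecords <- function(slope = 2, siteSd = 0.5, nSites = 7L,
                              nMonths = 24L, residSd = 0.3, seed = 1L) {
  set.seed(seed)
  dates <- seq(as.Date("2013-06-01"), by = "month", length.out = nMonths)
  shared <- list(temp = runif(nMonths, 5, 26),
                 eps = rnorm(nMonths, 0, residSd))
  do.call(rbind, lapply(seq_len(nSites), function(i) {
    if (siteSd > 0) {
      temp <- runif(nMonths, 5, 26)
      eps <- rnorm(nMonths, 0, residSd) + rnorm(1, 0, siteSd)
    } else {
      temp <- shared$temp
      eps <- shared$eps
    }
    data.frame(site_id = sprintf("S%d", i), date = dates,
               water_temp = temp,
               chl_a = 1 + slope * sqrt(temp) + eps,
               stringsAsFactors = FALSE)
  }))
}
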