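# bloomwarn

Early warning of *Microcystis*-dominated cyanobacterial blooms from
chlorophyll-fluorescence lead times.

## The problem

Routine bloom surveillance relies on microscope counts of algal cells —
accurate, but far too slow to warn anyone. PAM fluorometry measures the
photosynthetic condition of the phytoplankton the same day: the maximum
quantum yield of photosystem II,

    Fv/Fm = (Fm − F0) / Fm,

taken on the blue (phycocyanin-excited) channel of a multiwavelength
fluorometer, isolates the cyanobacterial fraction. In monthly multi-site
lake monitoring, the seasonal peak of blue-channel Fv/Fm precedes the peaks
of total, cyanobacterial and *Microcystis* cell density by roughly 40 days.
`bloomwarn` turns that lead into a forecasting pipeline for limnologists
and water-supply managers running monthly monitoring programmes.

## The method

1. **Seasonal fits** — each monthly series is fit by OLS to one annual
   harmonic plus a local trend,
   `y = β0 + β1·x + β2·sin(2πx) + β3·cos(2πx) + ε`, with `x` in fractional
   years (`fitTrigonometric()`); significance optionally by a 9999-replicate
   re-randomisation (permutation) test (`rerandomizationTest()`).
2. **Lead estimation** — the lag maximising the Pearson cross-correlation
   of the two *fitted* curves on a daily grid, ±183 days, per site;
   reported as across-site mean ± SD (`crossCorrelationLag()`,
   `siteLagDistribution()`).
3. **Driver screening / density prediction** — Gaussian linear mixed models
   with a site random intercept: chlorophyll *a* vs environmental drivers
   (sqrt-transformed), and cell density vs the fluorescence curve 40 days
   earlier (`fitDriverModel()`, `fitCfparDensityModel()`).
4. **The warning rule** — threshold-plus-trend on the fitted Fv/Fm (BC)
   curve: at/above 0.28 and rising ⇒ `ELEVATED`; above but falling ⇒
   `REDUCED`; below and falling ⇒ `UNLIKELY`; below but rising ⇒ `REDUCED`
   (watch). Density ≥ 10⁷ cells/L defines a bloom
   (`classifyWarning()`, `forecastPeak()`, `predictBloom()`,
   `assessBloomRisk()`).
5. **Synthetic campaigns** — `generateDataset()` emulates the 7-site ×
   24-month design (site effects, noise, configurable injected lead) so the
   whole pipeline is testable without field data.

## Worked example

```r
library(bloomwarn)

rec    <- generateDataset(syntheticConfig())      # 7 sites x 24 months
pooled <- monthlySiteMean(rec)
fit    <- fitTrigonometric(pooled$date, pooled$fv_fm_bc, response = "fv_fm_bc")

sites <- unique(rec$site_id)
fitsA <- setNames(lapply(sites, \(s) fitTrigonometric(
  rec$date[rec$site_id == s], rec$fv_fm_bc[rec$site_id == s])), sites)
fitsB <- setNames(lapply(sites, \(s) fitTrigonometric(
  rec$date[rec$site_id == s], rec$c_total[rec$site_id == s])), sites)
est   <- siteLagDistribution(fitsA, fitsB)
model <- fitCfparDensityModel(rec, "c_total", "fv_fm_bc", lagDays = 40)

assessBloomRisk(fit, as.Date("2014-06-01"), lag = est, densityModel = model)
```

```
WarningAssessment [ELEVATED] at 2014-06-01
  Fv/Fm (BC) = 0.303, trend rising
  forecast density peak: 2014-09-26 +/- 4.0 days
  predicted density: 1.02e+07 cells/L (bloom: TRUE)
  - Fv/Fm = 0.3027 >= threshold 0.28
  - trend rising
  - level ELEVATED
  - Fv/Fm peak at 2014-08-19; density peak forecast 2014-09-26 +/- 3.958114 days
  - predicted density 1.02e+07 cells/L >= bloom threshold 1e+07
```

Reading it: the fitted blue-channel Fv/Fm stands at 0.303 — past the 0.28
threshold — and is still climbing, so bloom likelihood is `ELEVATED`. Its
seasonal peak is located at 2014-08-19; adding the estimated lead (the
pipeline recovered 38.0 ± 4.0 days against the 40 days injected into this
synthetic campaign, per-site lags 31–43) forecasts the density peak around
2014-09-26 ± 4 days. The trained density model translates the current
Fv/Fm into 1.02 × 10⁷ cells/L — at the 10⁷ bloom definition, so the bloom
flag is set. The pooled seasonal fit itself prints report-style statistics
(`adj R² = 0.994, F(3,20) = 1196.7`), and its 9999-replicate
re-randomisation test returns p = 1e-04, the smallest attainable value.

A command-line front end with `simulate` / `fit` / `lag` / `warn` /
`drivers` subcommands is installed at
`system.file("scripts", "bloomwarn-cli.R", package = "bloomwarn")`; each
takes `--in`/`--out` and an optional `--config` YAML mirroring
`analysisConfig()`.

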