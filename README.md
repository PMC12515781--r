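# cgmcompare

Comparative analysis of continuous glucose monitoring (CGM) profiles across
clinical cohorts, built around the contrast between adults after Roux-en-Y
gastric bypass (RYGB) with post-bariatric hypoglycaemia (PBH),
insulin-pump-treated type 1 diabetes (T1D), and healthy controls. The package
is aimed at biostatisticians and clinical researchers who need reproducible
consensus CGM metrics, event counting, covariate-matched cohort comparison --
and a synthetic data generator that exercises the whole pipeline when real
recordings cannot be shared.

## What it computes

For each subject, from a 10-day analysis window (earliest window of
consecutive calendar days with sensor wear >= 70%) on a nominal 5-minute
grid, stratified into the full 24 h, daytime (06:00-24:00) and nighttime
(00:00-06:00):

* **Band times** (percent of non-missing readings): TIR 70 <= g <= 180 mg/dL,
  TITR 70 <= g <= 140, TAR g > 180, TBR g < 70, level-1 range 54 <= g < 70,
  level-2 range g < 54. By construction `TIR + TAR + TBR = 100` and
  `TBR = time_L1 + time_L2`.
* **Variability**: CV = 100 * s_g / mean(g) (sample SD over mean).
* **Events**: an episode starts at the first of >= 3 consecutive readings
  beyond threshold (< 70 for L1, < 54 for L2 hypoglycaemia, > 180 for
  hyperglycaemia) and ends after 3 consecutive recovered readings, a data
  gap, or the period end; duration = readings spanned x 5 min.
* **GMI**: the glucose management indicator 3.31 + 0.02392 * mean(g).
* **Cohort comparison**: median (IQR) per metric, Shapiro-Wilk-gated Welch t
  / Mann-Whitney U tests, |SMD| effect bands (> 0.2, > 0.5), and the pooled
  daily percentile profile (per clock bin: median, 5th, 95th percentiles).
* **Matching**: logistic propensity scores on sex, age and BMI; greedy 1:1
  matching without replacement, exact on sex, choosing within the
  0.2-SD logit-score caliper by Mahalanobis distance on (age, BMI); balance
  reported as standardized mean differences (balanced when all |SMD| < 0.1).

The simulator (`simulateCohorts`) generates three 45-subject, 10-day cohorts
whose cohort-median metrics reproduce the signatures above (RYGB: normal
mean glucose with fast post-meal excursions and reactive hypoglycaemia;
T1D: elevated mean, high day-and-night variability; healthy: tight control),
with multiplicative AR(1) sensor noise calibrated to a mean absolute
relative difference (MARD) of ~9% against the latent glucose.

## Worked example

```r
library(cgmcompare)

sim <- simulateCohorts(simConfig(seed = 1))        # 3 x 45 subjects, 10 days
panels <- do.call(rbind, lapply(cohorts(sim), cohortMetricPanel))
ov <- panels[panels$period == "overall", ]
round(sapply(split(ov$mean_glucose, ov$cohort), median), 1)
#> HEALTHY    RYGB     T1D
#>    98.0   107.0   136.8
round(sapply(split(ov$cv, ov$cohort), median), 1)
#> HEALTHY    RYGB     T1D
#>    16.9    29.7    31.3
sapply(split(ov$n_l1_events, ov$cohort), median)
#> HEALTHY    RYGB     T1D
#>       6      14       8
```

The RYGB cohort sits between the other two: near-normal average glucose
(~107 mg/dL) but variability (CV ~30%) approaching the T1D cohort and the
highest frequency of level-1 hypoglycaemic episodes -- the PBH signature.
`buildReport(panels)` turns the panels into the 14-metric median (IQR)
comparison table with effect flags and p-values, and `runPipeline()` runs
simulation/ingestion, eligibility, matching, metrics and reporting end to
end from one configuration.

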