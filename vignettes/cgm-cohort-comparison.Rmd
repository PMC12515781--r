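---
title: "Comparing CGM profiles across cohorts: methods and design"
author: "cgmcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing CGM profiles across cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmcompare)
```

## The analytical problem

Continuous glucose monitoring samples interstitial glucose every five
minutes for days at a time. After Roux-en-Y gastric bypass (RYGB), altered
gut anatomy accelerates glucose absorption: meals produce fast, tall
excursions followed by reactive undershoots that can reach hypoglycaemic
levels (post-bariatric hypoglycaemia, PBH). Interpreting such traces against
thresholds designed for diabetes is misleading; the informative comparison
is against sex-, age- and BMI-matched healthy controls on one side and
insulin-treated type 1 diabetes (T1D) on the other. This package implements
that comparison as a reusable, tested pipeline: eligibility filtering,
consensus metrics, event detection, day/night stratification, propensity
matching with balance reporting, and cohort-level testing -- plus a
three-archetype simulator so every stage can be exercised and validated
without access to patient data.

## Data model and eligibility

A `CgmTrace` holds one subject's readings on a nominal 5-minute grid;
gaps are absent slots, never `NA`s. On ingestion timestamps are snapped to
the nearest grid slot (every timestamp is within half an interval of a
slot, so snapping drops nothing), duplicate slots keep the first
occurrence, and glucose is clipped to the reportable sensor span of
40--400 mg/dL with a clip counter in the parse report.

The analysis window is the *earliest* run of 10 consecutive calendar days
whose wear fraction (observed readings over nominal slots, 2880 for 10
days) is at least 0.7, threshold inclusive. Earliest-start is a convention
-- the eligibility rule does not pin down which window -- chosen because it
is deterministic and reproducible; it is recorded in the run manifest.
Daytime is the half-open clock interval [06:00, 24:00) and nighttime
[00:00, 06:00), so the two partition each day exactly and
`|day| + |night| = |overall|` holds for every trace.

## Metric conventions

Band boundaries are closed below and open above: TIR is 70 <= g <= 180
mg/dL, TITR 70 <= g <= 140, TAR g > 180, TBR g < 70, the level-1 range
54 <= g < 70 and the level-2 range g < 54. These choices make the
identities `TIR + TAR + TBR = 100` and `TBR = time_L1 + time_L2` exact,
which the test suite asserts on random traces. All percentages use
non-missing readings in the period as denominator, so wear gaps do not
deflate them.

An event starts at the first of at least three consecutive readings
strictly beyond the threshold. The consensus start rule says nothing about
termination; we end an event after three consecutive recovered readings
(15 minutes), at a data gap wider than one interval, or at the period end,
and absorb shorter interior recoveries into the event. Duration is the
number of readings spanned times five minutes (not clock time across
gaps), so a gap can never inflate a duration. Runs that deepen below 54
count as both a level-2 and a level-1 event (`l1IncludesL2 = TRUE`; the
stricter pure-L1 convention is available in `metricConfig()`).
Hyperglycaemic events use the same rule above 180 mg/dL. Events are
detected once on the full windowed trace and assigned to day or night by
the period of their first reading, full duration credited there -- a
detector run on the stitched day-only subset would hallucinate runs across
the nightly seams.

The glucose management indicator uses the published linear map
`GMI = 3.31 + 0.02392 x mean glucose`.

## Group comparison

Per-subject metric distributions are summarized as median and IQR
(linear-interpolation quantiles, R type 7 -- the convention matters at
n = 45). Two-group tests are gated on normality: Shapiro-Wilk at alpha
0.05 on each sample; only if both pass is the Welch unequal-variance t
test used, otherwise the Mann-Whitney U test (exact for small tie-free
samples, tie-corrected normal approximation otherwise). P-values are
two-sided, significance at 0.05, and deliberately unadjusted for multiple
testing: the report mirrors a per-metric descriptive table, and its footer
says so. Effect sizes are absolute standardized mean differences banded at
0.2 and 0.5. The daily profile pools all readings of a cohort by 5-minute
clock bin and reports per-bin median and 5th/95th percentiles.

## Propensity matching

Comparison cohorts are matched 1:1 without replacement to the fixed RYGB
reference, independently per comparator (the reference cohort size is what
must be preserved). The propensity model is a logistic regression on age,
sex and BMI, fit by IRLS (tolerance 1e-8, 100 iterations maximum);
continuous covariates are standardized internally and coefficients
back-transformed, so a single binary covariate recovers its log odds
ratio exactly.

`matchNearest()` is the textbook greedy matcher: descending reference
score order (protecting hard-to-match subjects), nearest available pool
subject on the logit-score scale, lexical tie-breaks, optional caliper of
0.2 SD of the logit scores. Two refinements were adopted for the default
high-level matcher `propensityMatch()` after simulation showed the bare
score matcher cannot deliver reliable balance at these sample sizes:

* **Exact sex matching.** With similar sex proportions in reference and
  pool the sex coefficient is near zero, the score carries almost no sex
  information, and the matched subset's sex composition is a random draw
  whose SMD has standard deviation ~0.15 at n = 45 -- balance on sex would
  fail in a third of runs no matter how good the score match. Matching
  within sex strata fixes the sex SMD at exactly zero, and reproduces the
  design in which all three cohorts have an identical 36 F / 9 M
  composition.
* **Mahalanobis metric within propensity calipers.** Selecting candidates
  by score alone leaves per-covariate residual imbalance (age SMD mean
  ~0.11 on pools shifted +8 y / -2 kg/m2); selecting, among same-sex
  candidates inside the score caliper, the pool subject nearest in
  Mahalanobis distance on (age, BMI), and rejecting pairs farther than
  0.5, brings the mean maximum |SMD| to ~0.04 and achieves balance
  (all |SMD| < 0.1) in ~99 of 100 replicates. This is the classic
  caliper-matching recommendation; its cost is attrition (a median of ~25
  of 45 reference subjects retain a pair on such shifted pools), which is
  the honest price of near-certain balance and is reported via the
  unmatched list and the run manifest.

## The simulator: what it emulates, and what not

Each subject's latent glucose is

* a circadian basal sinusoid (24-h period, minimum near 03:00),
* bi-exponential meal-excursion kernels at jittered daytime meal times
  (three main meals, an optional afternoon snack), with archetype-specific
  peak heights and rise/fall constants,
* for undershoot-prone archetypes, a delayed negative kernel after meals
  (the PBH mechanism: insulin overshoot after rapid absorption),
* smooth AR(1) physiological wander, plus for the T1D archetype an extra
  nocturnal instability component active 00:00--06:00,
* a soft counterregulatory floor near 45 mg/dL (softplus), which both
  reflects the physiological defence of glucose and guarantees latent
  traces are never clipped at the sensor span.

The sensor trace adds multiplicative AR(1) noise (lag-1 correlation 0.7)
whose stationary SD is set so that E|relative error| equals the 9% MARD
target, then rounds to integer mg/dL and clips to [40, 400]. Wear gaps are
injected as geometric bursts (mean 6 slots) totalling exactly 7% of slots,
keeping every subject above the 0.7 eligibility threshold. Covariates:
age ~ N(48, 14) truncated to 18--80, BMI per cohort near the clinical
means (26.7/25.5/27.4, SDs 5.2/2.8/6.1), sex exactly 36 F / 9 M per
matched cohort of 45; the confounded scenario draws comparison pools four
times larger with age shifted +8 years and BMI -2 kg/m2 for matching
studies.

Archetype defaults were calibrated once by coarse search so that
45-subject, 10-day cohort medians land on the clinical signatures (RYGB
mean glucose ~108 mg/dL with CV ~30% and ~12 L1 events per 10 days,
healthy mean ~98 with CV ~17 and TIR ~98%, T1D mean ~139 with CV ~32 and
TAR ~16%), then frozen; they are part of the package contract and are not
analysis-time dials. What the simulator does *not* emulate: true
glucose-insulin dynamics (no ODEs), meal composition, exercise,
sensor-specific artefacts (compression lows, calibration jumps), or the
worse relative accuracy of real sensors below 70 mg/dL -- noise is
proportional to glucose at all levels. Passing tests on synthetic cohorts
therefore demonstrate the correctness and calibration of the *analysis*,
not device behaviour or physiology beyond the modelled mechanisms.

```{r example}
sim <- simulateCohorts(simConfig(nSubjects = 6, nDays = 3, seed = 42))
sim
panels <- do.call(rbind, lapply(cohorts(sim), cohortMetricPanel))
head(panels[panels$period == "overall",
            c("subject_id", "cohort", "mean_glucose", "cv", "tir",
              "n_l1_events")])
```

## Numerical choices and degenerate inputs

* Quantiles: linear interpolation (type 7) everywhere.
* `wearFraction` of a window disjoint from the trace is 0, not an error;
  an ineligible subject raises a typed condition carrying the best
  achievable wear fraction.
* An empty period ("no data in period") is an error, never a silent 0;
  CV requires at least two readings.
* SMD with zero pooled variance is 0 when means agree and an error
  otherwise; identical samples in a two-group test give p = 1 with a
  warning.
* Event durations for subjects with no events are `NA` and are summarized
  over event-experiencing subjects only, as in clinical tables.
* The master seed fans out to per-subject seeds by stable hashing of the
  subject id, so adding a subject never perturbs the others' traces, and a
  fixed configuration reproduces byte-identical pipeline outputs.
* Problem sizes used in the validation suite (10^4-trace property checks,
  2000-replicate type-I calibration, 100-replicate matching recovery,
  45-subject cohort calibrations) were chosen to make Monte-Carlo error
  small relative to the tolerances being asserted.

## Known limitations

Clock times are naive local time on a UTC-like axis: daylight-saving
transitions and travel are out of scope. Device-native export formats are
not parsed; ingestion expects the long CSV dialect. The matcher is greedy,
not optimal assignment, and with heavily shifted pools retains only the
well-overlapped part of the reference. Hyperglycaemic events have no
level-2 (>250 mg/dL) split, and variability indices beyond CV (MAGE, MODD,
LBGI/HBGI) are not computed.
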