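---
title: "Methods: re-classifying non-response to wasting treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: re-classifying non-response to wasting treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cmamnr` implements a pooled-analysis methodology for longitudinal
anthropometry from community-based management of acute malnutrition
(CMAM) programmes. Its scientific claim is that children discharged as
"non-responders" — those who never reached MUAC ≥ 125 mm or
weight-for-height z-score (WHZ) ≥ −2 within the programme's maximum stay
— are not one group: most grow along a trajectory parallel to the
children who recover, just starting lower, while a minority show
essentially no MUAC or weight growth at all. The pipeline makes that
distinction operational and testable. This vignette records the model
choices, their defaults, and the reasoning behind the decisions that were
genuinely open.

## 1. Z-scores and the LMS reference

Z-scores use the LMS method: for measurement $x$ with reference Box-Cox
power $L$, median $M$ and coefficient of variation $S$,
$z = ((x/M)^L - 1)/(LS)$, or $\log(x/M)/S$ when $L = 0$. Lookup between
tabulated keys (age in days for WAZ/HAZ/MUACZ at 30.4375 days per month;
length/height in mm for WHZ) is linear; keys outside the tabulated range
yield missing values and are counted, not errored, because out-of-range
children are a data property, not a caller mistake.

For the weight-based indicators (WHZ, WAZ, MUACZ) the WHO computation
replaces values beyond ±3 SD by a "restricted" value measured in units of
the gap between the ±2 and ±3 SD bounds. Whether the original pooled
analysis applied this adjustment is not documented; we default it **on**,
matching the reference z-scoring implementations used in this field, and
expose `restricted = FALSE` to turn it off. The round-trip identity
(`lms_invert()` after `lms_zscore()`) holds exactly whenever the
adjustment does not fire.

The bundled reference, `synthetic_lms_reference()`, is **synthetic**: a
set of smooth, monotone, sex-specific curves anchored at field-plausible
medians, with the weight-for-age median derived by composing the
height-for-age and weight-for-length medians so that the three references
are mutually consistent. It exists so that the pipeline is fully
exercisable and testable without external files; it is not the WHO 2006
standard, and real analyses should load the WHO tables with
`read_lms_reference()`. Everything downstream is agnostic to which
reference is supplied.

## 2. Cleaning

Three layers, in a fixed order, each blanking values (never deleting a
visit that still holds any measurement) and appending to an audit trail:

1. **Plausibility bounds** per visit: height/length outside 60–120 cm,
   MUAC outside 70–200 mm, weight outside 3.5–40 kg.
2. **Pooled Tukey fences** on each z-score indicator: values outside
   $[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]$, $k = 1.5$ by
   default. Fences are computed on the pooled dataset (the analysis pools
   studies), configurable. Only the z-score is blanked — the outlier
   decision is made on the z scale, and blanking the raw measurement
   would also destroy the other indicators it feeds.
3. **Longitudinal consistency** within child: any height/length decrease
   blanks the later height; changes beyond ±1.5 kg (weight), ±15 mm
   (MUAC) or +1.5 cm (height) per week blank the later value.

Open points we had to decide:

* *Which of the two visits to blank.* The later one, always: admission
  measurements anchor every gain computed downstream, so the admission
  visit must stay authoritative.
* *Non-weekly gaps.* The thresholds are stated per week; for a gap of $g$
  weeks we allow $g$ times the threshold, with $g$ capped at 4 (beyond a
  month, a large change is plausible growth, and scaling further would
  stop the rule from ever firing). Gaps under a week use the one-week
  threshold.
* *Idempotence.* Removing an outlier changes the quartiles, and blanking
  a z-score changes the pool the fences are estimated on, so a naive
  single pass is not a fixed point. `clean_visits()` therefore iterates
  the fence estimation (and its interplay with the longitudinal stage) to
  convergence; a second call to `clean_visits()` is guaranteed to change
  nothing, which the tests assert. The price is slightly more aggressive
  trimming than a single Tukey pass; with $k = 1.5$ the iteration
  converges in one or two rounds on realistic data.
* Visits recording no anthropometry at all are dropped (and counted)
  before the rules run; visits emptied *by* the rules are dropped at the
  end, which keeps the pass idempotent.

## 3. Exit re-classification

Study-assigned `recovered` and `non_responder` labels are respected.
Children with oedema at admission are excluded (their fluid retention
confounds weight- and MUAC-based indices), as are deaths and medical
transfers. Defaulters and unknowns with at least 12 weeks of follow-up
(length of stay = `floor(days/7)`, "at least 12" meaning ≥ 12) are
re-classified from their exit anthropometry: recovered if at least one
recovery criterion is met (exit MUAC ≥ 125 mm or WHZ ≥ −2) with no
oedema and no observed criterion of severe wasting (MUAC ≥ 115 mm and
WHZ ≥ −3); non-responder if every observed indicator is below both
recovery thresholds.

The two published rules do not partition all cases: a child with exit
MUAC 126 mm but WHZ −3.4 satisfies neither. We exclude such children as
unclassifiable rather than forcing them into either group — the recovery
rule requires the absence of any severe criterion, and the non-responder
rule requires both indicators below threshold, so both definitions
genuinely decline the case. A missing indicator cannot satisfy a
criterion and does not veto one (many programmes measure only MUAC at
late visits). Exit values are taken per indicator from the last visit
with a non-missing value, so MUAC and WHZ may come from different final
visits.

## 4. The first-quartile split

Admission-to-exit gains are computed per indicator (admission value = the
admission visit's value; exit = last non-missing). The split threshold is
the 25th percentile of the pooled non-responder gains under the
linear-interpolation quantile rule (`stats::quantile` type 7). The
convention matters only in small samples, and the original choice is
undocumented, so it is exposed as a parameter. Ties at the threshold go
to high growth, matching the published "≥ threshold is high growth"
reading. MUAC gain is the default split indicator — it is the
measurement CMAM programmes most commonly track, and the published
exploration continued with it after finding the choice of indicator
immaterial to the curve shapes.

Note one discreteness effect the tests make explicit: with gains recorded
in whole millimetres, many children tie exactly at the threshold, and
because ties go high, the realised low-growth fraction can fall visibly
below 25%. On continuous gains it converges to 0.25.

## 5. Growth-trajectory model

Per response group we fit penalized-spline mean curves over weeks since
admission (`floor(days/7)`) with mgcv:

```{r}
y ~ group + s(week, by = group, bs = "ps", k = 12, m = c(2, 2)) +
  s(child_id, bs = "re")        # + age_adm_months for MUAC and weight
```

Cubic P-splines with a second-difference penalty leave straight-line
trends unpenalized (the tests verify noiseless linear group means are
reproduced to numerical precision), group-specific smooths give each
category its own curve, and the child-level random intercept absorbs the
repeated-measures clustering as a ridge-penalized effect. Random slopes
were deliberately not included: the published description says only
"clustering at the individual level", and the group-by-time smooths
already carry the trajectory differences the analysis is about.

Smoothing parameters are selected by GCV by default (REML optional); with
more than 400 children the fit switches to `mgcv::bam(discrete = TRUE)`
with fast REML, which is the standard mgcv route once the random-effect
factor has thousands of levels. Basis dimension (default 12, roughly ten
interior knots at week quantiles) shrinks automatically, with a warning,
when a group has fewer distinct weeks. Confidence bands are pointwise
Wald intervals from the penalized coefficient covariance, evaluated at
the population level (random intercept excluded, admission age fixed at
its mean for age-adjusted outcomes). Predictions outside the observed
week range are refused rather than extrapolated, mirroring the bounded
axes of the published trajectory figures.

## 6. Multinomial prediction model

The three-category outcome (reference: recovered) is modelled by
baseline-category multinomial logistic regression, written in-package
because the estimator itself is part of the method's contract: full
Newton–Raphson on the multinomial log-likelihood with step-halving
(the log-likelihood is asserted non-decreasing), convergence when the
largest score component is below 1e-8 (at most 100 iterations), and
standard errors from the inverse observed information. For a single
categorical predictor the MLE reproduces the closed-form contingency
odds ratio to 1e-6, which is both a test and the bridge to the published
univariate tables. Diverging coefficients with a vanishing score — the
signature of separation, e.g. an empty predictor-by-outcome cell — flag
the fit as non-converged rather than reporting meaningless estimates.

The multivariate covariate set is fixed to: sex, age band, admission
MUAC band, admission WHZ and WAZ bands, any reported morbidity, and the
first-month no-gain flags. "No gain in the first month" is gain ≤ 0
between admission and the visit closest to day 28 within days 21–42; a
child with no visit in that window gets a missing flag (the window is
our choice; the original definition is not stated). Collinearity is
screened with VIFs (`1/(1 - R_j^2)` over the dummy-encoded design,
flagging ≥ 1.5); missing covariates imply complete-case analysis with
counts logged. Accuracy is in-sample argmax accuracy; multiclass AUC
defaults to the Hand–Till pairwise one-vs-one average (a one-vs-rest
macro average is available) because the published single AUC figure does
not name its construction.

## 7. The synthetic cohort generator

The generator exists because the 14 source datasets are not public.
It emulates the study conditions rather than any single dataset:

* **Classes**: recovering (86%), delayed responder (10%), non-grower
  (4%) — matching an overall non-responder share near 10% before
  re-classification, three quarters of them delayed.
* **Admission anthropometry**: MUAC centred at 121/111.5/120 mm for the
  three classes (truncated normals, SD 6–6.5 mm chosen so the realised
  medians sit on the published group medians of 120/111/120 mm and all
  four admission MUAC bands are populated in roughly the published
  proportions); WHZ centred at −2.4/−3.0/−2.9; HAZ at −2.7 (SD 1.1);
  ages log-normal with median 17 months, truncated to 6–59.
* **Trajectories**: monotone saturating exponentials in MUAC and WHZ
  (the shape of the published group curves): recovering children plateau
  above the discharge thresholds, delayed responders on the same shape
  plateau just below, non-growers stay flat. Height follows a slowly
  rising height-for-age track in every class, and true weight is derived
  from the true WHZ at the true height through the LMS reference — so
  the pipeline's z-scoring recovers the planted z-scores up to noise,
  and the three references stay mutually consistent.
* **Observation model**: measurement noise at
  technical-error-of-measurement scale (MUAC 2 mm, weight 0.15 kg,
  height 0.4 cm), values rounded to field precision (1 mm / 0.01 kg /
  0.1 cm); weekly visits; geometric weekly dropout (hazard 0.01,
  class-independent by default); 20% oedema at admission (the pooled
  cohort's share), generated only to exercise the exclusion branch; 5%
  of completer labels recorded as `unknown` to exercise
  re-classification.
* **Exit labels**: discharge as recovered on two consecutive qualifying
  visits (MUAC ≥ 125 mm or observed WHZ ≥ −2), checked from week 4
  (programmes treat for a minimum period before discharging); dropouts
  are defaulters; completers reaching week 16 without qualifying are
  non-responders.

What the generator does **not** emulate: between-study heterogeneity in
protocols and visit schedules, informative (class-dependent) dropout by
default, mortality, oedema-specific growth, or the morbidity–growth
feedback of real cohorts (morbidity is class-conditional noise, not a
cause). A green synthetic-recovery test therefore shows the pipeline
correctly inverts its own generating assumptions — planted classes are
recovered with ≥ 90% agreement on a low-noise cohort of 2,000, degrading
monotonically with noise — not that real cohorts are this clean.

## 8. Problem sizes and numerical choices

The test and verification runs use cohorts of 300–2,000 children
(10,000 for the distributional checks on the generator alone), 300
children × 12 weeks for the planted-curve recovery benchmark (fitted
curve RMSE < 1 mm against the generating function at noise SD 2 mm), and
1,000 replicates of n = 500 for the Wald size calibration — sizes at
which every property under test is already stable. Quantiles use type 7
throughout; Newton iterations start from zero coefficients; the Tukey
fence multiplier, delta thresholds, gap cap, minimum re-classification
stay, split indicator and quantile type are all config-exposed with the
defaults above.

Headline numbers that depend on the original pooled data — the 9.6%
non-responder share, the published per-indicator Q1 thresholds (2 mm
MUAC, 0.4 kg weight, 0.6 g/kg/day, 0.5 WAZ, 0.0 WHZ), the 87.7% model
accuracy and 74.1% AUC — cannot be recomputed from synthetic data and
are carried as documented reference constants (`reference_values()`).
What *is* recomputed, exactly, are the published univariate odds ratios,
which derive entirely from printed group-by-level counts
(`pooled_reference_counts()`): the package's multinomial estimator
reproduces all of them to the printed two decimal places
(`scripts/acceptance.R`).

## Known limitations

* The bundled LMS reference is synthetic; absolute z-score values from it
  are internally consistent but not WHO values.
* The generator's discharge rule uses observed (noisy) measurements, so a
  small fraction of delayed responders is discharged as recovered near
  the thresholds — realistic, and visible as most of the residual
  disagreement in the class-recovery tests.
* Penalized-spline confidence bands are conditional on the selected
  smoothing parameters; smoothing-parameter uncertainty is not
  propagated.
* The multivariate model needs enough children in every
  predictor-by-outcome cell; at a few hundred children the rare
  low-growth category can separate, which the fit flags rather than
  hides.
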