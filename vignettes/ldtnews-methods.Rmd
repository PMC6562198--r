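---
title: "Methods: the LDTEWS:NEWS risk index and its evaluation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the LDTEWS:NEWS risk index and its evaluation machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldtnews)
```

## The model

Hospital ward patients are monitored through two asynchronous channels:
vital-sign observation sets, taken every few hours and summarised by the
National Early Warning Score (NEWS, an integer 0–20), and routine blood
tests, taken roughly daily and summarised by the Laboratory Decision Tree
Early Warning Score (LDT-EWS, an integer 0–15 over seven analytes:
albumin, creatinine, haemoglobin, potassium, sodium, urea and white cell
count). The combined *risk index* blends the two on a common 0–1 scale
with a weight on the laboratory component that decays linearly with the
age of the most recent laboratory result:

$$
\mathrm{index} \;=\; \omega\,\frac{\mathrm{LDTEWS}}{15}
  \;+\; (1-\omega)\,\frac{\mathrm{NEWS}}{20},
\qquad
\omega \;=\; \beta\left(1-\frac{\min(t, 120)}{120}\right),
$$

where $t$ (`time_since_labs`) is the time in hours since the most
recently received laboratory result among the linked analytes, capped at
120 h (5 days). Fresh bloods receive the full coefficient $\beta$; at or
beyond the horizon the index reduces exactly to NEWS/20. With the
development-phase value $\beta = 0.26$, the laboratory share of the index
therefore ranges over 0–26 % and the vital-signs share over 74–100 %;
these bounds are verified analytically in the test suite and recomputed
by `scripts/acceptance.R`.

The index is recomputed only at vital-sign observation times
(event-driven), never between observations. All index arithmetic is
double precision; a 3-decimal rounding is applied for display only.

## Scoring tables

Both component scores are table-driven (`default_scoring_table()`,
`read_scoring_table()`). Numeric variables are banded into half-open
lower-inclusive intervals $[\ell, u)$; a value lying exactly on a printed
integer cut-off scores in the higher-risk band, a conservative choice for
a safety score that is resolved once at transcription time. Temperature
is banded at 0.1 °C resolution; no other input is rounded before
banding. `validate_scoring_table()` checks that each variable's bands
tile the real line without gaps or overlaps and that the worst-band sums
equal the declared maxima of 20 and 15.

The shipped NEWS half is the Royal College of Physicians NEWS (2012)
weighting. The LDT-EWS half is a **reconstruction**: the original
decision-tree cut-offs are not reproduced here, so the shipped bands use
standard adult reference-range limits, with sex-specific cut-offs for
haemoglobin and creatinine (the two analytes with clearly sex-dependent
reference ranges) and per-analyte maximum weights (albumin 3, urea 3,
sodium 2, potassium 2, white cell count 2, haemoglobin 2, creatinine 1)
chosen so the attainable aggregate equals the declared maximum of 15.
Users holding the original cut-offs can supply them as a YAML file; every
scoring path in the package is driven by the table, not by code.

Consciousness recorded as a Glasgow Coma Scale total is converted to the
AVPU scale with the configurable default 15 → A, 13–14 → V, 9–12 → P,
3–8 → U (`gcs_to_avpu()`).

## Linkage and missing data

Laboratory results are attached to an admission if received between the
start of the day before admission (capturing emergency-department bloods
for patients admitted overnight) and the end of the day of discharge;
"days" are local calendar midnights, and timestamps are naive local
clock times at minute resolution. At each observation time the most
recent value of each analyte is carried forward, subject to the 120 h
horizon. Three conventions fix the edge cases: results received strictly
after the observation time are never used (no look-ahead); a result
received at exactly the observation time counts with age 0; and an
analyte older than the horizon is treated as absent *both* for scoring
(it contributes weight 0, like a never-measured analyte) and for
`time_since_labs` (which is then the minimum over the remaining
analytes, or 120 when none remain). Ages are computed in exact
real-valued hours from the received-by-laboratory timestamp. If two
results for the same analyte share a timestamp, the row appearing later
in the input wins.

## Cohort construction and outcomes

The analysis cohort keeps emergency admissions of adults (≥ 16 years) to
qualifying higher-risk medical specialties with at least one complete
vital-sign set, then excludes (a) admissions discharged alive before the
first midnight after admission and (b) admissions with no vital signs in
the 24 h before the earliest of ICU admission, discharge or death — a
proxy for end-of-life pathways. Exclusion (b) is measured from the event
time minus 24 h, not from a midnight boundary. Audit counts attribute
each exclusion to the first failing criterion so the flow table sums
exactly.

Each observation set is labelled with the primary outcome — the first of
in-hospital death or unanticipated ICU admission within 24 h — and with
each event separately. The window is half-open, $(t, t+24\,\mathrm{h}]$:
an event at exactly +24 h counts. Observation sets recorded at or after
the first event are dropped from evaluation, since the patient is no
longer at risk on a ward. The qualifying-specialty list is configuration
data; the synthetic generator uses a single qualifying specialty code.

## Fitting the decay coefficient

`fit_beta()` estimates $\beta$ by grid search over 0.01–0.99 in steps of
0.01. Admissions are split into 10 random folds (admission-level, so all
observations of one admission share a fold and no within-admission
leakage occurs; folds are not stratified on outcome). For every grid
value the risk index is computed on each fold's observations and that
fold's AUROC against the primary outcome recorded; the fitted
coefficient maximises the mean AUROC across folds, with ties broken
towards the smallest value. Because $\beta$ is the only fitted quantity
there is no per-fold training step; the partitioning controls the
variance of the selection. A fold containing a single outcome class
makes its AUROC undefined and raises an error suggesting more data or
fewer folds.

## Discrimination, calibration and thresholds

The c-statistic is the Mann–Whitney concordance — the probability that a
randomly chosen event-positive observation outscores a randomly chosen
negative one, ties counted one half — computed via midranks, and its
confidence interval uses the DeLong variance estimate with a normal
approximation clipped to $[0,1]$ (the default method of the standard ROC
packages; `pROC` serves as an independent cross-check in the test
suite). When every score is identical the variance degenerates and the
interval is reported as the full unit interval with a flag. ROC curves
return one point per distinct threshold under the "flag when score ≥
threshold" convention, so the trapezoidal area reproduces the
c-statistic exactly.

Calibration is assessed by binning the index into equal-width bins
(default width 0.05 — the index is continuous, so "each possible value"
is operationalised as a bin) and comparing per-bin observed event rates
with mean predicted risk. `matched_specificity_threshold()` compares a
new score with an incumbent trigger level (e.g. NEWS ≥ 5 or ≥ 7) by
finding the smallest threshold on the new score whose specificity is at
least the incumbent's, reporting sensitivity, specificity, PPV and NPV
for both; an unattainable specificity is reported at the
maximum-specificity threshold with a flag.

## The synthetic cohort generator

No public admission-level EHR data exist for this problem, so
`simulate_cohort()` generates cohorts that emulate the *structure* of
emergency medical admissions: lognormal ages centred near a median of
73 (IQR roughly 57–83), ~49 % male, right-skewed length of stay with
median ≈ 3.7 days, vital-sign sets at lognormal intervals (median 6 h),
laboratory panels roughly daily with probability 0.9 on the admission
day declining by a factor 0.75 per day (plus possible
emergency-department bloods received up to 10 h before admission), 8 %
per-analyte dropout within a panel, and 20 % of observation sets
recording consciousness as a GCS total. Small fractions of under-16,
elective and non-qualifying-specialty admissions exercise the cohort
filters.

Each admission carries **two** correlated latent severity components,
each a slow reflected Gaussian random walk on `[0, 1]`: one read by the
vital-sign channel and one by the laboratory channel (by default the
laboratory severity is 15 % the vitals component and 85 % an
independent walk). This reflects the clinical reality that biochemical
derangement and haemodynamic instability are related but distinct — and
it is what makes the decay coefficient identifiable in recovery
experiments: if both channels were monotone reads of a single scalar,
any mixing weight would produce nearly the same risk ranking and the
grid search would have a flat, drifting objective. Monotone maps take each severity into every vital sign and analyte, so
higher severity occupies higher-weight bands in both scores.
Measurement noise on the vital signs is persistent rather than
independent per observation — an AR(1) process per channel, a single
oxygen-therapy propensity per admission, and a per-admission
consciousness offset — reflecting that observation context (device,
observer, therapy in progress) carries over between rounds. Persistence
matters for coefficient recovery: outcome labels attach to every
observation within 24 h of an event, so if vitals noise were
independent per observation while laboratory values are carried forward
unchanged, the laboratory term would predict neighbouring observations'
labels better than the vitals term and bias the recovered coefficient
upward.

Events are generated from a per-observation Bernoulli hazard,
$p = \operatorname{logit}^{-1}(a + b\,x)$, where the risk driver $x$ is
the normalised NEWS aggregate by default, or — in the
planted-coefficient mode — the combined risk index computed with a
chosen $\beta^\*$ through the package's own linkage, scoring and decay
code. The first observation whose draw fires places the event uniformly
in the following 24 h; deaths truncate the stay and unanticipated ICU
admissions end ward observation. The hazard is deliberately steep
($b = 22$) so that outcome labels carry a strong signal about the
planted index. The two drivers live on slightly different scales (the
combined index down-weights its ingredients relative to NEWS/20), so
each mode carries its own intercept ($a = -15.4$ for the NEWS driver,
$-14.6$ for the planted index), both calibrated once, by pilot
simulation, so that either mode lands near the cohort targets of
≈ 4.8 % in-hospital mortality and ≈ 1.1 % unanticipated ICU admission.
All of these are ordinary configuration fields.

Randomness is organised as one master stream split by admission index,
so enlarging a cohort leaves earlier admissions byte-identical — stable
fixtures for tests. What the generator does *not* emulate: laboratory
turnaround lag, per-analyte ageing differences, temporal trends,
disease-specific patterns, or the measurement-noise structure of real
observations beyond the persistence structure described above. Passing
tests therefore demonstrate that the grid search finds a planted decay
coefficient under these conditions — not that $\beta = 0.26$ is optimal
for any real hospital's data.

## Problem sizes and numerical choices

The test suite exercises the scoring oracle equivalence on thousands of
random inputs, the concordance oracle on 100 random instances of up to
500 observations, the binormal closed-form AUROC limit at $10^5$ scores,
and the recovery experiment on 20 seeded replicates of 2,000-admission
cohorts — sizes chosen so the full suite runs comfortably on a single
CPU while keeping Monte-Carlo error well inside the asserted tolerances.
Determinism is enforced end-to-end: identical seeds and configurations
produce identical tables, manifests and fitted coefficients.

## Known limitations

The LDT-EWS bands are a reconstruction (see above); absolute aggregate
values are not comparable with deployments using the original cut-offs,
though every structural property (maxima, monotone banding, zero-scoring
of absent analytes) is preserved. The generator does not model
laboratory turnaround lag (collection-to-report time), per-analyte decay
horizons, temporal trends, specific diseases, or inter-hospital case-mix
differences, and real-data discrimination figures cannot be reproduced
without hospital EHR access. Daylight-saving clock shifts are out of
scope: timestamps are naive local times.
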