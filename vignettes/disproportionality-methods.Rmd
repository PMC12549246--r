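---
title: "Disproportionality methods and the synthetic report model"
author: "faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods and the synthetic report model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event (AE) reporting databases collect suspected
drug–event associations without an exposure denominator, so absolute risks
cannot be estimated. Signal detection instead asks whether a drug–event
pair is reported *disproportionately* often relative to the database
background. `faersignal` implements that analysis for FAERS-dialect
quarterly ASCII extracts, together with the supporting stages a real
analysis needs (deduplication, cohort selection, MedDRA mapping, onset
modelling, stratification, outcome tabulation) and a synthetic data
generator so the whole pipeline can be exercised and validated offline.

## Counting convention

All four statistics operate on a 2×2 table of **unique (case,
preferred-term) event pairs**, not of reports: `a` = pairs in the
target-drug cohort involving the term, `b` = the cohort's other pairs,
`c`/`d` the same split among all non-cohort cases, and `N = a+b+c+d` the
database's total pair count at the analysis level. At SOC level a case
contributes once per distinct system organ class. This pair-level
denominator convention is what reproduces published FAERS tables whose
database total is an AE count in the tens of millions rather than a report
count; the package's `reconstruct_contingency()` exploits it to rebuild a
published row's full table from its printed margins (a, the drug's pair
total, N, and the printed PRR) so that every other statistic of the row can
be recomputed and checked.

Duplicate preferred terms within a case collapse to one pair, and PT
strings are whitespace-normalized and sentence-cased before comparison,
because reaction capitalization in raw extracts is inconsistent.

## The four estimators and their thresholds

* **ROR** `= ad/(bc)`, CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
  flagged when the lower bound exceeds 1. Undefined (reported as a
  sentinel, never continuity-corrected) when any cell is zero; a Haldane
  0.5-correction would change published values, so it is deliberately not
  applied.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with CI
  `exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))` and the
  *uncorrected* χ² `= N(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]` (a Yates
  correction does not reproduce published χ² values); flagged when
  PRR ≥ 2 and χ² > 4.
* **BCPNN IC** `= log2[aN/((a+b)(a+c))]`, the observed-count information
  component without Bayesian shrinkage of the point estimate, with the
  normal-approximation credible bound
  `IC025 = IC − 3.3·a^(−1/2) − 2·a^(−3/2)`; flagged when IC025 > 0. The
  shrunken (expectation-based) IC variant differs noticeably at small `a`;
  the observed-count form is the one that matches published SOC-level
  tables to ±0.02.
* **MGPS / EBGM**: the relative reporting rate λ of each pair has prior
  `w·Gamma(α₁, β₁) + (1−w)·Gamma(α₂, β₂)` and `a | λ ~ Poisson(λE)` with
  `E = (a+b)(a+c)/N`. Marginally `a` is a two-component negative-binomial
  mixture; the hyperparameters are fitted by maximizing the summed log
  marginal likelihood over all pairs with multi-start BFGS on
  log/logit-transformed parameters (a fixed start set plus seed-derived
  jittered starts, so the fit is deterministic). The posterior is again a
  two-gamma mixture with components `Gamma(αⱼ+a, βⱼ+E)`;
  `EBGM = 2^E[log2 λ | a]` is evaluated through the digamma function and
  EBGM05 by bisection on the posterior CDF to 10⁻⁶. Flagged when
  EBGM05 > 2. With fewer than 50 usable pairs the conventional default
  prior (0.2, 0.1, 2, 4, w = 1/3) is used and logged.

Terms with `a` below a configurable minimum count (default 3, the
conventional pharmacovigilance gate) are reported as unassessed rather
than flagged. Published practice is ambiguous about whether a "signal"
requires one positive method or all four, so both combined flags
(`combined_any`, `combined_all`) are always reported and the choice is
left to the analyst.

On any all-positive table the three frequentist estimators necessarily
agree on direction (`sign(ROR−1) = sign(PRR−1) = sign(IC)`, since each
reduces to the sign of `ad−bc`); the test suite checks this as a property.

## Deduplication

FAERS publishes one row per report *version*. Per CASEID the package keeps
the version with the latest FDA receipt date, breaking ties by the largest
PRIMARYID — compared numerically when both parse as numbers, falling back
to lexicographic order otherwise, since primaryids are numeric strings and
`"9" > "21"` lexicographically would pick the wrong version. A version
with a missing receipt date is presumed older and always loses. Reports
with a missing CASEID cannot be grouped; they are retained as singletons
and counted in the run log. The operation is idempotent and its output is
ordered by caseid, so re-runs are byte-stable.

## Weibull time-to-onset model

Onset is the day count from the earliest parsed therapy-start date among
the target drug's primary-suspect therapy rows (FAERS repeats therapy rows
per dose change) to the event date. Intervals are excluded, with a
recorded reason, when either date is missing or partial or the interval is
negative; partial (4- or 6-digit) dates are excluded rather than imputed.
Same-day onsets are kept — they dominate acute hypersensitivity — and
mapped to 0.5 days for fitting so the log-likelihood stays finite, while
remaining 0 in descriptive output.

The two-parameter Weibull density is fitted by maximum likelihood: the
shape solves the profile score equation by damped Newton iteration
(relative tolerance 10⁻¹⁰, at most 100 steps) started from the
log-variance moment estimator `k₀ = 1.2826/sd(log t)` — a start that, unlike
`k₀ = 1`, converges reliably for the heavily right-skewed, shape < 1
samples typical of onset data. The scale then follows in closed form as
`(mean(t^k))^(1/k)`. 95% intervals are Wald intervals on the
log-parameters from the observed information. No censoring is modelled:
all fitted samples are exact event times, matching the naive fit that
published onset analyses report. The test suite cross-checks the fitter
against `fitdistrplus` and against a fine grid-search oracle, and verifies
near-nominal Wald coverage at the study-scale sample size (n = 346,
shape 0.4, scale 79 days).

Note one tension this model reports but does not resolve: a fitted
Weibull(0.4, 79) has model median `79·(ln 2)^{1/0.4} ≈ 32` days, while
empirical onset medians in this field are typically much smaller (about a
week); the package therefore reports the empirical median/IQR (linear
interpolation between order statistics, the standard `quantile()` type-7
convention) alongside the model-based fit and leaves the interpretation to
the analyst.

## Stratified analysis and outcomes

Stratified runs restrict *both* the cohort and the comparator background
to the stratum, so each stratum's 2×2 table has a within-stratum `N` —
without this the stratified ROR is uninterpretable. Cases with unknown sex
or age are excluded from strata (mirroring "Not specified" bookkeeping in
descriptive tables) and counted. Age bands are left-closed/right-open on
age in years as a real number: a 64.99-year-old is 45–64, a 65.0-year-old
is ≥65. Outcome tabulation counts a case once per distinct outcome code it
carries (the codes are not mutually exclusive), with CA and RI folded into
"Other serious"; percentages are over each term's outcome-coded cases, so
outcome percentages need not sum to 100.

## The synthetic generator: what it emulates, and what it does not

The generator emits byte-deterministic '$'-delimited quarterly tables plus
a flat-text ground-truth file. Per case it draws sex, age band, outcome
code and dates independently; a Bernoulli primary-suspect indicator per
drug (cases drawing no drug receive one concomitant-role medication so
every report lists a drug); and the PT list per case with probability
`baseline × multiplier` when a primary-suspect drug carries a multiplier
for that PT. Duplicate report versions (1–3 extra, later receipt dates,
higher version-suffixed primaryids, identical clinical payload) exercise
the deduplication path, and a fraction of dates are emitted as 6-digit
partials to exercise the parser's exclusion path.

Defaults are chosen once to emulate a 21-year piroxicam-like extract:
about 65% female among sex-recorded cases with 8.4% of sexes missing
(≈59.7% female overall), age-band weights 1.9/21.2/36.5/40.4% with 29.7%
of ages missing, outcome probabilities DE/LT/HO/DS/OT =
5.8/4.8/29.5/3.4/41.6%, onset times Weibull(0.4, 79 days), and a
per-date-field missingness of 0.45, which leaves roughly 30% of cohort
reports with a computable onset interval — the usability fraction typical
of real extracts. The default association pattern places multipliers of
8/6/5/4/12 on hypersensitivity, gastric ulcer, GI haemorrhage, urticaria
and AGEP for the target drug, emulating an NSAID signal profile. The
default batch size is 5,000 cases; validation tests that need tighter
sampling error use 20,000–30,000.

Deliberately *not* emulated (they do not affect 2×2 margins, which is all
the statistics consume): drug co-prescription structure, realistic PT
co-reporting correlation, free-text drug-name noise beyond
case/punctuation variation, non-US date formats, and reports guaranteed to
carry at least one reaction. Ground-truth expected cell counts are exact
under a single-drug multiplier structure and first-order in drug
co-occurrence otherwise. Passing the pipeline's recovery tests on this
model therefore demonstrates correctness of the counting and estimation
machinery — not robustness to the coding noise, masking bias or duplicate
near-misses of real spontaneous reports.

A note on calibration testing: with all multipliers at 1 the fraction of
pairs whose ROR lower bound exceeds 1 should approach the one-sided
nominal 2.5%, but small-count distortion (many pairs with single-digit
`a`) pushes it slightly up; the suite allows up to 7.5% over 20 seeds.
Conversely a multiplier of 8 with expected `a ≥ 20` must be flagged by all
four methods in at least 95% of seeds.

## Numerical and design choices

* Zero cells yield undefined sentinels everywhere; an optional Haldane
  correction exists nowhere in the default path because published tables
  never use one.
* All cell arithmetic is done in double precision (the χ² numerator
  overflows 32-bit integers at database scale).
* PRIMARYID comparison, date parsing and age-unit conversion
  (YR×1, DEC×10, MON÷12, WK÷52.18, DY÷365.25, HR÷8766) never throw:
  missing is a value, not an error.
* Report year is taken from the FDA receipt date, since event dates are
  missing too often to build a stable yearly series.
* Country tabulation uses `occr_country` by default with a config switch
  to `reporter_country`; which one published analyses use is generally
  unstated.
* The generator names its file set after the latest receipt quarter of
  the batch rather than splitting one batch across ~84 calendar quarters;
  the reader globs any number of per-quarter files, so either layout
  ingests identically.
* Stage sizes in the test suite (batches of 1,200–30,000 cases, 20-seed
  calibration loops, 200-seed coverage checks) were chosen to keep
  sampling error comfortably below the asserted tolerances while the
  whole suite runs in about a minute.

## Known limitations

Disproportionality is hypothesis-generating only: no exposure denominator,
no causality, and signals can be confounded by indication, co-medication
and reporting fashion (the Weber effect). The MGPS prior fit assumes the
pair grid is large and roughly exchangeable; with a single target drug and
a dozen events the default prior is used instead, which shrinks more
aggressively than a database-wide fit would. The onset model ignores
censoring and duplicate-survivor bias. The stratified analysis treats
strata independently — no interaction testing, no continuous-age
modelling, no regression adjustment.
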