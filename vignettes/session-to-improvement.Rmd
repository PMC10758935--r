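---
title: "Sessions to reliable improvement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sessions to reliable improvement: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rccsurv)
```

`rccsurv` estimates how many coaching sessions precede clinically
reliable improvement in youth anxiety and depressive symptoms. This
vignette documents the statistical model, the choices the package makes
where the underlying protocol leaves room, and what the synthetic-cohort
generator does and does not emulate.

## The measurement model

Members are screened at enrollment with DSM-5 Level 1 cross-cutting
items (frequency of symptoms in the past two weeks, 0–4 per item).
Whether the screener's thresholds apply per item or per domain sum is a
genuinely open design point; the package defaults to the per-item rule —
any domain item at or above 2 ("mild" frequency) triggers the domain's
full assessment — because Level 1 guidance uses mild-or-greater for most
domains. The threshold is configurable per instrument.

Full assessments are scored on each instrument's reporting scale:

* **GAD-7** (adolescent self-report anxiety): plain sum, 0–21.
* **PHQ-9A, 8 items** (adolescent self-report depression, suicide item
  not administered): the 8-item raw sum is prorated by 9/8 and rounded
  half-up to an integer, so scores live on the published 0–27 scale.
  Whether proration should keep fractional scores is unstated in the
  protocol; integer half-up was chosen so severity cutoffs defined on
  the integer PHQ-9 scale apply without modification. Proration is
  monotone, with 0 → 0 and 24 → 27.
* **PROMIS pediatric anxiety / depressive symptoms** (caregiver report
  for children): raw sums convert to population-normed T-scores (mean
  50, SD 10) through a monotone lookup table. The official conversion
  tables are licensed publications, so the package ships *synthetic*
  monotone calibrations with a realistic shape (T ≈ 33 at the raw floor
  to ≈ 88 at the ceiling) and accepts real tables as two-column CSVs via
  `instrument_config()` / `read_instrument_config()`.

Severity bands use the published cutoffs (GAD-7: 5/10/15; PHQ: 5/10/15/20;
PROMIS pediatric T: 55/60/70). Band boundaries are inclusive lower
bounds, so a score on a boundary belongs to the higher band. "Moderate or
moderately severe" eligibility maps to `moderate` for GAD-7 and PROMIS —
which have no moderately-severe band — and to `moderate` plus
`moderately severe` for the PHQ-9A.

## Cohort assembly

`align_assessments()` assigns each assessment the number of sessions on
or before its date and keeps one assessment per inter-session interval
(the first), because multiple assessments between the same two sessions
carry no additional session-resolution information. The baseline is the
*latest* pre-coaching completed full assessment: it is the most current
picture of the member at the start of care, and a screened-out
observation can never displace a scored baseline. The operation is
idempotent.

`apply_inclusion_criteria()` applies the protocol's criteria
sequentially, counting each excluded member under the first criterion
that removes them, so per-criterion counts are well defined:

1. two completed assessments — a scored baseline before the first
   session (required downstream by the RCC comparison) and at least one
   assessment observation (full or screened-out) during coaching;
2. 1.5–2.5 sessions per month;
3. 1–3 weeks *mean* between-session gap;
4. three or more sessions attended;
5. baseline severity in the eligible bands.

Two conventions deserve note. Duration in coaching is measured
first-to-last session in 30.44-day months ("duration *in coaching*", not
enrollment span). And the gap criterion applies to the member's mean gap,
not every gap: applied per-gap it would interact with assessment jitter
to exclude nearly everyone in simulation. A consequence of the
first-to-last convention is that members below the session floor cannot
satisfy the rate and gap windows simultaneously (for two sessions the
windows imply disjoint gap ranges), so criteria 2–3 are treated as
evaluable only at three or more sessions and shorter schedules fall to
criterion 4.

## Reliable change and event times

The Jacobson–Truax criterion `RCC = z·SD·√2·√(1 − r)` uses `z = 1.96`
(95% confidence, configurable), per-instrument reliabilities supplied as
configuration (defaults: GAD-7 0.92, PHQ-9A 0.89, PROMIS pediatric 0.90
— conventional published values, not estimates from data), and a baseline
SD estimated from the converted enrollment scores of the *full* reference
sample, before inclusion filtering — mirroring the practice of using all
members at enrollment for measure variance. `RCC` is linear in the SD,
strictly decreasing in reliability, and zero at perfect reliability.

A follow-up shows reliable change when `baseline − score > RCC`
(*strictly* — "greater than" is taken literally) or when the member
screens out of the full assessment. Stable reliable change is two
successive flagged assessments; the event is assigned to the confirming
(second) assessment by default, with `stable_assign = "first"` exposed
because the alternative reading is defensible. Two successive screen-outs
count as a stable pair: each is a reliable-change observation in its own
right.

Event times are the session index of the triggering assessment; members
without the event are right-censored at their total attended sessions. A
trigger dated before the first session (session index 0) is floored to
time 1 so that all event times are positive — real cohorts guarantee
assessments during coaching, but synthetic edge cases need the rule.
Members are analyzed under their enrollment instrument; mixed-instrument
trajectories (a child turning 13 mid-care) are out of scope.

## Survival estimation

The product-limit estimator, Greenwood variance, log(−log S) confidence
bands and median CI are implemented from scratch (the `survival` package
appears only as an independent oracle in the test suite, where the two
implementations agree to 1e-8 on 200 random event tables). Conventions:

* ties at a time point process events before censorings, so same-time
  censored members remain in that time's risk set;
* bands are degenerate `[1, 1]` while S = 1 and undefined once S = 0
  (the Greenwood term diverges);
* the median is the *first time S ≤ 0.5*, uninterpolated — medians on a
  session grid are integers. `km_median(..., interpolate = TRUE)`
  implements the midpoint-of-flat-region convention of mainstream
  survival software, which yields half-integer medians when the curve
  sits exactly at 0.5 (this is how a median of 1.5 sessions can arise on
  an integer grid); comparisons with 0.5 use square-root machine
  precision, matching that software's tie tolerance. The default stays
  the uninterpolated rule;
* the median CI is of the band-crossing (Brookmeyer–Crowley) type: the
  bounds are the first times the pointwise lower and upper bands drop to
  0.5, the upper bound reported as not available when the upper band
  never gets there. An untransformed-Greenwood variant sits behind
  `conf_type = "plain"`.

Subgroup analysis refits the estimator within age bands (children 6–12,
adolescents 13–17, by age at enrollment); the pooled curve equals the fit
of the union of the band tables.

## What the generator emulates — and what it does not

`generate_cohort()` draws, per member, from an independent pseudo-random
stream derived from `(seed, member index)`, so cohorts are bit-for-bit
reproducible and stable under reordering. The calibrated preset
`paper_like_params()` encodes the study conditions: a 392-member eligible
pool; session gaps normal with mean 16.5 d, SD 2.6 d, truncated to
[4, 35] d; coaching durations from a beta(0.9, 2) draw scaled onto
3.0–7.23 months (mean ≈ 4.3, SD ≈ 1.0 — stays are right-skewed);
assessments every 30 d with 3 d jitter; baselines uniform over the
eligible severity bands; a geometric first-improvement process with
per-assessment probability 0.55; relapse probability 0.35 and screen-out
probability 0.25 per post-improvement assessment; and planted inclusion
violations at the protocol's per-criterion exclusion rates
(24/101/77/37 per 392, plus 28 below the severity threshold), leaving an
expected 125 analyzable members.

The gap mean and duration shape were calibrated jointly against the
reference care statistics, because measuring duration first-to-last
session inflates sessions per month by n/(n−1) at finite session counts;
with these defaults the retained cohort lands within about 7% of all
three reference statistics (≈2.1 sessions/month, ≈2.3-week gaps,
≈4.5-month durations). The three reference statistics are not exactly
jointly attainable under the first-to-last convention, so the calibration
optimizes balance rather than matching any one of them exactly.

Improvement sizing is conservative by construction: planted improvements
drop below baseline by more than an upper bound on any RCC the pipeline
could derive from in-band baselines (0.6 × band width in SD units), and
pre-improvement fluctuation is non-negative (scores never decrease before
the planted event), so generator truth and pipeline detection coincide
exactly. Item responses are back-filled from target raw sums by an even
greedy spread, making re-scoring the items reproduce the trajectory
exactly.

The generator does **not** model therapy or psychiatric co-care,
medication, dropout correlated with symptom level, demographic effect
modification beyond the child/adolescent split, instrument switching, or
measurement error correlated over time. Passing tests on synthetic
cohorts therefore demonstrate the *pipeline's* correctness under the
stated data-generating process, not clinical conclusions about real
members.

## Numerical and testing choices

Percentages in report tables round half-up; the headline results
summary rounds through a one-decimal intermediate (95.45 → 95.5 → 96),
the convention evident in the reference report's printed values.
Degenerate inputs are defined rather than erroneous wherever a
convention exists: empty cohorts produce empty event tables, all-censored
fits have no median, empty subgroup bands are omitted with a warning.

Test problem sizes were chosen to make sampling error negligible
relative to the assertion margins: 200 random event tables (n ≤ 50) for
the estimator oracle; 100 replicates of n = 500 for median parameter
recovery (first improvement geometric with q = 0.45 on an
every-2-sessions assessment grid, analytic median 4 sessions); 2000
trajectories for the geometric distribution check; 8 seeds × 200-member
pools for the care-statistic calibration; 50 random cohorts plus one of
n = 1000 for ledger conservation and planted-rate recovery.

## Known limitations

* Screener scoring details and the study's exact RCC values are not
  public; reliabilities and screener thresholds are configuration inputs
  and the shipped values are conventions, not ground truth.
* The exclusion-ledger counts depend on the criterion order; other
  orderings redistribute members among criteria (the totals are
  invariant).
* The PROMIS T-tables shipped for simulation are synthetic; analyses of
  real PROMIS data must supply the licensed tables.
* The estimator handles right censoring only — no left truncation or
  interval censoring, and no between-group significance testing
  (log-rank, Cox), which the analysis design does not call for.
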