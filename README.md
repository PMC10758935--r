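# rccsurv

How many behavioral health coaching sessions precede clinically reliable
improvement in youth anxiety and depressive symptoms? `rccsurv` implements
the full analysis pipeline for answering that question from member-level
records of a pediatric digital mental health service: instrument scoring
with screener gating, protocol-based cohort filtering with an exclusion
ledger, reliable-change event construction, and discrete-time
Kaplan–Meier estimation over session counts. A seeded synthetic-cohort
generator reproduces the statistical structure of such a service, so the
whole pipeline is testable without access to any member data.

It is written for biostatisticians and mental-health services researchers
working with longitudinal patient-reported outcomes (GAD-7, PHQ-9A,
PROMIS pediatric measures) and session-based care.

## The method

**Scoring.** DSM-5 Level 1 cross-cutting screeners (items 0–4) gate the
full assessments: any item at or above the trigger threshold (default 2)
administers the domain's instrument. GAD-7 totals stay on the raw 0–21
scale; the 8-item PHQ-9A (suicide item removed) is prorated onto the 0–27
scale by `round(raw × 9/8)`; PROMIS pediatric raw sums convert to
T-scores through a monotone lookup table. Severity bands use the
published cutoffs, with band boundaries as inclusive lower bounds.

**Reliable change.** For each instrument the Jacobson–Truax reliable
change criterion is

```
RCC = z · SD_baseline · √2 · √(1 − r)
```

with `z = 1.96`, `r` the instrument's published reliability, and
`SD_baseline` the dispersion of enrollment scores in the full reference
sample. A follow-up shows *reliable change* when its score drops from
baseline by strictly more than the RCC, or when the member screens out of
the full assessment; *stable reliable change* is two successive
assessments with reliable change, assigned to the confirming (second)
one.

**Time-to-event.** Each member contributes the session index of the
triggering assessment (sessions attended on or before its date), or their
total attended sessions as a right-censored time. The survival function
S(t) = Π(1 − dᵢ/nᵢ) is estimated from scratch with Greenwood variance and
log(−log S) 95% bands; the median is the first time S ≤ 0.5, with its CI
read off the band crossings of 0.5. Analyses run per symptom group, with
child (6–12) / adolescent (13–17) subgroup curves.

## Worked example

```r
library(rccsurv)

cohort <- generate_cohort(paper_like_params(seed = 1))
result <- run_pipeline(cohort)

result$ledger
#> # A tibble: 6 × 2
#>   criterion                                              n_excluded
#>   <chr>                                                       <int>
#> 1 2 completed assessments (baseline and during coaching)         27
#> 2 1.5-2.5 sessions per month                                    100
#> 3 1-3 weeks between-sessions                                     82
#> 4 3 or more sessions attended                                    34
#> 5 moderate or moderately severe baseline severity                26
#> 6 retained                                                      123

result$summary
#> # A tibble: 4 × 8
#>   group      endpoint            n n_events pct_events median_sessions ci_lower ci_upper
#>   <chr>      <chr>           <int>    <int>      <int>           <dbl>    <dbl>    <dbl>
#> 1 anxiety    first_reliable     64       64        100               2        2        3
#> 2 anxiety    stable_reliable    64       53         83               6        4        7
#> 3 depression first_reliable     59       59        100               2        2        3
#> 4 depression stable_reliable    59       45         76               5        4        6
```

The ledger shows the 392-member eligible pool thinning to 123 analyzable
members, each exclusion counted under the first protocol criterion that
removes it. The summary says that in this simulated cohort the median
time to first reliable change is 2 sessions in both symptom groups, and
stable improvement consolidates around 5–6 sessions. Derived thresholds
and subgroup curves are inspectable directly:

```r
result$rcc$GAD7
#> <rcc_spec> GAD7: RCC = 1.494 (SD 1.906, r 0.920, z 1.96)

result$subgroups[["anxiety.stable_reliable"]]$child
#> <km_curve> n=37, events=30; median 6 (95% CI 4-7)

plot_km(result$curves[["anxiety.first_reliable"]])  # step plot with CI bands
```

`write_pipeline_outputs(result, "out/")` emits every table as CSV, so any
number in a report traces back to a CSV cell. Cohorts round-trip through
the three-file CSV interface (`write_cohort_csv()` / `read_cohort_csv()`)
with item-level responses in long format.

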