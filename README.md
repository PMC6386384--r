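# stiecon

Whole-system cost-effectiveness analysis of online STI testing.

`stiecon` is for sexual-health service planners, commissioners and health
economists who need to know when adding or growing an online (postal
self-sampling) STI testing service lowers the cost per diagnosis of a local
*sexual health economy* — all specialist clinics plus the online service,
considered jointly. It implements the full pipeline from individual-level,
GUMCAD-coded attendance records to the planning rule, and ships a seeded
synthetic cohort generator so everything is runnable and testable without
confidential patient data.

## What it computes

From attendance records (one person, one provider, one day, up to 12 GUMCAD
service codes):

1. **Harmonisation** — exclusion filters (no codes; age < 16 or ≥ 100;
   prisoner records), collapse to one record per person/provider/day, and
   the six-week restriction to one test-or-diagnosis record per person
   (keeping the record with the most diagnosis codes), with a conservation-
   checked report.
2. **Activity metrics** — per-quarter tests-or-diagnoses, diagnoses and
   composite positivity (chlamydia, gonorrhoea, syphilis, HIV) by setting:

   `positivity = diagnoses / (tests + diagnosis-only attendances)`

3. **Tariff costing** — visits classified simple/complex and
   genital/triple-site, priced at £80.58 / £56.11 / £70.24 with a
   configurable online price (default £30); period totals, annualised and
   monthly costs, cost per test and cost per diagnosis.
4. **Scenario models** — closed forms in the clinic cost *C*, cost ratio
   *r*, online fraction *f*, clinic positivity *p*, positivity ratio *ρ*,
   dispatch share *s* and return rate *R*:

   - blended cost per test `C((1−f) + f·r)`
   - blended cost per diagnosis `C((1−f) + f·r) / (p((1−f) + f·ρ))`
   - cost per completed online test `c(s/R + (1−s))`

   with the **break-even rule**: growing the online share lowers the
   system's cost per diagnosis exactly when the positivity ratio ρ exceeds
   the cost ratio r.

## Worked example

```r
library(stiecon)

res <- run_pipeline(default_study_config(seed = 42))
res$harmonisation_report
#> Harmonisation report
#>   input records:           22145
#>   excluded, no codes:        101
#>   excluded, age:              64
#>   excluded, prisoner:         34
#>   collapsed same-day:          0
#>   removed, 6-week rule:     1946
#>   output records:          20000
```

22,145 synthetic records (20,000 testers plus repeat visits, unreturned-kit
order events and exclusion-triggering records) harmonise to exactly one
test-or-diagnosis episode per tester. Quarterly positivity and the period
cost comparison then come out table-shaped:

```r
online_share(res$quarterly, "2016-Q3")   # 0.367 — online share of testing
res$return_rate                          # 0.756 — kits returned/dispatched
res$period_summaries$period2
#> Period cost summary: period2 (15 months)
#>   clinic visits with test/diagnosis: 7417
#>   online tests: 1706
#>   clinic cost: GBP 492,082   online cost: GBP 51,180
#>   combined: GBP 543,262   annualised: GBP 434,610
#>   monthly tests: 608   monthly diagnoses: 61
#>   cost per test: GBP 60   cost per diagnosis: GBP 594
```

Cost per test falls from £66 (clinic-only baseline period) to £60 once
~19% of period-2 testing is online at £30 a test. The scenario models give
the same answer analytically and generalise it:

```r
p <- scenario_params(online_fraction = 0.37, cost_ratio = 0.45,
                     clinic_positivity = 0.10, positivity_ratio = 0.7)
blended_cost_per_test(p)         # 52.57
blended_cost_per_diagnosis(p)    # 591.33
break_even_positivity_ratio(p)   # 0.45: online pays off while rho > 0.45
```

At a 37% online share, 45% relative cost and 0.7 relative positivity, the
system's cost per test is £52.57 and its cost per diagnosis £591 — below
the clinic-only £660 because ρ = 0.7 sits above the break-even 0.45.
Cross-area comparison from the packaged profiles:

```r
profiles <- read_area_profiles(system.file("extdata", "area_profiles.csv",
                                           package = "stiecon"))
area_comparison_table(profiles)[, c(1, 5, 6)]
#>   area      cost_per_diagnosis_clinic cost_per_diagnosis_online
#> 1 SE London                       880                       732
#> 2 Area A                          835                       517
#> 3 Area B                          904                       417
#> 4 Area C                         1200                       545
```

Where clinic and online positivity are similar (Areas B, C) the cheaper
online test dominates; where online positivity is much lower (SE London)
the advantage narrows.

See `vignette("online-sti-testing-economics")` for the model derivations,
harmonisation rules, generator design and tolerances.

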