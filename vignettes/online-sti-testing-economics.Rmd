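---
title: "Methods: whole-system economics of online STI testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-system economics of online STI testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiecon)
```

## The problem

Online STI testing — a kit ordered on a website, self-sampled at home and
posted to a laboratory — has a much lower unit cost than a clinic visit, but
it does not replace clinic activity one for one: it recruits new testers,
shifts existing ones, and typically tests a lower-prevalence population. A
cost-effectiveness judgement therefore has to be made at the level of the
whole local *sexual health economy* (all specialist clinics plus the online
service), not per service. `stiecon` implements that whole-system analysis:
it harmonises individual-level attendance records, computes per-quarter
testing volumes, diagnoses and composite positivity by setting, assigns
tariffs to produce period cost summaries, and provides the closed-form
scenario models that say when growing the online share lowers the system's
cost per diagnosis.

## Data model

One attendance record is one person at one provider on one day, carrying up
to 12 STI service codes (plus reproductive-health and contraception codes)
in the GUMCAD v2 vocabulary. The composite measure covers four infections —
chlamydia, gonorrhoea, syphilis and HIV:

* **test codes**: `T1, T2, T3, T4, T7, T8, TT`, with `T4` genital-only
  testing and `TT` triple-site (genital, rectal, oral) testing offered to
  MSM;
* **diagnosis codes**: `A1, A2, A3, A4, A5, B(R,O), C4(R,O), H1, H1a, H1b`.

The site modifiers printed on `B(R,O)` and `C4(R,O)` have no documented
semantics in the coding summaries we follow, so matching is deliberately
permissive: a code matches a set member when their base codes (the part
before any parenthesised modifier) agree. `B`, `B(R)` and `B(R,O)` are all
syphilis diagnoses. This is the loosest rule that cannot silently drop a
diagnosis; it can in principle over-match a hypothetical unrelated code
that shares a base, which the parse report would surface as it flags any
code outside the configured vocabulary.

## Harmonisation

Three steps, each with counted in/out flows that must satisfy a
conservation identity (`n_output = n_input - exclusions - collapsed -
removed`), asserted at run time:

1. **Exclusions.** Records with no codes at all, ages under 16 or 100 and
   over, and prisoner-flagged records are dropped; each dropped record is
   counted once under the first matching reason (no codes, then age, then
   prisoner). The age boundaries are inclusive-exclusive: 16 and 99 stay,
   15 and 100 go.
2. **Same-day collapse.** One record per person, provider and day; code
   lists become their de-duplicated union in first-occurrence order, other
   fields come from the group's first record.
3. **Six-week restriction.** Clinic diagnoses are not reliably tied to a
   test episode, so for positivity each person is restricted to one
   test-or-diagnosis record per six weeks, keeping the record with the most
   diagnosis codes.

The six-week rule needs a precise operational form, and we fixed three open
choices:

* *Window.* "Within six weeks" is read half-open: records strictly less
  than 42 days after the window's anchor conflict; a record exactly 42 days
  later does not.
* *Selection.* Within a conflict set: most diagnosis codes, then earliest
  date, then input order. Deterministic regardless of row order.
* *Advance.* A window is anchored at the earliest unresolved record, but
  after the kept record is chosen, any later record closer than 42 days
  *to the kept record* is also removed. The simpler alternative — advance
  from the anchor only — can retain two records 14 days apart (events at
  days 0, 30 with a diagnosis, 44) and is not idempotent; the rule used
  here guarantees retained records are always at least 42 days apart, so
  running the restriction twice changes nothing. The tests check both
  properties and equality with an independent brute-force implementation
  on small random instances.

Deduplication is applied within each person–provider pair by default
(each clinic restricts its own caseload); a person tested in two clinics
within six weeks counts twice. `scope = "person"` switches to
economy-wide restriction for sensitivity analysis.

## Positivity and classification

A record is in the positivity **denominator** when it carries at least one
test *or* diagnosis code — diagnosis-only attendances (contact of
infection, symptomatic or microscopy-based diagnoses without a simple
test) belong in the quarterly totals. The **numerator** is records with at
least one diagnosis code. Treatment codes recording a diagnosis made
elsewhere are excluded from the diagnosis set (none are configured by
default; supply your extract's codes via
`default_code_sets(treatment_elsewhere_codes = ...)`). Positive tests and
clinical diagnoses are not distinguishable in this schema; both appear as
diagnosis codes, which is exactly what the composite formula needs.

A visit is **complex** when any code across the three code lists falls
outside the test and diagnosis sets (treatment, examination, or another
service delivered alongside testing), otherwise **simple**. Online visits
are simple by construction — nothing but testing happens online. Site
scope is **triple-site** when `TT` is present, else genital.

## Costing

Tariffs per classified visit (London integrated sexual health tariff):

| class                          | GBP    |
|--------------------------------|--------|
| genital test, simple visit     | 80.58  |
| genital test, complex visit    | 56.11  |
| triple-site test (any visit)   | 70.24  |
| online test (indicative price) | 30.00  |

Diagnosis-only clinic attendances are costed by their complexity class like
any other visit, keeping the visit denominator consistent with the volume
counts. Period totals are annualised by scaling to 12 months (a 15-month
period's cost is multiplied by 4/5); monthly averages keep unrounded
intermediates; pounds and counts are rounded only at presentation. One
consequence worth knowing: a cost-per-diagnosis figure computed from
*rounded* monthly diagnoses can differ by £1 from the same figure computed
from unrounded ones; this package always divides unrounded monthly cost by
unrounded monthly diagnoses.

## Scenario models

Let `C` be the clinic cost per test, `r` the online/clinic cost ratio, `f`
the online share of tests, `p` clinic positivity, `rho` the online/clinic
positivity ratio, `s` the dispatch share of the online unit cost and `R`
the kit return rate. Holding total testing volume constant:

* **Blended cost per test**: `C * ((1 - f) + f r)` — the volume-weighted
  average of the two unit costs.
* **Blended cost per diagnosis**: divide blended cost per test by blended
  positivity `p * ((1 - f) + f rho)`, giving
  `C ((1 - f) + f r) / (p ((1 - f) + f rho))`.
* **Break-even**: the derivative of the cost per diagnosis with respect to
  `f` has the sign of `r - rho`; at `rho = r` the expression collapses to
  `C / p` for every `f`. So shifting tests online lowers the system's cost
  per diagnosis exactly when the positivity ratio exceeds the cost ratio —
  the central planning rule. The tests verify the identity on a grid and
  the strict monotonicity on either side.
* **Return rate**: each completed online test requires `1 / R` dispatches;
  the dispatch share `s` of the unit cost `c = r C` is spent per dispatch
  and the remainder per completed test, so the cost per completed test is
  `c (s / R + (1 - s))`. At `s = 0.15` the markup over the nominal cost
  crosses 10% exactly at `R = 0.6`, which is why return rates below ~60%
  are the operational red line.

These are the minimal closed forms consistent with the stated assumptions;
no curve values are read off published figures. Two reference online
prices coexist in practice — £30 (0.45 of a £66 clinic cost, used for the
cross-area comparison) and £33 (0.5, used for the return-rate curve) —
both are plain parameters here (`default_tariffs(online_price = ...)`,
`scenario_params(online_cost = ...)`).

The cross-area comparison divides each setting's unit cost by its local
chlamydia positivity: `area_cost_per_diagnosis()` on the packaged
`area_profiles.csv` (four English areas of varying rural/urban character)
reproduces all eight published cells.

## The synthetic cohort

No patient-level dataset can be shipped, so `synthesize_cohort()` generates
streams with the structure the pipeline assumes. Its defaults are the study
conditions, chosen once:

* 20,000 testers over eleven quarters (2014 Q1 – 2016 Q3), online service
  opening 2015 Q2 — a deliberate scale-down of the real economy's ~11,000
  tests per quarter that keeps the full suite fast while leaving binomial
  error small;
* clinic positivity 0.10, online positivity 0.07, kit return rate 0.75;
* online uptake per quarter ramping 0.10 → 0.37, so the final quarter's
  online share of completed tests is 37%;
* 39% of clinic test visits simple; 10.5% of testers MSM (triple-site
  tested, matching the baseline year's 6.5% + 4.0% triple-site visit mix);
* 10% repeat testers whose second visit falls 7–41 days after the first —
  inside the six-week window by construction, so deduplication always has
  work to do;
* ~1% of records trigger each exclusion rule.

Each tester's infection episode is drawn once, on the first visit; a repeat
visit is a plain retest carrying only a test code. This matters: if the
second visit re-drew a diagnosis, the six-week rule's preference for
diagnosed records would bias recovered positivity upward by about half a
percentage point, and configured-versus-recovered agreement is the
generator's acceptance surface. Unreturned kits are modelled as order-only
events (empty code list, `ordered_only` flag) attached geometrically to
completed tests, so the dispatch count per completed test has mean `1/R`;
they are dropped by harmonisation and consumed only by
`return_rate_estimate()`.

What the generator does *not* emulate: demand growth from unmet need
(volumes are flat at `n_persons`), seasonality, demographic risk structure
(ages and areas are uniform placeholders), cross-provider care pathways,
and any dependence of positivity on behaviour — positivity is a configured
margin, not an emergent quantity. Passing parameter-recovery tests
therefore shows the pipeline measures faithfully what the generator
encodes, not that the generator is epidemiologically realistic.

## Numerical and degenerate-input choices

* All randomness flows from one explicit seed per config
  (`withr::with_seed`); the global RNG state is untouched and identical
  configs give byte-identical output CSVs.
* Money is plain numeric GBP; category costs are count × tariff rounded to
  the penny, so no float accumulation is possible; whole-pound rounding
  happens only in printed/exported tables.
* Zero denominators are reported as `NA` ("undefined"), never `Inf`:
  positivity in an empty quarter, cost per diagnosis with zero diagnoses,
  simple-test share with no test-bearing clinic visits.
* Quarters are calendar quarters of the visit date; records outside any
  configured analysis period are still summarised in their own quarter.

## Problem sizes in the test suite

Unit tests use hand-built record sets of a handful of rows; property tests
run a few hundred random small instances (≤ 6 events per person in a
120-day span); the end-to-end recovery test runs the default 20,000-person
cohort, which completes in about a second. Recovery tolerances are set
from binomial error at those sizes: ±0.01 on positivities, ±0.02 on the
final-quarter online share and the return rate.

## Limitations

Per-infection breakdowns (beyond the chlamydia-only cross-area table),
treatment and partner-notification outcomes, primary-care testing, and any
statistical inference (confidence intervals, hypothesis tests) are out of
scope — the analysis is descriptive accounting plus deterministic
closed-form models. The six-week rule's provider scope means a person
tested in two clinics within six weeks counts twice; the `scope` switch
quantifies the sensitivity but there is no ground truth for which is
"right" in a given economy.
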