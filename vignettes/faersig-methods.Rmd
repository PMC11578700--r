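---
title: "Methods: disproportionality signal detection on spontaneous reports"
author: "faersig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection on spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersig)
```

## The problem and the design

Spontaneous reporting systems such as FAERS collect adverse-event reports
without denominators: we know how often a drug–event pair was *reported*,
not how often the drug was used. Disproportionality analysis sidesteps the
missing denominator with a case/non-case design inside the database itself:
reports mentioning the event of interest are cases, all other reports are
the comparator, and the question is whether the target drug is
over-represented among the cases relative to all other drugs. The resulting
statistics are *reporting* signals — they flag associations worth clinical
follow-up and say nothing causal, because reporting is subject to
stimulated reporting, confounding by indication and channeling.

The package implements this design end to end for the oral-bisphosphonate
/ oesophageal-toxicity cohort (alendronate, risedronate, ibandronate
screened against an oesophageal SMQ), but every component is parameterized:
any drug dictionary, SMQ and PT→SOC map can be supplied.

## Ingestion and deduplication

FAERS quarters are `"$"`-delimited ASCII tables. The readers validate every
row against the table's closed vocabularies (drug roles PS/SS/C/I, outcome
codes DE/HO/LT/DS/CA/RI/OT) and log each rejected row with a reason;
record plus reject counts always equal the line count, so nothing vanishes
silently. Dates may be full (`YYYYMMDD`), partial (`YYYYMM`, `YYYY`) or
missing; they are kept with an explicit precision level rather than being
discarded or coerced, and each downstream stage decides what precision it
needs (deduplication orders on the zero-padded key; time-to-onset requires
day precision on both ends). Ages are normalized to years at read time
(decades ×10, months /12, weeks /52.18, days /365.25) because the cohort's
age strata are in years. Drug names and preferred terms are upper-cased and
whitespace-collapsed before any matching, since FAERS free text is
inconsistent.

A FAERS case appears as multiple report versions sharing a `CASEID`.
`dedup_reports()` applies the FDA rule — keep the version with the highest
`FDA_DT`, break ties by the highest `PRIMARYID` — deterministically in any
input order. Two boundary decisions the rule itself does not specify: a
version with a missing `FDA_DT` loses to any dated version (a dated record
is more informative), and records with a missing `CASEID` cannot be grouped,
so they are kept as logged singletons.

## Cohort construction

A report is attributed to a target drug when a *primary-suspect* DRUG row
contains the dictionary pattern as a substring of the normalized name, so
`"ALENDRONATE SODIUM"` matches `"ALENDRONATE"`; suspect-role restriction is
the usual guard against counting co-medications. A report naming two target
drugs as PS contributes to both cohorts and the overlap is recorded. The
route field is exposed (`route = "ORAL"` restricts matching) but off by
default: FAERS route text is unreliable, and oral formulations are normally
selected through product-name dictionaries, which is the approach the
default dictionary takes.

The characteristics table uses the full case count of each drug as the
denominator for every percentage, missing categories included — this is
what makes the percentage blocks sum to 100. Age strata are
`[0,18)`, `[18,65)`, `[65,85]`, `(85,∞)`, with the boundary age 85 assigned
to the 65–85 stratum to match the conventional "65–85" label; the mean and
sample SD are computed over known ages only. Yearly report counts use the
FDA receipt date by default (the event date is an option): receipt dates
are near-complete, event dates are missing for roughly half of the reports,
and a reporting-volume figure is about reporting, not onset.

## The four algorithms

All four statistics are computed from the same 2×2 table. Counting is
*event-level* by default: the unit is a distinct (report, PT) pair, so a
report listing two SMQ terms contributes 2 to `a`. This is the convention
that makes per-term "AE numbers" exceed case counts, and it reconciles the
cohort's published event counts (3,621/361/196) with its case counts
(3,039/281/177); case-level counting is available with
`counting = "case"`.

**ROR** — `(a·d)/(b·c)` with the Woolf interval
`exp(log ROR ± z·√(1/a+1/b+1/c+1/d))`. A zero cell makes the statistic
incomputable and it is reported as `NA`: no Haldane 0.5 correction is
applied by default because the signal criterion already requires `a ≥ 3`,
and silently corrected estimates are easy to over-read. Tables built with
`correction = "haldane"` opt in to the correction.

**PRR** — `[a/(a+b)]/[c/(c+d)]`, conventionally paired with the Pearson χ²
of the table, `N(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]`, without Yates continuity
correction (the common PRR convention; the outcome contrasts follow the
same convention for consistency, and both are switchable).

**BCPNN** — the information component `IC = log₂ p₁₁/(p₁.p.₁)` under the
standard closed-form Bayesian formulation with priors `γ₁₁ = 1`,
`α₁ = β₁ = 1`, `α = β = 2` and the joint prior weight `γ` tuned so the
prior IC is centred at zero. The posterior expectation is the log of the
ratio of posterior means and the variance is the delta-method sum of the
three Beta relative variances; `IC025 = E(IC) − 2√V(IC)`. The priors
regularize zero cells, so the IC always exists. The closed form is checked
in the tests against a Monte-Carlo sampler of the exact Beta posteriors
(10⁶ draws, agreement well within 0.02 bits).

**MGPS** — the multi-item gamma Poisson shrinker. Each pair's observed
count is Poisson with mean `λE`, `E = (a+b)(a+c)/N` the count expected
under independence, and `λ` carries a two-component gamma-mixture prior
whose five hyperparameters are estimated by maximizing the marginal
(negative-binomial mixture) likelihood over all pairs in the universe —
by default every (PS drug, PT) pair with at least one report, so the
shrinkage reflects the whole database rather than the scanned terms.
Numerical choices, all fixed for determinism: optimization in
unconstrained space (log shapes/rates, logit weight), Nelder–Mead from the
conventional start `(0.2, 0.1, 2.0, 4.0, ⅓)` with `reltol = 1e-10`; on
null-like data the mixture is only weakly identified and the simplex can
degenerate on a likelihood ridge, in which case the fit restarts once from
the incumbent and finishes with a BFGS polish. `EBGM = 2^E[log₂λ|a]` has a
digamma closed form under the posterior (again a two-component gamma
mixture with negative-binomial weights); `EBGM05` is found by root-finding
on the posterior mixture CDF bracketed between the two component 5%
quantiles (`uniroot`, tolerance 10⁻¹²), which the tests verify satisfies
`CDF(EBGM05) = 0.05` to 10⁻⁶.

A pair is a **joint signal** only when all four per-algorithm criteria hold
(`a ≥ 3` with ROR CI lower bound > 1; PRR ≥ 2 with χ² ≥ 4; IC025 > 0;
EBGM05 > 2). The EBGM05 threshold of 2 is the conventional MGPS screen; all
thresholds live in `signal_criteria()` and in the YAML config, never in
code. Joint use of four algorithms trades sensitivity for specificity —
it is the multiplicity control of this field.

## Time-to-onset

Onset is measured from the earliest day-precision therapy start date of the
matched drug to the event date; both must have day precision and the
interval must be non-negative, and every exclusion is logged with its
reason. Same-day onset (0 days) is valid. All retained records are events:
a spontaneous report exists because the event occurred, so there is no
censoring mechanism, and the Kaplan–Meier curve (computed through
`survival::survfit`) coincides with the empirical distribution — the KM
formalism is kept because it is the field's presentation and because the
log-rank machinery (`survival::survdiff`) comes with it. The median is the
smallest time with cumulative incidence ≥ 0.5, evaluated with a 10⁻⁹
tolerance because the product-limit estimator can land a floating-point
epsilon below 0.5 at the exact median.

## Outcome contrasts

Hospitalization (HO) and death (DE) rates per drug use the drug's case
count as denominator — the outcome figures in this literature are framed
per case, not per event — and a case carrying both codes enters both
numerators. Pairwise contrasts are Pearson χ² without Yates correction;
raw p-values are reported (the published comparisons are raw pairwise
tests), with Bonferroni available. Tests with an expected cell below 1 are
flagged unreliable rather than suppressed.

## The synthetic generator and the reference fixture

The generator exists so that every stage can be validated against known
ground truth without a FAERS download. Its defaults *are* the study
conditions: three target drugs with report volumes proportional to
30,735/6,189/4,666 against a background universe (500,000 reports at full
scale, 50,000 at the one-tenth desk scale used by the default tests — the
published corpus of 20.6M reports is needlessly large for validation);
an oesophageal term catalog whose baseline reporting fraction is 1.3% of
event units, with per-PT weights led by gastroesophageal reflux disease;
an injected reporting-rate ratio of 6 for the target drugs (consistent
with the published RORs of 5.7–7); 10% of cases duplicated into
multi-version clusters; missingness patterned on the cohort's
characteristics table (9% sex, 52% age, and day-precision date
probabilities that leave roughly the published 28% of cases with usable
onset data); lognormal onset with medians 346/126/28 days and σ = 1 (a
typical dispersion for drug-onset distributions, for which the cohort
publishes only medians); and per-drug hospitalization/death probabilities
0.376/0.315/0.148 and 0.022/0.022/0.011. The ground-truth ledger records
each case's drug, SMQ terms, intended deduplication survivor, onset and
outcomes, enabling exact scoring.

`reference_fixture()` is the deterministic ("exact-expansion") counterpart:
cell counts are laid out by largest-remainder apportionment so that every
demographic block sums to its drug's case total at any scale, onset times
are lognormal quantile grids (`(i−0.5)/n`), and outcome counts are the
nearest integers to the published rates. Three consequences worth knowing:

* With an even onset count the KM median falls on the `n/2`-th order
  statistic of the quantile grid, slightly below the distribution median —
  the fixture's risedronate median computes to 124 days against the
  346/126/28 targets (alendronate and ibandronate land exactly).
* No integer count out of 281 risedronate cases yields the published
  31.5% hospitalization rate (or 2.2% mortality); the fixture uses the
  nearest integers, 89 (31.7%) and 6 (2.1%). All qualitative contrast
  conclusions are unaffected.
* The published per-drug RORs (5.75/5.74/7.03) cannot all be reproduced
  against any single shared comparator: solving the three ROR equations
  for one background universe has no non-negative solution, because the
  real comparator margins of the 20.6M-report corpus are not recoverable
  from the printed counts. The fixture therefore targets count arithmetic
  exactly and signal values only qualitatively (positive signals for all
  three drugs on a 1.3% background).

What the generator deliberately does not emulate: misspelled or
brand-specific drug names beyond case/whitespace variants, correlated
demographics (fixture blocks are expanded independently, so joint
distributions of sex × age × country are degenerate), real MedDRA (the
packaged 172-term SMQ and PT→SOC map are synthetic stand-ins; filenames
say so), indication fields, and reporting-volume seasonality. Passing
tests on synthetic data therefore demonstrate the *computational*
correctness and calibration of the pipeline, not the clinical validity of
any particular FAERS finding.

## Validation suite and problem sizes

The test suite runs at desk scale, chosen to keep the default run fast
while leaving Monte-Carlo margins comfortable: oracle equivalence of
ROR/PRR/χ²/EBGM on 1,000 random tables (10⁻⁸ relative; EBGM against direct
numerical integration of the posterior); IC against 10⁶-draw Monte-Carlo
posteriors on 10 tables (0.02-bit tolerance); MGPS hyperparameter recovery
on 5,000 pairs simulated from a known prior (fitted marginal log-likelihood
within 1 unit of the generating prior's); null calibration on a ~54,000
report all-RR-1 universe (joint-signal rate ≤ 1%); detection and Woolf-CI
coverage of an injected RR = 8 signal with a ≈ 200 over 200 replicates
(≥ 95% detection, ≥ 93% coverage against the nominal 95%); log-rank
type-I error within [0.03, 0.07] over 2,000 identical-distribution
replicates; and 100-replicate separation of the 346/126/28-day onset
groups at the published sizes 847/88/19 (p < 10⁻⁴ in ≥ 95%). The
full-scale fixture reproduction (41,590 reports, 3,497 cases, 8.41%, and
the characteristics-table cells) is exact, not stochastic.

## Known limitations

Disproportionality statistics are reporting signals, not risks; the
package does not attempt stratified MGPS, regression-based signal
detection, fuzzy duplicate linkage across different `CASEID`s, dose or
indication analysis, or dechallenge/rechallenge. The no-censoring
assumption in the onset analysis is an interpretation choice inherited
from the design (every report contains the event); onset data are present
for only a quarter of cases and are themselves subject to reporting
selection.
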