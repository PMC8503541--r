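---
title: "Methods: case/non-case disproportionality for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case/non-case disproportionality for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect tens of
millions of reports without any denominator of drug exposure, so incidence
cannot be estimated. What can be estimated is *disproportionality*: whether
a drug–event pair is reported more often than the background reporting
pattern of the whole database would predict. `faersignal` implements this
case/non-case design for a target drug (the bundled lexicon covers
carfilzomib and its brand name Kyprolis) against cardiovascular events
grouped into the eight narrow Standardized MedDRA Query (SMQ) categories —
cardiac arrhythmias, cardiac failure, cardiomyopathy, embolic and
thrombotic events, hypertension, ischemic heart disease, pulmonary
hypertension, and torsade de pointes/QT prolongation.

## Record cleaning

Two cleaning rules run before any counting, mirroring standard
pharmacovigilance practice:

* **Deduplication.** Spontaneous databases carry re-submissions of the
  same case. Two records are treated as duplicates when they agree on the
  *entire* key — sex, age (truncated to whole years, because reporting
  units vary), country of reporter, event date, reporting year, the set of
  normalized drug names with their start and end dates, the reaction term
  set, and the outcome set. Only the first record of a key survives.
  Records missing any key field are never merged: missing is not equal to
  missing, which is the conservative choice when sparse records would
  otherwise collapse.
* **Aberrant dates.** A report whose target-drug start date falls
  *strictly after* the event onset date cannot describe a drug-induced
  event and is excluded; the comparison is anchored at the earliest start
  date across the report's target-drug entries. Reports with either date
  missing are retained — no imputation is performed anywhere in the
  package.

The two steps run in that order, and the resulting `cleaning_report`
satisfies the partition identity
`n_input = n_duplicates_removed + n_aberrant_removed + n_retained` on
every run.

Time-to-onset is the day difference between the event date and the
earliest target-drug start date; after aberrant-record removal it is
non-negative by construction.

## The statistics

For a drug–event pair, reports are cross-classified into the 2×2 table
(`a` drug+event, `b` drug only, `c` event only, `d` neither), and the
expected count under independence is

$$E = \frac{n_\mathrm{drug}\, n_\mathrm{event}}{n_\mathrm{total}}.$$

Two measures of disproportionality are computed, both with statistical
shrinkage to damp small-count noise:

* the **information component**,
  $\mathrm{IC} = \log_2\frac{a + 0.5}{E + 0.5}$, in bits. The added 0.5
  (the shrinkage proposed for rare-event signal screening) keeps the IC
  defined at $a = 0$ and pulls extreme ratios towards 0 when counts are
  small; the IC retains the sign of the raw log ratio
  ($\mathrm{IC} > 0 \iff a > E$) and is attenuated relative to it
  ($\mathrm{IC} < \log_2(a/E)$ whenever $a > E > 0$).
* the **reporting odds ratio** with Haldane–Anscombe continuity
  correction,
  $\mathrm{ROR} = \frac{(a+0.5)(d+0.5)}{(b+0.5)(c+0.5)}$, with the
  log-normal (Woolf) 95% interval computed on the corrected cells.

The default IC interval is the standard shrinkage-IC approximation
$\mathrm{IC}_{025} = \mathrm{IC} - 3.3(a+0.5)^{-1/2} - 2(a+0.5)^{-3/2}$
and
$\mathrm{IC}_{975} = \mathrm{IC} + 2.4(a+0.5)^{-1/2} + 0.5(a+0.5)^{-3/2}$;
a gamma-posterior credible interval
($\mu \sim \Gamma(a+0.5,\, E+0.5)$, $\mathrm{IC} = \log_2 \mu$) is
selectable via `ic_method = "gamma"`. The two methods agree closely at
moderate counts; published lower bounds reproduce to two decimals under
the approximation, while published *upper* bounds are occasionally a
little wider than either method produces — a known ambiguity of
unreported interval conventions that the package documents rather than
chases.

An `"observed_expected"` ROR variant equal to $(a+0.5)/(E+0.5) = 2^{IC}$
is retained behind a flag. It is not the default because an
observed-to-expected ratio and an odds ratio differ at the third decimal
already for common events, and published odds-ratio rows (for example a
total row with IC 0.90 but ROR 2.02 ≠ $2^{0.90}$) are only reproduced by
the corrected odds ratio with the Woolf interval.

**Signal rule.** A pair is a signal when $\mathrm{ROR}_{025} > 1$ *and*
$\mathrm{IC}_{025} > 0$ *and* at least three records carry the pair. The
inequalities are strict: bounds sitting exactly on the threshold do not
fire. No multiplicity adjustment is applied — shrinkage is the
false-positive control, and the joint rule is conservative (simulated
false-positive rates under the null are well below the nominal 2.5% per
criterion).

**Reconstruction from published marginals.** Published tables print `a`,
the drug and database totals, and the estimates, but not the comparator
event count `c`. `reconstruct_table()` solves for the continuous `c` at
which the corrected ROR equals the printed value, which lets every other
printed statistic of the row (expected count, shrunk IC, interval bounds,
signal status) be recomputed exactly. This is what `scripts/acceptance.R`
does for the bundled carfilzomib reference rows.

## Views of the data

* `run_category_analysis()` produces the total row plus the eight
  category rows. Reports of other categories stay in the background of
  each per-category table (the non-case set is "everything without this
  category", the usual reading when no explicit non-case definition is
  given).
* `ic_time_series()` estimates on cumulative subsets (all reports up to
  each year), the scheme under which interval width shrinks
  monotonically as evidence accumulates.
* `stratified_analysis()` crosses sex with an age dichotomy (default
  cutoff 65 years, the conventional geriatric boundary; configurable)
  and restricts cases *and* background to each stratum.
* `restricted_background_analysis()` reruns the whole computation inside
  a subpopulation (e.g. reports with the drug's main indication), the
  standard sensitivity analysis when the background's risk profile is
  suspected to differ from the cases'.
* Descriptive surfaces: `tto_summary()` (median and quartiles by linear
  interpolation between order statistics — `quantile()` type 7, pinned
  by a test since changing the convention silently shifts published-style
  quartiles), with "first month" and "first three months" fixed as ≤30
  and ≤90 days (calendar-month arithmetic on durations is ill-defined);
  `outcome_profile()` resolves multi-coded records to their single most
  severe outcome (death > life-threatening > disability >
  hospitalization > congenital anomaly > required intervention > other
  serious), so level counts sum to the available denominator.

## The synthetic report stream

Real FAERS extracts are large and carry no ground truth, so the package
ships a generator whose defaults emulate the 2015–2019 reporting-period
conditions of the carfilzomib cardiovascular analysis and whose implied
statistics are available in closed form:

* Drug mentions are independent Bernoulli draws per catalog drug
  (polypharmacy arises naturally; a filler "concomitant therapy" entry
  guarantees at least one drug per report). Independence — rather than
  drawing a drug count and sampling names — is what makes the 2×2 cell
  probabilities of `ground_truth()` exactly computable, which every
  calibration test leans on.
* Preferred-term rates are baseline marginals inflated multiplicatively
  by the (drug, SMQ-category) association multipliers λ of the drugs a
  report mentions; λ = 1 everywhere gives exact independence and
  expected IC 0. The default multipliers plant the published carfilzomib
  magnitudes (1.4–2.8 across the eight categories).
* Onset lag is log-normal with median 41 days and `sdlog` 1.5
  (quartiles ≈ 15 and 113 days), reproducing the right-skewed
  time-to-onset shape of reported cardiovascular events; event dates are
  uniform over 2015–2019.
* Field-level missingness defaults (sex 14%, age 30%, dates 30–50%,
  outcome 10%) match the "data available" denominators typical of
  published FAERS characteristics tables.
* Contamination is injected with exactly countable ledgers: duplicates
  copy the complete dedup key of an earlier *fully-observed* report
  (a copy of a record with a missing key field would never merge, so
  such records are not eligible sources), and aberrant-date records are
  drawn from target-drug reports with their two dates forced observed
  (the exclusion rule must see both). The perturbation of the
  missingness rates is below sampling noise at the default 0.5%
  aberrant fraction. Duplicate and aberrant removals therefore equal the
  injected counts *exactly*, which the test suite asserts.

What the generator does **not** emulate: reporter-level behaviour
(stimulated reporting, notoriety waves), country-specific reporting
cultures, indication channelling unless planted explicitly, and MedDRA's
hierarchy (terms are flat synthetic strings; the bundled
`synthetic_smq_map.tsv` is an illustrative mapping, not the licensed SMQ
listing). Green tests on synthetic data therefore certify the
*machinery* — counting, cleaning, estimation, calibration — not the
epidemiology of any real extract.

## Simulation design choices

Replicate-heavy studies sample 2×2 tables directly from the ground-truth
multinomial (`simulate_pair_tables()`), the exact sampling distribution
of the per-report stream's table, keeping hundreds of replicates cheap;
the per-report generator is cross-checked against the same cell
probabilities separately. Problem sizes used by the test suite: null
calibration at 500 replicates of 50,000 reports with expected count ≥ 20;
parameter recovery at 200 replicates of 200,000 reports; brute-force
recount equivalence on 100 independent 5,000-report sets.

The parameter-recovery study plants λ = 4 on a *rare drug* (0.5% of
reports) against a category with a 5% baseline rate, giving expected
counts near 50. The pair must not be made rare on both margins: with
expected counts below ~20 the deliberate shrinkage attenuation — not
estimation error — dominates the mean shrunk IC, and the study would
measure the shrinkage offset instead of recovery of the planted
$\log_2 4$.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_reports = 50000, seed = 1)
res <- run_pipeline(run_config(cfg))
res$cleaning
res$signals[, c("category", "n", "ic", "ic025", "ror", "ror025", "signal")]
```

## Known limitations

* Disproportionality is not risk: without exposure denominators a signal
  flags reporting imbalance, never incidence or causality.
* Masking (a dominant drug absorbing events from the background) and
  co-prescription confounding are not corrected; the restricted-background
  analysis is the only mitigation offered.
* The dedup key is exact-match; probabilistic record linkage and FDA
  case-version reconciliation are out of scope.
* Reconstructed tables treat the printed ROR as exact; its two-decimal
  rounding propagates about ±0.01 into recomputed ICs of rare categories.
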