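---
title: "Methods: disproportionality signal detection for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem and the data model

Spontaneous adverse-event reporting systems collect unsolicited case
reports linking drugs to suspected adverse events. A national extract of
this kind arrives as four linked tables keyed by a case identifier:

- **DEMO** — one row per case: sex, age (as 10-year decade bins 0–100),
  report year;
- **DRUG** — drug exposures with an involvement role (*suspected
  medicine*, *concomitant medicine*, *interaction*) and a
  first-administration date;
- **REAC** — adverse events coded as MedDRA preferred terms (PTs), with an
  onset date and a six-category outcome (recovery, remission, no recovery,
  death, after-effects, unknown);
- **HIST** — primary diseases from the medical history, also as PTs.

`pvsignal` models dates as integer day indices (a reader-side parser
converts ISO dates), so onset arithmetic is exact, and represents unknown
sex explicitly rather than as `NA`. The preparation stages are:
deduplication (`dedup_reports()`), linkage (`link_reports()`), and the
standard exclusion of cases with missing sex or age
(`filter_complete_demo()`). Each stage records its counts on the database
object so input, removed and retained rows always reconcile — these counts
also populate the JSON manifest written by `run_pipeline()`.

**Deduplication key.** Source systems say only that duplicate rows were
removed. We take the least destructive reading: exact tuples on
(case, drug, role) for DRUG rows and (case, PT, onset day) for REAC rows.
Two reports of the same PT with different onset days are therefore kept as
distinct events. The operation is idempotent and its removal count is
reported.

**Exclusion accounting.** A case with unknown sex is counted under
"missing sex"; a case with known sex but missing age under "missing age",
so the two exclusion counts and the retained count partition the input.

## Case definitions

Events of interest are *PT sets* — named collections of (code, name)
pairs. Matching is by exact normalized name (case-folded,
whitespace-collapsed) or by numeric PT code when both sides carry one. The
package ships the 51-term vasculitides definition of the 2012 revised
International Chapel Hill Consensus Conference nomenclature
(`vasculitides_pt_set()`), which includes polymyalgia rheumatica
(PT 10036099, `pmr_pt_set()`) because the reporting system's dictionary
files PMR under vasculitides.

Exposures of interest are *drug sets* with a role filter defaulting to
*suspected medicine* — the role that attributes causality. A concomitant
record never counts as exposure. Drug names are normalized and configured
salt suffixes stripped.

Cancer categories are classified from the history table by a configurable
`cancer_map()`. The published category-to-PT mapping is not public, so the
default map pairs each category with its identically-named PT plus obvious
synonyms and is declared approximate; categories may overlap, and any
non-empty, unmatched history falls back to *others/uncertain*.

## The reporting odds ratio and the signal rule

Every 2×2 table is built by **case-level counting**: a case with several
qualifying events contributes once, so a + b + c + d equals the number of
analyzed cases. Event-level tallies (each distinct vasculitis counted per
patient) are available through `event_records()` and the onset summaries,
but are never fed into a ROR: mixing the two units would break the
case-partition invariant of the 2×2 table. This is the conservative
resolution of the tension between "total patients" table headings and
per-event counting language in the source analysis.

The ROR is the cross-product ratio (a·d)/(b·c); its interval is the Woolf
log-normal interval with z = 1.959964 and **no continuity correction**.
Zero cells leave the estimate undefined (`N.A.` in output tables) rather
than applying a Haldane–Anscombe 0.5 correction; the undocumented interval
method was pinned down by reproduction: the Woolf interval reproduces the
published cohort intervals (4.642–49.149 and 0.082–0.569) to all printed
digits, which no corrected variant does. Signals require *strict*
inequalities: ROR > 1 and lower bound > 1, so a perfectly null table is
not a signal.

The comparator population for "all other drugs" is every retained case
without the target drug as suspected medicine; no further restriction is
applied.

## Predictor analysis

Within one drug's exposed cohort, binary predictors (male sex, age decade
≥ 70 — the "older adult" definition) are analyzed two ways:

- **Univariate**: the covariate-by-event 2×2 with the same Woolf interval,
  plus a Pearson chi-square **without Yates continuity correction**. The
  convention is observable: the uncorrected statistic reproduces the
  published p-values (0.104 for the nivolumab sex table, 0.001 for
  pembrolizumab), while the corrected one gives ≈ 0.13 and ≈ 0.002. The
  correction remains available behind a flag.
- **Multivariate**: maximum-likelihood logistic regression (binomial GLM,
  IRLS; 50 iterations, tolerance 1e-8 by default) with Wald intervals
  exp(estimate ± 1.959964·SE). Complete or quasi-complete separation — a
  covariate stratum holding all events or all non-events, e.g. a cohort
  in which every event case is 70+ — is detected from the covariate ×
  outcome cross-tab *before* fitting and reported as `N.A.`; letting IRLS
  drift toward an infinite estimate would print meaningless numbers.

**Hosmer–Lemeshow.** Cases are grouped by fitted probability into up to
ten groups, but identical fitted values are never split: with two binary
covariates there are at most four covariate patterns, so the test runs on
the patterns themselves. The statistic is Σ (O−E)²/(E(1−E/n_g)) with
df = groups − 2, floored at 1 (with a warning) below three groups. With so
few patterns this df convention is conservative relative to the J − p
asymptotics for grouped binary data — its null distribution sits below the
nominal chi-square — so we treat the statistic as a descriptive fit check,
not a calibrated test, and do not assert null uniformity in the test
suite. The published multivariate goodness-of-fit p-values cannot be
reproduced at all without the unpublished joint sex × age distribution of
each cohort; they are out of scope.

**Mann–Whitney U.** U counts pairs (x, y) with x > y, ties as ½ (identical
samples give n₁n₂/2). The p-value is exact by enumeration when
n₁·n₂ ≤ 400 with no ties, otherwise the tie-corrected normal approximation
without continuity correction. The period comparison
(`yearly_event_counts()`) applies it to *yearly* event counts in two
calendar windows; the original granularity (yearly vs quarterly) is
unstated, and yearly is the implemented choice.

## Time to onset and outcomes

Onset is measured from the **first** exposure: the event's onset day minus
the earliest first-administration day over the case's matching suspected
drug records. Bins partition the non-negative integers — [0, 7], [8, 30],
[31, 60], [61, 120], [121, ∞) — and day 0 falls in "within 7 days" (the
source does not state whether same-day onset was possible; including it is
the permissive choice). Missing dates, and negative intervals (event
recorded before first exposure — plausible data-entry noise in spontaneous
reports), are binned as *unknown*; negative intervals are additionally
counted.

Summaries are per case: the earliest qualifying event sets the bin (ties
keep the first record); when qualifying events disagree on outcome, the
best-ranked outcome wins (recovery > remission > no recovery >
after-effects > death > unknown) and the conflict is counted. Displayed
percentages are round(100·k/n), so a column of displayed percentages can
sum to 98–102.

## The synthetic generator

`generate_reports()` emits the four tables plus a ground-truth log from a
fully specified model: demographics (sex, age decade, report year) are
sampled first, drug exposures independently per drug, and each event from
the logistic link

logit P(event) = logit(baseline) + log-ROR·exposed + β_male·male + β_older·older,

so planted coefficients are exactly the quantities the analysis estimates.
For rare events (baseline ≤ 0.01) the case-level ROR converges on the
planted odds ratio; ROR-recovery experiments should respect that
rare-event requirement. Onset delays are log-normal days added to the
first exposure day; outcomes are categorical; duplicates are **verbatim
row copies** (the strictest test of an exact-tuple dedup key); sex and age
are blanked independently, each with `missing_demo_prob`. One seeded
stream with a documented draw order makes output byte-identical across
runs.

`paper_shaped_config()` pins the expected marginals to the published
characteristics of the 573,316-case extract: exposure probabilities give
expected cohort sizes of 8,705 / 5,202 / 2,362 / 1,039 / 876 / 17; ~72%
male and ~44% aged 70+ (the nivolumab-cohort margins, applied
population-wide since exposures are sampled independently of
demographics); PMR as a rare event with planted log-RORs at the published
magnitudes (28.8, 17.4, 26.0) and covariate effects β_older = ln 15,
β_male = ln 2; 5% demographic missingness and duplicates; 40% missing
onset dates; outcome mass concentrated on recovery/remission. Where the
source states no value (onset log-normal μ = ln 45, σ = 1.2; year weights
rising after 2014, when these drugs entered wide use), values were chosen
once as realistic for this reporting system and are not tuned.

What the generator deliberately does **not** emulate: drug co-prescription
correlation, reporting waves and stimulated-reporting artifacts,
under-reporting biases, duplicate reports that differ in content (only
verbatim copies are injected), and any dependence of exposure on
demographics. Passing recovery tests on this generator therefore
demonstrates correctness of the estimators and plumbing under a clean
model — not robustness to the biases of real spontaneous data, which no
disproportionality statistic corrects.

`simulate_ror_tables()` is the generator's vectorized replicate path — the
same case-level binomial model reduced to one drug and one event — used
for Monte-Carlo studies: Woolf coverage of planted RORs in {0.5, 1, 5, 30}
stays within 93–97% over 2,000 replicates, and the null signal-flag rate
at planted ROR = 1 sits near the one-sided 2.5%.

## Validation fixtures

Two deterministic fixtures tie the pipeline to published cohort tables.
`make_table7_fixture()` expands the published cohort margins (total /
male / older, among event and non-event cases) into case-level rows; the
univariate stage then reproduces the published odds ratios exactly,
because univariate analyses depend only on the margins. The joint
sex × age assignment within each stratum is not published; it is fixed
deterministically as close to independence as the margins allow, which
keeps every joint covariate pattern populated so the multivariate fit is
well-behaved (its estimates land near the published multivariate values
but are not asserted — they depend on the unpublished joint distribution).
One numerical footnote: the exact nivolumab age odds ratio from the
printed margins is (35·4890)/(3·3777) = 15.1046, displayed as 15.11 in the
source via double rounding; the package reports the exact value.

`make_table8_fixture()` encodes the published time-to-onset bins and
outcome counts as a report database (representative delays 3, 15, 45, 90,
150 days; bins and outcomes paired by position, as only the margins are
published) and the onset/outcome stage returns the published shares (82% /
76% / 58% recovery-or-remission, 32% within 60 days, 33% within 7 days).

## Problem sizes and numerical choices

The test suite and acceptance script use: 500 replicate cohorts of 50,000
cases for planted-ROR coverage; 2,000 replicates of 20,000 for the null
flag rate; 2,000 replicates per planted value for interval coverage; one
full-generator run of 100,000 cases for end-to-end recovery; and small
generated databases (1,000–5,000 cases) for bookkeeping reconciliation.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted bands while keeping a full run in the low minutes on one core.
Other numerical choices: z = 1.959964 throughout; IRLS tolerance 1e-8
(1e-12 where equality with closed forms is asserted to 6 significant
figures); strict inequalities in the signal rule; `N.A.` literals, never
imputed zeros, for undefined statistics.

## Known limitations

- Disproportionality on spontaneous reports estimates reporting
  association, not incidence or risk; confounding by indication and
  reporting biases are untouched.
- The cancer-category map is approximate by necessity and should be
  overridden when the real category definitions are available.
- The Hosmer–Lemeshow statistic on few covariate patterns is descriptive
  (see above).
- The multivariate results on marginal-expansion fixtures depend on an
  arbitrary (if fixed) joint covariate assignment.
- No multiple-comparison adjustment is applied across a screen, matching
  standard practice for hypothesis-generating pharmacovigilance scans;
  PRR, EBGM and Bayesian alternatives are out of scope.
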