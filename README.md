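# pvsignal

Disproportionality signal detection for spontaneous adverse-event report
databases, built around the analysis that flagged polymyalgia rheumatica
(PMR) as an immune-related adverse event of checkpoint-inhibitor therapy in
a national JADER-style reporting system.

## Who this is for

Pharmacovigilance analysts and pharmacoepidemiologists who work with
four-table spontaneous-report extracts (DEMO / DRUG / REAC / HIST: one case
linked to its drug exposures, coded adverse events and medical history) and
want a tested, scriptable pipeline for:

- table linkage, exact-tuple deduplication, and the standard exclusion of
  cases with missing sex or age;
- MedDRA preferred-term case definitions (a built-in 51-term vasculitides
  set per the 2012 revised Chapel Hill consensus nomenclature, and
  user-defined PT/drug sets) with suspected-medicine exposure semantics;
- reporting-odds-ratio screens with Woolf confidence intervals and the
  lower-bound signal rule;
- within-cohort predictor analysis (chi-square, univariate odds ratios,
  multiple logistic regression with Hosmer–Lemeshow fit, complete-separation
  handling);
- time-to-onset binning and outcome summaries;
- a synthetic report-database generator with planted effects, so the whole
  pipeline is testable without any data download.

## The statistic

For a drug set D and event set E, each analyzed case falls in exactly one
cell of the 2×2 table

|            | drug in D (suspected) | all other drugs |
|------------|----------------------|-----------------|
| event in E | a                    | b               |
| other events | c                  | d               |

The reporting odds ratio is

    ROR = (a/b) / (c/d) = (a·d) / (b·c)

with the Woolf (log-normal) 95% interval

    exp( ln ROR ± 1.959964 · sqrt(1/a + 1/b + 1/c + 1/d) )

A drug–event pair is a **signal** when both the ROR and the lower interval
bound strictly exceed 1. Any zero cell makes the ROR undefined; it is
reported as `N.A.` with no continuity correction. The ROR is a reporting
disproportionality measure, not a risk estimate.

## Worked example

```r
library(pvsignal)

# simulate a spontaneous-report database shaped like the real extract,
# at a tenth of its size, then run the filtering stages
gen <- generate_reports(paper_shaped_config(n_cases = 57000, seed = 2024))
db <- gen$db |> dedup_reports() |> link_reports() |> filter_complete_demo()
db
#> <report_db>
#>   cases: 51452   drug rows: 1683   event rows: 193   history rows: 27130
#>   duplicates removed: drug 82, reac 11, hist 0
#>   orphan rows dropped: drug 0, reac 0, hist 0
#>   exclusions: 2843 missing sex, 2705 missing age; 51452 of 57000 cases retained

screen <- screen_signals(db, icpi_drug_sets(), list(pmr = pmr_pt_set()))
dplyr::select(screen, drug, event, a, ror, ci_low, ci_high, significant)
#>            drug                  event  a  ror ci_low ci_high significant
#> 1     nivolumab polymyalgia_rheumatica 40 20.7  14.38    29.7        TRUE
#> 2 pembrolizumab polymyalgia_rheumatica 15 12.0   7.01    20.6        TRUE
#> 3    ipilimumab polymyalgia_rheumatica 12 19.0  10.38    34.7        TRUE
#> 4  atezolizumab polymyalgia_rheumatica  0   NA     NA      NA          NA
#> 5    durvalumab polymyalgia_rheumatica  0   NA     NA      NA          NA
#> 6      avelumab polymyalgia_rheumatica  0   NA     NA      NA          NA
```

The three drugs with planted log-RORs (28.8, 17.4, 26.0 on the odds scale)
come out as signals; the drugs with no planted effect and almost no exposed
cases are `N.A.` because a zero cell leaves the ROR undefined. Estimates
scatter around the planted values — at ~40 event cases the Woolf interval
spans roughly a factor of two.

Single tables work too; here the age-by-PMR table of the nivolumab cohort
(cells assembled from the published cohort margins):

```r
ror_stats(35, 3, 3777, 4890)
#>    a b    c    d  ror ci_low ci_high significant
#> 1 35 3 3777 4890 15.1  4.642   49.15        TRUE
```

An end-to-end run over CSV inputs — `run_pipeline(run_config(...))` or a
YAML file via `read_run_config()` — writes the characteristics tables,
both screens, the predictor table, the onset/outcome summary, a load
report and a JSON manifest whose stage counts reconcile.

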