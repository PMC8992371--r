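# Small hand-built database used across tests: three complete cases, one
# case with unknown sex, one with missing age; nivolumab suspected for c1,
# concomitant-only for c3.
tiny_db <- function() {
  report_db(
    demo = data.frame(
      case_id = c("c1", "c2", "c3", "c4", "c5"),
      sex = c("female", "male", "male", "unknown", "female"),
      age_decade = c(70, 50, 80, 60, NA),
      report_year = c(2018, 2016, 2019, 2017, 2015)
    ),
    drug = data.frame(
      case_id = c("c1", "c2", "c3", "c3"),
      drug_name = c("nivolumab", "pembrolizumab", "nivolumab", "cisplatin"),
      role = c("suspected", "suspected", "concomitant", "suspected"),
      first_admin_day = c(100L, 200L, 50L, 40L)
    ),
    reac = data.frame(
      case_id = c("c1", "c1", "c2"),
      pt_name = c("Polymyalgia rheumatica", "Vasculitis", "Pyrexia"),
      pt_code = c(10036099L, 10047115L, NA),
      onset_day = c(140L, 105L, 210L),
      outcome = c("remission", "recovery", "unknown")
    ),
    hist = data.frame(
      case_id = c("c1", "c2", "c2", "c3"),
      primary_disease_pt = c("Non-small cell lung cancer", "Melanoma",
                             "Gastric cancer", "Rare disease X")
    )
  )
}

# A small generated database with duplicates and missingness, fixed seed.
small_synth <- function(n = 2000, seed = 42, dup = 0.05, miss = 0.1) {
  cfg <- synthetic_config(
    n_cases = n, seed = seed,
    drugs = data.frame(name = c("nivolumab", "pembrolizumab"),
                       exposure_prob = c(0.3, 0.2)),
    events = data.frame(pt_code = c(10036099L, 10047115L),
                        pt_name = c("Polymyalgia rheumatica", "Vasculitis"),
                        baseline_prob = c(0.02, 0.05)),
    planted_log_ror = data.frame(drug = "nivolumab",
                                 event = "Polymyalgia rheumatica",
                                 log_ror = log(4)),
    missing_demo_prob = miss,
    duplicate_prob = dup,
    missing_onset_prob = 0.2
  )
  generate_reports(cfg)
}
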