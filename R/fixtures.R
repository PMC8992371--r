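# Case-level fixtures that expand published marginal counts into individual
# synthetic case rows, for validating the predictor and onset/outcome stages
# against printed tables. Univariate analyses use only the margins; the
# joint sex x age assignment within a stratum is not published, so it is
# fixed deterministically as close to independence as the margins allow
# (older cases split across sexes in proportion), which keeps every joint
# covariate pattern populated and the multivariate fit well-behaved.

expand_margins <- function(n, n_male, n_older) {
  male <- seq_len(n) <= n_male
  o_male <- round(n_older * n_male / n)
  o_male <- min(max(o_male, n_older - (n - n_male)), n_male, n_older)
  older <- logical(n)
  older[seq_len(o_male)] <- TRUE
  older[n_male + seq_len(n_older - o_male)] <- TRUE
  tibble::tibble(male = male, older = older)
}

#' Cohort fixtures from published sex/age margins
#'
#' For each of the three drugs with polymyalgia rheumatica reports, expands
#' the published cohort margins (total / male / aged 70+, among event and
#' non-event cases) into one case row each, giving an analysis table on
#' which the predictor stage reproduces the published univariate odds
#' ratios exactly. The margins are: nivolumab 8,705 cases (6,306 male,
#' 3,812 older; 38 events of which 32 male, 35 older); pembrolizumab 5,202
#' (3,969 male, 2,879 older; 17 events, 7 male, 12 older); ipilimumab 2,362
#' (1,547 male, 942 older; 12 events, 10 male, 12 older).
#'
#' @return Named list (one per drug) of analysis-table tibbles with columns
#'   `case_id`, `sex`, `age_decade`, `older_adult`, `report_year`,
#'   `exposed_<drug>`, `event_polymyalgia_rheumatica`.
#' @export
make_table7_fixture <- function() {
  margins <- list(
    nivolumab = list(n = 8705, male = 6306, older = 3812,
                     ev = 38, ev_male = 32, ev_older = 35),
    pembrolizumab = list(n = 5202, male = 3969, older = 2879,
                         ev = 17, ev_male = 7, ev_older = 12),
    ipilimumab = list(n = 2362, male = 1547, older = 942,
                      ev = 12, ev_male = 10, ev_older = 12)
  )
  out <- purrr::imap(margins, function(m, drug) {
    ev <- expand_margins(m$ev, m$ev_male, m$ev_older)
    ev$event <- TRUE
    no <- expand_margins(m$n - m$ev, m$male - m$ev_male, m$older - m$ev_older)
    no$event <- FALSE
    all <- dplyr::bind_rows(ev, no)
    out <- tibble::tibble(
      case_id = sprintf("%s%05d", substr(drug, 1, 3), seq_len(nrow(all))),
      sex = ifelse(all$male, "male", "female"),
      age_decade = ifelse(all$older, 70L, 50L),
      older_adult = all$older,
      report_year = 2018L
    )
    out[[paste0("exposed_", drug)]] <- TRUE
    out$event_polymyalgia_rheumatica <- all$event
    out
  })
  # every cohort carries all three exposure columns so the cohorts can be
  # row-bound into one analysis table (a case is exposed only to its drug)
  for (nm in names(out)) {
    for (other in setdiff(names(margins), nm)) {
      out[[nm]][[paste0("exposed_", other)]] <- FALSE
    }
  }
  out
}

#' Report-database fixture from published onset/outcome counts
#'
#' Builds a [report_db] in which each drug's polymyalgia rheumatica cases
#' carry onset days and outcomes that reproduce the published
#' time-to-onset bins and outcome counts: nivolumab bins (7, 1, 4, 6, 4, 16
#' unknown) and outcomes (8 recovery, 23 remission, 7 unknown);
#' pembrolizumab bins (2, 2, 2, 0, 2, 9) and outcomes (5, 8, 3 no recovery,
#' 1 unknown); ipilimumab bins (4, 0, 0, 2, 0, 6) and outcomes (2, 5, 5
#' unknown). Bins and outcomes are paired by position (the margins, not
#' the joint distribution, are published). All cases share first exposure
#' day 1000; representative onset delays are 3, 15, 45, 90 and 150 days.
#'
#' @return A [report_db].
#' @export
make_table8_fixture <- function() {
  bin_days <- c(within_7 = 3L, d8_30 = 15L, d31_60 = 45L, d61_120 = 90L,
                over_121 = 150L, unknown = NA_integer_)
  spec <- list(
    nivolumab = list(bins = c(7, 1, 4, 6, 4, 16),
                     outcomes = c(recovery = 8, remission = 23,
                                  no_recovery = 0, death = 0,
                                  after_effects = 0, unknown = 7)),
    pembrolizumab = list(bins = c(2, 2, 2, 0, 2, 9),
                         outcomes = c(recovery = 5, remission = 8,
                                      no_recovery = 3, death = 0,
                                      after_effects = 0, unknown = 1)),
    ipilimumab = list(bins = c(4, 0, 0, 2, 0, 6),
                      outcomes = c(recovery = 2, remission = 5,
                                   no_recovery = 0, death = 0,
                                   after_effects = 0, unknown = 5))
  )
  rows <- purrr::imap(spec, function(s, drug) {
    n <- sum(s$bins)
    stopifnot(n == sum(s$outcomes))
    delays <- rep(bin_days, times = s$bins)
    outs <- rep(names(s$outcomes), times = s$outcomes)
    tibble::tibble(
      case_id = sprintf("t8_%s_%03d", substr(drug, 1, 3), seq_len(n)),
      drug = drug,
      onset_day = 1000L + delays,
      outcome = outs
    )
  })
  all <- dplyr::bind_rows(rows)
  report_db(
    demo = tibble::tibble(case_id = all$case_id, sex = "male",
                          age_decade = 70L, report_year = 2018L),
    drug = tibble::tibble(case_id = all$case_id, drug_name = all$drug,
                          role = "suspected", first_admin_day = 1000L),
    reac = tibble::tibble(case_id = all$case_id,
                          pt_name = "Polymyalgia rheumatica",
                          pt_code = 10036099L, onset_day = all$onset_day,
                          outcome = all$outcome),
    hist = tibble::tibble(case_id = character(),
                          primary_disease_pt = character())
  )
}
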