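# Synthetic JADER-like report databases with known ground truth: planted
# drug-event log-RORs, covariate effects, demographic missingness, verbatim
# duplicate rows, onset delays and outcome distributions.

#' Configuration for the synthetic report generator
#'
#' Event probabilities use the logistic link,
#' logit P(event) = logit(baseline) + log_ror * exposed + beta_male * male +
#' beta_older * older, so planted coefficients are exactly the quantities
#' the analysis estimates; for rare events (baseline at or below 0.01) the
#' case-level reporting odds ratio converges on exp(log_ror).
#'
#' @param n_cases Number of cases to generate.
#' @param seed Mandatory integer seed; one pseudo-random stream per run with
#'   a fixed draw order (demographics, exposures, events, dates, outcomes,
#'   history, missingness, duplicates), so output is byte-identical across
#'   runs.
#' @param drugs Data frame `name`, `exposure_prob` and optionally `role`
#'   (default `"suspected"`); exposures are sampled independently per drug.
#' @param events Data frame `pt_code`, `pt_name`, `baseline_prob`.
#' @param planted_log_ror Data frame `drug`, `event` (PT name), `log_ror`;
#'   pairs not listed default to 0.
#' @param covariate_effects Data frame `event`, `beta_male`, `beta_older`;
#'   events not listed default to 0.
#' @param sex_prob_male Probability of male sex.
#' @param age_decade_probs Named numeric over decades `"0"`..`"100"`,
#'   normalized internally.
#' @param missing_demo_prob Probability that a case's sex is blanked, and
#'   independently that its age is blanked (each with this probability).
#' @param missing_onset_prob Probability an event's onset date is missing.
#' @param duplicate_prob Per-row probability of appending a verbatim copy in
#'   the DRUG and REAC tables (the strictest test of the dedup key).
#' @param onset_delay List `meanlog`, `sdlog`: log-normal onset delay in
#'   days since first exposure.
#' @param outcome_probs Named numeric over the six outcome categories,
#'   normalized internally.
#' @param years Data frame `year`, `weight` for report years.
#' @param history_pts Optional named numeric: probability a case's history
#'   carries that primary-disease PT (at most one drawn; remaining mass
#'   means no history row).
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n_cases,
                             seed,
                             drugs,
                             events,
                             planted_log_ror = NULL,
                             covariate_effects = NULL,
                             sex_prob_male = 0.6,
                             age_decade_probs = c("40" = 0.1, "50" = 0.2,
                                                  "60" = 0.3, "70" = 0.25,
                                                  "80" = 0.15),
                             missing_demo_prob = 0,
                             missing_onset_prob = 0,
                             duplicate_prob = 0,
                             onset_delay = list(meanlog = log(45), sdlog = 1),
                             outcome_probs = c(recovery = 0.3, remission = 0.3,
                                               no_recovery = 0.1, death = 0.05,
                                               after_effects = 0.05,
                                               unknown = 0.2),
                             years = data.frame(year = 2004:2019, weight = 1),
                             history_pts = NULL) {
  if (missing(seed) || is.null(seed)) rlang::abort("seed is mandatory")
  drugs <- tibble::as_tibble(drugs)
  events <- tibble::as_tibble(events)
  stopifnot(all(c("name", "exposure_prob") %in% names(drugs)),
            all(c("pt_code", "pt_name", "baseline_prob") %in% names(events)))
  if (!"role" %in% names(drugs)) drugs$role <- "suspected"
  stopifnot(all(drugs$role %in% role_levels))
  probs <- c(drugs$exposure_prob, events$baseline_prob, sex_prob_male,
             missing_demo_prob, missing_onset_prob, duplicate_prob)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    rlang::abort("all probabilities must lie in [0, 1]")
  }
  if (is.null(planted_log_ror)) {
    planted_log_ror <- tibble::tibble(drug = character(), event = character(),
                                      log_ror = numeric())
  }
  planted_log_ror <- tibble::as_tibble(planted_log_ror)
  if (is.null(covariate_effects)) {
    covariate_effects <- tibble::tibble(event = character(),
                                        beta_male = numeric(),
                                        beta_older = numeric())
  }
  covariate_effects <- tibble::as_tibble(covariate_effects)
  dec <- as.integer(names(age_decade_probs))
  stopifnot(all(dec %% 10L == 0L), all(dec >= 0L), all(dec <= 100L),
            all(age_decade_probs >= 0), sum(age_decade_probs) > 0)
  stopifnot(setequal(names(outcome_probs), outcome_levels),
            all(outcome_probs >= 0), sum(outcome_probs) > 0)
  years <- tibble::as_tibble(years)
  stopifnot(all(c("year", "weight") %in% names(years)), all(years$weight >= 0))
  structure(list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    drugs = drugs, events = events, planted_log_ror = planted_log_ror,
    covariate_effects = covariate_effects, sex_prob_male = sex_prob_male,
    age_decade_probs = age_decade_probs / sum(age_decade_probs),
    missing_demo_prob = missing_demo_prob,
    missing_onset_prob = missing_onset_prob,
    duplicate_prob = duplicate_prob, onset_delay = onset_delay,
    outcome_probs = outcome_probs / sum(outcome_probs), years = years,
    history_pts = history_pts
  ), class = "synthetic_config")
}

#' Generate a synthetic spontaneous-report database
#'
#' Samples cases under the configured model and emits the four linked
#' tables plus a ground-truth log that reconciles exactly with the tables
#' before duplication and demographic blanking: per-case true demographics
#' and exposure/event assignments, per-event true onset delays, and the
#' injected duplicate rows.
#'
#' @param config A [synthetic_config()].
#' @return List with `db` (a [report_db]) and `truth` (list: `cases` tibble
#'   with `sex_true`, `age_decade_true`, `older_true`, `complete_demo` and
#'   `exposed_*` / `event_*` flags; `events` tibble with true delays;
#'   `n_duplicates` per table).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cases
  cid <- sprintf("case%07d", seq_len(n))

  # 1. demographics
  sex_true <- ifelse(runif(n) < config$sex_prob_male, "male", "female")
  age_true <- as.integer(sample(names(config$age_decade_probs), n,
                                replace = TRUE,
                                prob = config$age_decade_probs))
  year <- sample(config$years$year, n, replace = TRUE,
                 prob = config$years$weight)
  older <- age_true >= 70L

  # 2. exposures (independent per drug)
  expo <- matrix(FALSE, n, nrow(config$drugs),
                 dimnames = list(NULL, config$drugs$name))
  for (j in seq_len(nrow(config$drugs))) {
    expo[, j] <- runif(n) < config$drugs$exposure_prob[j]
  }

  # 3. events via the logistic link
  evmat <- matrix(FALSE, n, nrow(config$events),
                  dimnames = list(NULL, config$events$pt_name))
  male <- sex_true == "male"
  for (k in seq_len(nrow(config$events))) {
    ev <- config$events$pt_name[k]
    eta <- qlogis(config$events$baseline_prob[k])
    pl <- config$planted_log_ror[config$planted_log_ror$event == ev, ]
    for (j in seq_len(nrow(pl))) {
      eta <- eta + pl$log_ror[j] * expo[, pl$drug[j]]
    }
    ce <- config$covariate_effects[config$covariate_effects$event == ev, ]
    if (nrow(ce)) {
      eta <- eta + ce$beta_male[1] * male + ce$beta_older[1] * older
    }
    evmat[, k] <- runif(n) < plogis(eta)
  }

  # 4. drug rows with first-administration days
  idx <- which(expo, arr.ind = TRUE)
  drug_tbl <- tibble::tibble(
    case_id = cid[idx[, 1]],
    drug_name = config$drugs$name[idx[, 2]],
    role = config$drugs$role[idx[, 2]],
    first_admin_day = sample.int(3650L, nrow(idx), replace = TRUE)
  )
  drug_tbl <- dplyr::arrange(drug_tbl, .data$case_id, .data$drug_name)
  first_exposure <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(drug_tbl, .data$role == "suspected"),
                    .data$case_id),
    day0 = min(.data$first_admin_day), .groups = "drop"
  )

  # 5. event rows: onset = first exposure (or a random day) + log-normal delay
  eidx <- which(evmat, arr.ind = TRUE)
  delay <- as.integer(round(stats::rlnorm(nrow(eidx),
                                          config$onset_delay$meanlog,
                                          config$onset_delay$sdlog)))
  reac_tbl <- tibble::tibble(
    case_id = cid[eidx[, 1]],
    pt_name = config$events$pt_name[eidx[, 2]],
    pt_code = config$events$pt_code[eidx[, 2]],
    delay_true = delay
  )
  reac_tbl <- dplyr::left_join(reac_tbl, first_exposure, by = "case_id")
  reac_tbl$day0[is.na(reac_tbl$day0)] <-
    sample.int(3650L, sum(is.na(reac_tbl$day0)), replace = TRUE)
  reac_tbl$onset_day <- reac_tbl$day0 + reac_tbl$delay_true
  if (config$missing_onset_prob > 0) {
    blank <- runif(nrow(reac_tbl)) < config$missing_onset_prob
    reac_tbl$onset_day[blank] <- NA_integer_
  }
  reac_tbl$outcome <- sample(names(config$outcome_probs), nrow(reac_tbl),
                             replace = TRUE, prob = config$outcome_probs)
  reac_tbl <- dplyr::arrange(reac_tbl, .data$case_id, .data$pt_name)
  truth_events <- dplyr::select(reac_tbl, "case_id", "pt_name", "delay_true")
  reac_out <- dplyr::select(reac_tbl, "case_id", "pt_name", "pt_code",
                            "onset_day", "outcome")

  # 6. history
  if (!is.null(config$history_pts)) {
    hp <- config$history_pts
    pick <- sample(c(names(hp), NA_character_), n, replace = TRUE,
                   prob = c(hp, max(0, 1 - sum(hp))))
    hist_tbl <- tibble::tibble(case_id = cid, primary_disease_pt = pick)
    hist_tbl <- hist_tbl[!is.na(hist_tbl$primary_disease_pt), ]
  } else {
    hist_tbl <- tibble::tibble(case_id = character(),
                               primary_disease_pt = character())
  }

  # 7. demographic missingness (sex and age blanked independently)
  sex_obs <- sex_true
  age_obs <- age_true
  if (config$missing_demo_prob > 0) {
    sex_obs[runif(n) < config$missing_demo_prob] <- "unknown"
    age_obs[runif(n) < config$missing_demo_prob] <- NA_integer_
  }
  complete_demo <- sex_obs != "unknown" & !is.na(age_obs)

  # 8. verbatim duplicate rows
  n_dup <- c(drug = 0L, reac = 0L)
  if (config$duplicate_prob > 0) {
    dup <- which(runif(nrow(drug_tbl)) < config$duplicate_prob)
    n_dup[["drug"]] <- length(dup)
    if (length(dup)) drug_tbl <- dplyr::bind_rows(drug_tbl, drug_tbl[dup, ])
    dup <- which(runif(nrow(reac_out)) < config$duplicate_prob)
    n_dup[["reac"]] <- length(dup)
    if (length(dup)) reac_out <- dplyr::bind_rows(reac_out, reac_out[dup, ])
  }

  demo_tbl <- tibble::tibble(case_id = cid, sex = sex_obs,
                             age_decade = age_obs, report_year = year)
  truth_cases <- tibble::tibble(case_id = cid, sex_true = sex_true,
                                age_decade_true = age_true,
                                older_true = older, report_year = year,
                                complete_demo = complete_demo)
  for (d in colnames(expo)) truth_cases[[paste0("exposed_", d)]] <- expo[, d]
  for (e in colnames(evmat)) truth_cases[[paste0("event_", e)]] <- evmat[, e]

  list(
    db = report_db(demo_tbl, drug_tbl, reac_out, hist_tbl),
    truth = list(cases = truth_cases, events = truth_events,
                 n_duplicates = as.list(n_dup))
  )
}

#' A configuration shaped like the real ICPI report database
#'
#' Default marginals approximate the published characteristics of the
#' 573,316-case extract: exposure probabilities put the expected
#' checkpoint-inhibitor counts at the printed values (8,705 nivolumab,
#' 5,202 pembrolizumab, 2,362 ipilimumab, 1,039 atezolizumab, 876
#' durvalumab, 17 avelumab); ~72% male and ~44% aged 70+ (as among the
#' nivolumab cases, since exposures are sampled independently of
#' demographics); polymyalgia rheumatica as a rare event with planted
#' log-RORs at the published signal magnitudes (28.8, 17.4, 26.0).
#'
#' @param n_cases Number of cases; the default is the real extract's size.
#'   Exposure probabilities are fixed, so expected exposure counts scale
#'   proportionally at other sizes.
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @export
paper_shaped_config <- function(n_cases = 573316, seed = 1) {
  n0 <- 573316
  drugs <- tibble::tibble(
    name = c("nivolumab", "pembrolizumab", "ipilimumab", "atezolizumab",
             "durvalumab", "avelumab"),
    exposure_prob = c(8705, 5202, 2362, 1039, 876, 17) / n0
  )
  events <- tibble::tibble(
    pt_code = c(10036099L, 10047115L),
    pt_name = c("Polymyalgia rheumatica", "Vasculitis"),
    baseline_prob = c(1.5e-4, 4e-4)
  )
  planted <- tibble::tibble(
    drug = c("nivolumab", "pembrolizumab", "ipilimumab"),
    event = "Polymyalgia rheumatica",
    log_ror = log(c(28.8, 17.4, 26.0))
  )
  covar <- tibble::tibble(event = "Polymyalgia rheumatica",
                          beta_male = log(2), beta_older = log(15))
  synthetic_config(
    n_cases = n_cases, seed = seed, drugs = drugs, events = events,
    planted_log_ror = planted, covariate_effects = covar,
    sex_prob_male = 6306 / 8705,
    age_decade_probs = c("20" = 0.03, "30" = 0.06, "40" = 0.10, "50" = 0.15,
                         "60" = 0.2221, "70" = 0.25, "80" = 0.15,
                         "90" = 0.035, "100" = 0.0029),
    missing_demo_prob = 0.05,
    missing_onset_prob = 0.4,
    duplicate_prob = 0.05,
    onset_delay = list(meanlog = log(45), sdlog = 1.2),
    outcome_probs = c(recovery = 0.2, remission = 0.55, no_recovery = 0.05,
                      death = 0.01, after_effects = 0.01, unknown = 0.18),
    years = tibble::tibble(year = 2004:2019,
                           weight = c(rep(1, 10), seq(2, 12, 2))),
    history_pts = c("Non-small cell lung cancer" = 0.25, "Melanoma" = 0.05,
                    "Gastric cancer" = 0.08, "Renal cell carcinoma" = 0.05,
                    "Diabetes mellitus" = 0.10)
  )
}

#' Replicate 2x2 tables under the generator's case-level model
#'
#' Fast path for Monte-Carlo studies: each replicate draws one cohort of
#' `n_cases` under the same binomial model as [generate_reports()] with a
#' single drug and a single event and returns its case-level 2x2 cell
#' counts. Exposure ~ Binomial(n, exposure_prob); P(event | exposure) from
#' the logistic link with the planted log-ROR.
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_cases Cases per cohort.
#' @param exposure_prob Exposure probability.
#' @param baseline_prob Event probability among the unexposed.
#' @param log_ror Planted log reporting-odds-ratio.
#' @return Tibble with `n_reps` rows: cells `a`, `b`, `c`, `d`.
#' @export
simulate_ror_tables <- function(n_reps, n_cases, exposure_prob,
                                baseline_prob, log_ror = 0) {
  stopifnot(exposure_prob >= 0, exposure_prob <= 1,
            baseline_prob > 0, baseline_prob < 1)
  p1 <- plogis(qlogis(baseline_prob) + log_ror)
  n_exp <- rbinom(n_reps, n_cases, exposure_prob)
  a <- rbinom(n_reps, n_exp, p1)
  b <- rbinom(n_reps, n_cases - n_exp, baseline_prob)
  tibble::tibble(a = a, b = b, c = n_exp - a, d = n_cases - n_exp - b)
}
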