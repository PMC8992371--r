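test_that("Pearson chi-square without continuity correction matches textbook formula", {
  # identical row proportions -> statistic 0, p 1
  t0 <- chisq_2x2(contingency_table(10, 20, 30, 60))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # zero margin -> undefined
  expect_true(is.na(chisq_2x2(contingency_table(0, 0, 5, 5))$p_value))
  # brute-force oracle: sum over cells of (O-E)^2/E
  brute <- function(a, b, c, d) {
    o <- matrix(c(a, c, b, d), 2, 2)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    sum((o - e)^2 / e)
  }
  set.seed(3)
  for (i in 1:30) {
    cells <- sample(1:40, 4, replace = TRUE)
    got <- chisq_2x2(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(got$statistic, brute(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
  # invariant under simultaneous row and column swaps
  s1 <- chisq_2x2(contingency_table(7, 12, 40, 90))$statistic
  s2 <- chisq_2x2(contingency_table(90, 40, 12, 7))$statistic
  expect_equal(s1, s2)
})

test_that("univariate odds ratios match the published cohort analyses", {
  # ipilimumab PMR by sex: 2.645 (0.578-12.10)
  u <- univariate_or(contingency_table(10, 2, 1537, 813))
  expect_equal(round(u$or, 3), 2.645)
  expect_equal(round(u$ci_low, 3), 0.578)
  expect_equal(round(u$ci_high, 2), 12.10)
  # pembrolizumab PMR by age: 1.940 (0.683-5.516)
  u2 <- univariate_or(contingency_table(12, 5, 2867, 2318))
  expect_equal(round(u2$or, 3), 1.940)
  expect_equal(round(u2$ci_low, 3), 0.683)
  expect_equal(round(u2$ci_high, 3), 5.516)
  expect_equal(univariate_or(contingency_table(1, 1, 1, 1))$or, 1)
})

test_that("logistic fit is flagged on degenerate or separated data", {
  dat <- tibble::tibble(outcome = rep(FALSE, 10), x = rep(c(TRUE, FALSE), 5))
  expect_error(fit_event_predictors(dat, "outcome", "x"), "degenerate")
  # complete separation: all events in one stratum
  dat2 <- tibble::tibble(
    outcome = c(rep(TRUE, 12), rep(FALSE, 50)),
    older = c(rep(TRUE, 12), rep(TRUE, 20), rep(FALSE, 30))
  )
  fit <- fit_event_predictors(dat2, "outcome", "older")
  expect_equal(fit$separated, "older")
  expect_true(all(is.na(tidy(fit)$odds_ratio)))
  expect_true(glance(fit)$separated)
  expect_error(hosmer_lemeshow(fit), "separated|converged")
})

test_that("fitted model recovers planted covariate effects", {
  set.seed(4)
  n <- 50000
  male <- runif(n) < 0.6
  older <- runif(n) < 0.4
  p <- plogis(qlogis(0.002) + log(15) * older + log(2) * male)
  dat <- tibble::tibble(outcome = runif(n) < p, male = male, older = older)
  fit <- fit_event_predictors(dat, "outcome", c("male", "older"))
  td <- tidy(fit)
  expect_true(fit$converged)
  or_male <- td[td$term == "male", ]
  or_older <- td[td$term == "older", ]
  expect_true(or_male$ci_low <= 2 && 2 <= or_male$ci_high)
  expect_true(or_older$ci_low <= 15 && 15 <= or_older$ci_high)
  # model log-likelihood improves on the intercept-only fit
  ll0 <- as.numeric(stats::logLik(glm(dat$outcome ~ 1, family = binomial())))
  expect_gte(glance(fit)$log_lik, ll0)
})

test_that("Hosmer-Lemeshow collapses covariate patterns and floors df", {
  set.seed(5)
  n <- 4000
  male <- runif(n) < 0.5
  older <- runif(n) < 0.5
  p <- plogis(-2 + 0.8 * older + 0.4 * male + 0.5 * (male & older))
  dat <- tibble::tibble(outcome = runif(n) < p, male = male, older = older,
                        inter = male & older)
  # saturated model: fitted = observed in every pattern -> statistic ~ 0
  fit_sat <- fit_event_predictors(dat, "outcome", c("male", "older", "inter"))
  hl_sat <- hosmer_lemeshow(fit_sat)
  expect_equal(hl_sat$statistic, 0, tolerance = 1e-8)
  expect_equal(hl_sat$n_groups, 4L)
  expect_equal(hl_sat$df, 2L)          # groups collapsed to 4 -> df = 2
  # single binary covariate: 2 groups -> df floored at 1 with a warning
  fit1 <- fit_event_predictors(dat, "outcome", "male")
  expect_warning(hl1 <- hosmer_lemeshow(fit1), "floored")
  expect_equal(hl1$df, 1L)
})

test_that("Mann-Whitney U matches the brute-force pairwise count", {
  brute_u <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  # identical samples -> U = n1*n2/2
  expect_equal(mann_whitney_u(1:5, 1:5)$u, 12.5)
  # complete separation convention: U counts pairs with x > y
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$u, 0)
  expect_equal(mann_whitney_u(c(3, 4), c(1, 2))$u, 4)
  set.seed(6)
  for (i in 1:20) {
    x <- sample(1:30, sample(3:8, 1), replace = TRUE)
    y <- sample(1:30, sample(3:8, 1), replace = TRUE)
    expect_equal(unname(mann_whitney_u(x, y)$u), brute_u(x, y))
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("yearly event counts reconcile and the period test behaves", {
  gen <- small_synth(n = 2000, seed = 31, dup = 0, miss = 0)
  db <- link_reports(dedup_reports(gen$db))
  yc <- yearly_event_counts(db, pmr_pt_set(), 2004:2013, 2014:2019)
  at <- build_analysis_table(db, drug_set("nivolumab", "nivolumab"),
                             pmr_pt_set())
  n_event_cases <- sum(at$event_polymyalgia_rheumatica &
                         at$report_year %in% 2004:2019)
  expect_equal(sum(yc$counts_a$n) + sum(yc$counts_b$n), n_event_cases)
  expect_error(yearly_event_counts(db, pmr_pt_set(), integer(0), 2014:2019),
               "non-empty")
  # all reports in one year
  db1 <- db
  db1$demo$report_year <- 2010L
  yc1 <- yearly_event_counts(db1, pmr_pt_set(), 2004:2013, 2014:2019)
  expect_equal(yc1$counts_a$n[yc1$counts_a$year == 2010], n_event_cases)
  expect_equal(sum(yc1$counts_b$n), 0)
  # constant yearly rate: rarely significant at the 5% level
  set.seed(7)
  sig <- replicate(500, {
    mann_whitney_u(stats::rpois(10, 5), stats::rpois(6, 5))$p_value < 0.05
  })
  expect_gte(mean(!sig), 0.9)
})

test_that("predictor table handles cohorts with no events", {
  cases <- tibble::tibble(
    case_id = as.character(1:50), sex = rep(c("male", "female"), 25),
    age_decade = rep(c(50L, 80L), 25), older_adult = rep(c(FALSE, TRUE), 25),
    report_year = 2018L, exposed_drugx = TRUE, event_pmr = FALSE
  )
  out <- predictor_table(cases, "drugx", "pmr")
  expect_equal(nrow(out), 2)
  expect_true(all(is.na(out$multi_or)))
  expect_true(all(is.na(out$uni_or)))   # zero event cells
})
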