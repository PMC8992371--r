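# Predictor analysis within an exposed cohort: chi-square + OR univariate,
# multiple logistic regression (sex, age >= 70) with Hosmer-Lemeshow fit,
# and the Mann-Whitney period comparison.

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square, by default WITHOUT the Yates continuity correction
#' (this convention matters: the corrected statistic gives visibly larger
#' p-values on sparse pharmacovigilance tables). df = 1; a zero margin
#' makes the statistic undefined.
#'
#' @param t A [contingency_table].
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return Tibble `statistic`, `p_value` (NA on a zero margin).
#' @export
chisq_2x2 <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  m <- matrix(c(t$a, t$c, t$b, t$d), 2, 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_))
  }
  st <- suppressWarnings(chisq.test(m, correct = correct))
  tibble::tibble(statistic = unname(st$statistic), p_value = st$p.value)
}

#' Univariate odds ratio with Woolf interval
#'
#' The within-cohort analogue of the ROR: same 2x2 arithmetic and Woolf
#' log-normal interval, applied to a covariate-by-event table.
#'
#' @inheritParams ror_stats
#' @return One-row tibble `or`, `ci_low`, `ci_high`.
#' @export
univariate_or <- function(t, level = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  s <- ror_stats(t, level = level)
  tibble::tibble(or = s$ror, ci_low = s$ci_low, ci_high = s$ci_high)
}

# Quasi-/complete separation on a binary covariate shows up as a zero cell
# in the covariate x outcome cross-tab: the MLE for that coefficient is
# infinite and IRLS would drift instead of converging.
separated_terms <- function(data, outcome, terms) {
  y <- as.logical(data[[outcome]])
  bad <- character()
  for (tm in terms) {
    x <- as.logical(data[[tm]])
    tab <- table(factor(x, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
    if (any(tab[, "TRUE"] == 0) || any(tab[, "FALSE"] == 0)) bad <- c(bad, tm)
  }
  bad
}

#' Fit a logistic predictor model
#'
#' Maximum-likelihood logistic regression (binomial GLM, iteratively
#' reweighted least squares) of a binary event on binary covariates within
#' an exposed cohort. Complete or quasi-complete separation — a covariate
#' stratum containing all events or all non-events — is detected up front
#' and flagged instead of letting the fit drift to an infinite estimate;
#' a separated fit carries no coefficient table.
#'
#' @param data Data frame, one row per case, with a binary outcome column
#'   and binary covariate columns.
#' @param outcome Name of the outcome column.
#' @param terms Character vector of covariate column names.
#' @param max_iter IRLS iteration cap (default 50).
#' @param tol IRLS convergence tolerance (default 1e-8).
#' @return A `pv_logistic` object; use [tidy()] for the per-term table
#'   (estimates, Wald 95% CIs as exp(estimate +/- 1.96 SE), p-values) and
#'   [glance()] for fit-level statistics.
#' @export
fit_event_predictors <- function(data, outcome, terms,
                                 max_iter = 50, tol = 1e-8) {
  data <- tibble::as_tibble(data)
  y <- as.logical(data[[outcome]])
  if (anyNA(y)) rlang::abort("outcome contains missing values")
  if (all(y) || !any(y)) {
    rlang::abort("outcome is degenerate: need at least one event and one non-event")
  }
  sep <- separated_terms(data, outcome, terms)
  if (length(sep)) {
    return(structure(list(model = NULL, terms = terms, outcome = outcome,
                          separated = sep, converged = FALSE,
                          n = nrow(data), n_events = sum(y)),
                     class = "pv_logistic"))
  }
  df <- data.frame(.y = as.integer(y),
                   lapply(data[terms], as.integer), check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- glm(fml, family = binomial(), data = df,
             control = stats::glm.control(epsilon = tol, maxit = max_iter))
  structure(list(model = fit, terms = terms, outcome = outcome,
                 separated = character(), converged = fit$converged,
                 n = nrow(data), n_events = sum(y)),
            class = "pv_logistic")
}

#' @export
print.pv_logistic <- function(x, ...) {
  if (length(x$separated)) {
    cat(sprintf("<pv_logistic> separation detected on: %s (no estimates)\n",
                paste(x$separated, collapse = ", ")))
  } else {
    cat(sprintf("<pv_logistic> %d cases, %d events; converged: %s\n",
                x$n, x$n_events, x$converged))
    print(tidy(x))
  }
  invisible(x)
}

#' @rdname fit_event_predictors
#' @param x A `pv_logistic` fit.
#' @param conf_level Confidence level for the Wald interval.
#' @param ... Unused.
#' @export
tidy.pv_logistic <- function(x, conf_level = 0.95, ...) {
  if (length(x$separated)) {
    return(tibble::tibble(term = x$terms, estimate = NA_real_,
                          std.error = NA_real_, statistic = NA_real_,
                          p.value = NA_real_, odds_ratio = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_))
  }
  est <- coef(x$model)
  se <- sqrt(diag(vcov(x$model)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  stat <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * stats::pnorm(-abs(stat))),
    odds_ratio = exp(unname(est)),
    ci_low = exp(unname(est - z * se)),
    ci_high = exp(unname(est + z * se))
  )
}

#' @rdname fit_event_predictors
#' @export
glance.pv_logistic <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_events = x$n_events,
    converged = x$converged,
    separated = length(x$separated) > 0,
    n_iter = if (is.null(x$model)) NA_integer_ else x$model$iter,
    log_lik = if (is.null(x$model)) NA_real_ else as.numeric(logLik(x$model))
  )
}

#' Hosmer-Lemeshow goodness of fit
#'
#' Cases are grouped by fitted probability into up to `n_groups` bins;
#' identical fitted values are never split across groups, so with a few
#' binary covariates the groups collapse to the covariate patterns (at most
#' four with two covariates). The statistic is sum over groups of
#' (O - E)^2 / (E (1 - E/n_g)) with df = groups - 2, floored at 1 (with a
#' warning) when fewer than 3 groups remain.
#'
#' @param fit A converged `pv_logistic`.
#' @param data The data the model was fitted on.
#' @param n_groups Target number of groups (default 10).
#' @return Tibble `statistic`, `df`, `p_value`, `n_groups`.
#' @export
hosmer_lemeshow <- function(fit, data = NULL, n_groups = 10) {
  stopifnot(inherits(fit, "pv_logistic"))
  if (length(fit$separated) || is.null(fit$model)) {
    rlang::abort("hosmer_lemeshow requires a converged, non-separated fit")
  }
  p <- unname(fitted(fit$model))
  y <- fit$model$y
  distinct_p <- sort(unique(p))
  if (length(distinct_p) <= n_groups) {
    # few covariate patterns: one group per distinct fitted probability
    g <- factor(match(p, distinct_p))
  } else {
    breaks <- unique(stats::quantile(p, probs = seq(0, 1,
                                                    length.out = n_groups + 1)))
    g <- cut(p, breaks = breaks, include.lowest = TRUE)
  }
  obs <- tapply(y, g, sum)
  expd <- tapply(p, g, sum)
  ng <- tapply(y, g, length)
  keep <- !is.na(obs)
  obs <- obs[keep]; expd <- expd[keep]; ng <- ng[keep]
  k <- length(obs)
  stat <- sum((obs - expd)^2 / (expd * (1 - expd / ng)))
  df <- k - 2L
  if (df < 1L) {
    rlang::warn("fewer than 3 groups after collapsing; df floored at 1")
    df <- 1L
  }
  tibble::tibble(statistic = stat, df = as.integer(df),
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 n_groups = as.integer(k))
}

#' Mann-Whitney U test
#'
#' U is the number of (x, y) pairs with x > y, counting ties as 1/2 (so
#' identical samples give U = n1*n2/2). The p-value is exact (full
#' enumeration) when n1*n2 <= 400 and there are no ties, otherwise the
#' tie-corrected normal approximation without continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return Tibble `u`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) rlang::abort("both samples must be non-empty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) * length(y) <= 400) && !ties
  st <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  tibble::tibble(u = unname(st$statistic), p_value = st$p.value,
                 method = ifelse(exact, "exact", "normal approximation"))
}

#' Yearly event counts and period comparison
#'
#' Counts the event cases per report year in two calendar windows and
#' compares the two vectors of yearly counts with the Mann-Whitney U test
#' (years with no reports count as zero).
#'
#' @param db A filtered [report_db].
#' @param pset A [pt_set] defining the event.
#' @param period_a,period_b Integer year ranges, e.g. `2004:2013`.
#' @return List with tibbles `counts_a`, `counts_b` (`year`, `n`) and
#'   `test` (`u`, `p_value`, `method`).
#' @export
yearly_event_counts <- function(db, pset, period_a, period_b) {
  stopifnot(inherits(db, "report_db"))
  if (!length(period_a) || !length(period_b)) {
    rlang::abort("both periods must be non-empty year ranges")
  }
  ids <- unique(event_records(db, pset)$case_id)
  yrs <- db$demo$report_year[db$demo$case_id %in% ids]
  count_period <- function(period) {
    tibble::tibble(year = as.integer(period),
                   n = vapply(period, function(y) sum(yrs == y, na.rm = TRUE),
                              integer(1)))
  }
  ca <- count_period(period_a)
  cb <- count_period(period_b)
  list(counts_a = ca, counts_b = cb, test = mann_whitney_u(ca$n, cb$n))
}

#' Univariate and multivariate predictor table for one drug cohort
#'
#' Within the cases exposed to a drug set: for each binary predictor (male
#' sex, older adult i.e. age decade >= 70), the univariate odds ratio with
#' Woolf 95% CI and Pearson chi-square p-value; then a multiple logistic
#' regression on both predictors with Wald CIs/p-values and the
#' Hosmer-Lemeshow goodness-of-fit p-value. When a predictor exhibits
#' complete separation the multivariate block is NA (rendered "N.A."),
#' mirroring how such cohorts are reported.
#'
#' @param cases Analysis table from [build_analysis_table()] containing
#'   `sex`, `older_adult`, the `exposed_<drug>` and `event_<event>` columns.
#' @param drug_name,event_name Names of the drug set and event set.
#' @param correct Yates correction for the chi-square (default FALSE).
#' @return Tibble, one row per predictor, with `uni_*`, `multi_*` and
#'   `hl_p` columns.
#' @export
predictor_table <- function(cases, drug_name, event_name, correct = FALSE) {
  cohort <- cases[cases[[paste0("exposed_", drug_name)]], , drop = FALSE]
  dat <- tibble::tibble(
    outcome = cohort[[paste0("event_", event_name)]],
    male = cohort$sex == "male",
    older_adult = cohort$older_adult
  )
  uni <- purrr::map_dfr(c("male", "older_adult"), function(tm) {
    t <- build_contingency(dat, tm, "outcome")
    dplyr::bind_cols(tibble::tibble(term = tm), univariate_or(t),
                     dplyr::rename(chisq_2x2(t, correct = correct),
                                   chisq = "statistic", p_value = "p_value"))
  })
  names(uni) <- c("term", "uni_or", "uni_ci_low", "uni_ci_high",
                  "uni_chisq", "uni_p")
  degenerate <- nrow(dat) == 0 || all(dat$outcome) || !any(dat$outcome)
  fit <- if (degenerate) NULL else {
    fit_event_predictors(dat, "outcome", c("male", "older_adult"))
  }
  if (degenerate || length(fit$separated)) {
    multi <- tibble::tibble(term = c("male", "older_adult"),
                            multi_or = NA_real_, multi_ci_low = NA_real_,
                            multi_ci_high = NA_real_, multi_p = NA_real_)
    hl_p <- NA_real_
  } else {
    td <- dplyr::filter(tidy(fit), .data$term != "(Intercept)")
    multi <- tibble::tibble(term = td$term, multi_or = td$odds_ratio,
                            multi_ci_low = td$ci_low,
                            multi_ci_high = td$ci_high, multi_p = td$p.value)
    hl_p <- hosmer_lemeshow(fit)$p_value
  }
  out <- dplyr::left_join(uni, multi, by = "term")
  out$hl_p <- hl_p
  out$drug <- drug_name
  out$event <- event_name
  out$n <- nrow(dat)
  out$n_events <- sum(dat$outcome)
  dplyr::relocate(out, "drug", "event")
}

#' Predictor tables across several drug cohorts
#'
#' @param cases Analysis table.
#' @param drug_sets Named list of [drug_set] objects.
#' @param pset The event [pt_set].
#' @param correct Yates correction flag, passed through.
#' @return Row-bound [predictor_table()] results.
#' @export
predictor_analysis <- function(cases, drug_sets, pset, correct = FALSE) {
  if (inherits(drug_sets, "drug_set")) drug_sets <- list(drug_sets)
  purrr::map_dfr(drug_sets, function(ds) {
    predictor_table(cases, ds$name, pset$name, correct = correct)
  })
}

#' Write a predictor table to CSV with "N.A." literals
#'
#' @param tbl Output of [predictor_analysis()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_predictor_csv <- function(tbl, path) {
  out <- dplyr::mutate(tbl, dplyr::across(
    dplyr::where(is.numeric),
    ~ ifelse(is.na(.x), "N.A.", formatC(.x, format = "fg", digits = 6))
  ))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
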