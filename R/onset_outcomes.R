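# Time-to-onset since first exposure, binning, and outcome tabulation.

onset_bin_levels <- c("within_7", "d8_30", "d31_60", "d61_120", "over_121",
                      "unknown")
onset_bin_labels <- c(within_7 = "Within 7 days", d8_30 = "8-30 days",
                      d31_60 = "31-60 days", d61_120 = "61-120 days",
                      over_121 = "Over 121 days", unknown = "Unknown")

# Best-ranked outcome wins when a case's qualifying events disagree.
outcome_rank <- c(recovery = 1, remission = 2, no_recovery = 3,
                  after_effects = 4, death = 5, unknown = 6)

#' Bin a time-to-onset in days
#'
#' The bins partition the non-negative integers: \[0, 7\], \[8, 30\],
#' \[31, 60\], \[61, 120\], \[121, Inf); missing values — and negative
#' intervals, which are treated as data-entry noise — fall in `unknown`.
#' Day 0 counts as within 7 days.
#'
#' @param days Integer vector of onset delays (may contain NA).
#' @return Ordered factor over the six bins.
#' @examples
#' bin_onset(c(0, 7, 8, 60, 61, 121, NA))
#' @export
bin_onset <- function(days) {
  lab <- dplyr::case_when(
    is.na(days) | days < 0 ~ "unknown",
    days <= 7 ~ "within_7",
    days <= 30 ~ "d8_30",
    days <= 60 ~ "d31_60",
    days <= 120 ~ "d61_120",
    TRUE ~ "over_121"
  )
  factor(lab, levels = onset_bin_levels, ordered = TRUE)
}

#' Per-event onset delay since first drug exposure
#'
#' For each event matching the PT set in a case exposed to the drug set,
#' the delay is the event's onset day minus the earliest first-administration
#' day over the case's matching drug records (first exposure). The delay is
#' missing when either date is missing; negative delays (event recorded
#' before first exposure) are flagged and binned as unknown.
#'
#' @param db A filtered [report_db].
#' @param dset The exposure [drug_set].
#' @param pset The event [pt_set].
#' @return Tibble, one row per qualifying event: `case_id`, `pt_name`,
#'   `onset_days`, `negative_onset`, `outcome`, with events in original
#'   record order within case.
#' @export
event_onsets <- function(db, dset, pset) {
  stopifnot(inherits(db, "report_db"))
  exposed_ids <- dplyr::filter(flag_exposure(db, dset), .data$exposed)$case_id
  ev <- event_records(db, pset)
  ev <- ev[ev$case_id %in% exposed_ids, , drop = FALSE]
  drows <- db$drug[normalize_drug_name(db$drug$drug_name) %in% dset$generic_names &
                     db$drug$role == dset$role_filter, , drop = FALSE]
  first_admin <- dplyr::summarise(
    dplyr::group_by(drows, .data$case_id),
    first_admin_day = if (all(is.na(.data$first_admin_day))) NA_integer_
                      else min(.data$first_admin_day, na.rm = TRUE),
    .groups = "drop"
  )
  ev <- dplyr::left_join(ev, first_admin, by = "case_id")
  delay <- ev$onset_day - ev$first_admin_day
  tibble::tibble(
    case_id = ev$case_id,
    pt_name = ev$pt_name,
    onset_days = ifelse(!is.na(delay) & delay < 0, NA_integer_, delay),
    negative_onset = !is.na(delay) & delay < 0,
    outcome = ev$outcome
  )
}

#' Time-to-onset and outcome summary for a drug-event pair
#'
#' One row per exposed case with a qualifying event. The case's bin comes
#' from its earliest qualifying event (missing delays sort last; ties keep
#' the first record); its outcome is the best-ranked outcome over its
#' qualifying events (recovery > remission > no recovery > after-effects >
#' death > unknown), with conflicts counted. Displayed percentages are
#' round(100 k / n).
#'
#' @param db A filtered [report_db].
#' @param dset The exposure [drug_set].
#' @param pset The event [pt_set].
#' @return An `onset_summary`: list with `drug`, `event`, `n_cases`,
#'   tibbles `bins` and `outcomes` (`n`, `pct`), `recovery_remission_pct`,
#'   `n_negative_onset`, `n_outcome_conflicts`.
#' @export
onset_outcome_summary <- function(db, dset, pset) {
  ev <- event_onsets(db, dset, pset)
  empty <- function() {
    structure(list(
      drug = dset$name, event = pset$name, n_cases = 0L,
      bins = tibble::tibble(bin = factor(onset_bin_levels,
                                         levels = onset_bin_levels,
                                         ordered = TRUE),
                            n = 0L, pct = NA_real_),
      outcomes = tibble::tibble(outcome = outcome_levels, n = 0L,
                                pct = NA_real_),
      recovery_remission_pct = NA_real_,
      n_negative_onset = 0L, n_outcome_conflicts = 0L
    ), class = "onset_summary")
  }
  if (nrow(ev) == 0) return(empty())

  per_case <- dplyr::summarise(
    dplyr::group_by(ev, .data$case_id),
    onset_days = {
      d <- .data$onset_days
      if (all(is.na(d))) NA_integer_ else d[which.min(replace(d, is.na(d), Inf))]
    },
    conflict = dplyr::n_distinct(.data$outcome) > 1,
    outcome = .data$outcome[which.min(outcome_rank[.data$outcome])],
    .groups = "drop"
  )
  n <- nrow(per_case)
  bins <- tibble::as_tibble(table(bin = bin_onset(per_case$onset_days)))
  bins$bin <- factor(bins$bin, levels = onset_bin_levels, ordered = TRUE)
  bins$n <- as.integer(bins$n)
  bins$pct <- round(100 * bins$n / n)
  outs <- tibble::as_tibble(table(outcome = factor(per_case$outcome,
                                                   levels = outcome_levels)))
  outs$n <- as.integer(outs$n)
  outs$pct <- round(100 * outs$n / n)
  rr <- sum(outs$n[outs$outcome %in% c("recovery", "remission")])
  structure(list(
    drug = dset$name, event = pset$name, n_cases = n,
    bins = dplyr::arrange(bins, .data$bin),
    outcomes = outs,
    recovery_remission_pct = round(100 * rr / n),
    n_negative_onset = sum(ev$negative_onset),
    n_outcome_conflicts = sum(per_case$conflict)
  ), class = "onset_summary")
}

#' @export
print.onset_summary <- function(x, ...) {
  cat(sprintf("<onset_summary> %s / %s: %d cases\n", x$drug, x$event, x$n_cases))
  if (x$n_cases > 0) {
    b <- x$bins
    cat("  time to onset: ",
        paste(sprintf("%s %d", onset_bin_labels[as.character(b$bin)], b$n),
              collapse = ", "), "\n", sep = "")
    o <- x$outcomes[x$outcomes$n > 0, ]
    cat("  outcomes: ",
        paste(sprintf("%s %d (%d%%)", o$outcome, o$n, o$pct), collapse = ", "),
        "\n", sep = "")
    cat(sprintf("  recovery or remission: %d%%\n", x$recovery_remission_pct))
  }
  invisible(x)
}

#' @rdname onset_outcome_summary
#' @param x An `onset_summary`.
#' @param ... Unused.
#' @export
tidy.onset_summary <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(drug = x$drug, event = x$event, block = "onset",
                   category = as.character(x$bins$bin), n = x$bins$n,
                   pct = x$bins$pct),
    tibble::tibble(drug = x$drug, event = x$event, block = "outcome",
                   category = x$outcomes$outcome, n = x$outcomes$n,
                   pct = x$outcomes$pct)
  )
}

#' Write onset/outcome summaries to CSV
#'
#' @param summaries A single `onset_summary` or a list of them.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_onset_csv <- function(summaries, path) {
  if (inherits(summaries, "onset_summary")) summaries <- list(summaries)
  readr::write_csv(purrr::map_dfr(summaries, tidy), path, progress = FALSE)
  invisible(path)
}

#' Bar chart of time-to-onset bins
#'
#' @param object An `onset_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.onset_summary <- function(object, ...) {
  b <- object$bins
  b$label <- factor(onset_bin_labels[as.character(b$bin)],
                    levels = unname(onset_bin_labels))
  ggplot2::ggplot(b, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "time to onset since first exposure", y = "cases",
                  title = sprintf("%s / %s (n = %d)", object$drug,
                                  object$event, object$n_cases)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
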