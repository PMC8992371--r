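# Reporting odds ratio disproportionality: 2x2 tables, Woolf intervals,
# and the lower-CI > 1 signal rule.

#' Construct a 2x2 contingency table of report counts
#'
#' Cells follow the standard disproportionality layout: `a` = cases with
#' the target event reported under the target drug, `b` = target event
#' under all other drugs, `c` = other events under the target drug, `d` =
#' other events under all other drugs. Counting is case-level: each case
#' contributes to exactly one cell, so a + b + c + d equals the number of
#' analyzed cases.
#'
#' @param a,b,c,d Non-negative counts.
#' @return A `contingency_table` object.
#' @examples
#' contingency_table(35, 3, 3777, 4890)
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    rlang::abort("contingency_table: cells must be non-negative counts")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("event", "no event"),
                              c("target drug", "other drugs")))
  cat("<contingency_table> n =", x$a + x$b + x$c + x$d, "\n")
  print(m)
  invisible(x)
}

#' Build a 2x2 table from the analysis table
#'
#' Cross-tabulates one logical exposure column against one logical event
#' column by case-level counting.
#'
#' @param cases Analysis table from [build_analysis_table()], or any data
#'   frame with the two logical columns.
#' @param exposed,event Column names (strings) of the exposure and event
#'   indicators.
#' @return A [contingency_table].
#' @export
build_contingency <- function(cases, exposed, event) {
  e <- cases[[exposed]]
  v <- cases[[event]]
  stopifnot(is.logical(e), is.logical(v))
  contingency_table(a = sum(e & v), b = sum(!e & v),
                    c = sum(e & !v), d = sum(!e & !v))
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' The ROR is (a/b)/(c/d) = (a*d)/(b*c). The interval is the Woolf
#' (log-normal) interval exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))
#' with no continuity correction. When any cell is zero the ROR and its
#' interval are undefined and reported as NA (rendered "N.A." in output
#' tables); no Haldane-Anscombe 0.5 correction is applied. A pair is a
#' signal when both the ROR and the lower bound strictly exceed 1.
#'
#' All functions are vectorized over the cell counts; `ror_stats()` returns
#' the full one-row-per-table summary.
#'
#' @param a,b,c,d Cell counts (vectors of equal length), or `t` a
#'   [contingency_table].
#' @param level Confidence level (default 0.95).
#' @return `ror_stats()`: tibble with columns `a,b,c,d,ror,ci_low,ci_high,
#'   significant`. `ror_estimate()`: numeric vector. `ror_ci()`: tibble
#'   `ci_low`, `ci_high`.
#' @examples
#' ror_stats(35, 3, 3777, 4890)
#' @export
ror_stats <- function(a, b, c, d, level = 0.95) {
  if (inherits(a, "contingency_table")) {
    t <- a
    a <- t$a; b <- t$b; c <- t$c; d <- t$d
  }
  stopifnot(level > 0, level < 1)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(ok, (a * d) / (b * c), NA_real_)
  z <- qnorm(1 - (1 - level) / 2)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  ci_low <- exp(log(ror) - z * se)
  ci_high <- exp(log(ror) + z * se)
  tibble::tibble(
    a = a, b = b, c = c, d = d,
    ror = ror, ci_low = ci_low, ci_high = ci_high,
    significant = ifelse(ok, ror > 1 & ci_low > 1, NA)
  )
}

#' @rdname ror_stats
#' @param t A [contingency_table].
#' @export
ror_estimate <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  ror_stats(t)$ror
}

#' @rdname ror_stats
#' @export
ror_ci <- function(t, level = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  s <- ror_stats(t, level = level)
  tibble::tibble(ci_low = s$ci_low, ci_high = s$ci_high)
}

#' @rdname ror_stats
#' @export
detect_signal <- function(t, level = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  s <- ror_stats(t, level = level)
  structure(
    list(table = t, ror = s$ror, ci_low = s$ci_low, ci_high = s$ci_high,
         significant = s$significant, level = level),
    class = "signal_result"
  )
}

#' @export
print.signal_result <- function(x, ...) {
  if (is.na(x$ror)) {
    cat("<signal_result> ROR = N.A. (zero cell)\n")
  } else {
    cat(sprintf("<signal_result> ROR = %.3f  %g%% CI (%.3f, %.3f)  signal: %s\n",
                x$ror, 100 * x$level, x$ci_low, x$ci_high,
                ifelse(x$significant, "yes", "no")))
  }
  invisible(x)
}

#' Screen every drug set against every event set
#'
#' One reporting-odds-ratio analysis per (drug set, event set) pair over the
#' analyzed cases, in deterministic order (drug sets outer, event sets
#' inner). Undefined statistics (zero cells) are NA and rendered "N.A." on
#' write.
#'
#' @param cases Analysis table containing the needed `exposed_*` / `event_*`
#'   columns, or a [report_db] (flags are then computed here).
#' @param drug_sets Named list of [drug_set] objects.
#' @param pt_sets Named list of [pt_set] objects.
#' @param level Confidence level.
#' @return A `ror_screen` tibble: `drug`, `event`, `n_event` (= a),
#'   `n_other` (= c), cells, ROR, CI and signal flag.
#' @export
screen_signals <- function(cases, drug_sets, pt_sets, level = 0.95) {
  if (inherits(drug_sets, "drug_set")) drug_sets <- list(drug_sets)
  if (inherits(pt_sets, "pt_set")) pt_sets <- list(pt_sets)
  if (inherits(cases, "report_db")) {
    cases <- build_analysis_table(cases, drug_sets, pt_sets)
  }
  rows <- purrr::map(drug_sets, function(ds) {
    purrr::map(pt_sets, function(ps) {
      t <- build_contingency(cases, paste0("exposed_", ds$name),
                             paste0("event_", ps$name))
      dplyr::bind_cols(tibble::tibble(drug = ds$name, event = ps$name),
                       ror_stats(t, level = level))
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out <- dplyr::mutate(out, n_event = .data$a, n_other = .data$c,
                       .after = "event")
  class(out) <- c("ror_screen", class(out))
  out
}

#' Write a screen to CSV with "N.A." for undefined statistics
#'
#' @param screen A `ror_screen` tibble from [screen_signals()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_screen_csv <- function(screen, path) {
  out <- dplyr::select(screen, "drug", "event", "n_event", "n_other",
                       "ror", "ci_low", "ci_high", "significant")
  out <- dplyr::mutate(out, dplyr::across(
    c("ror", "ci_low", "ci_high"),
    ~ ifelse(is.na(.x), "N.A.", formatC(.x, format = "fg", digits = 6))
  ))
  out$significant <- ifelse(is.na(out$significant), "N.A.",
                            ifelse(out$significant, "yes", "no"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname ror_stats
#' @param x A `signal_result`.
#' @param ... Unused.
#' @export
tidy.signal_result <- function(x, ...) {
  tibble::tibble(ror = x$ror, ci_low = x$ci_low, ci_high = x$ci_high,
                 significant = x$significant,
                 a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d)
}

#' Forest plot of a disproportionality screen
#'
#' Point estimates and confidence intervals on a log scale, one row per
#' drug-event pair; undefined (zero-cell) pairs are dropped. Signals are
#' highlighted.
#'
#' @param object A `ror_screen` from [screen_signals()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ror_screen <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$ror))
  df$pair <- paste(df$drug, df$event, sep = " – ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$pair,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey30"),
                                 name = "signal") +
    ggplot2::labs(x = "reporting odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}
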