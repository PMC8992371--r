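# Config-driven end-to-end orchestration:
# load -> dedup -> link -> exclude -> define -> screen -> predictors ->
# onset/outcomes, with a manifest whose stage counts telescope.

#' Build a run configuration
#'
#' @param input Named list/vector of the four CSV paths (`demo`, `drug`,
#'   `reac`, `hist`).
#' @param out_dir Output directory for tables and the manifest.
#' @param drug_sets Named list of [drug_set] objects; default the six
#'   checkpoint inhibitors.
#' @param event_sets Named list of [pt_set] objects; default the
#'   vasculitides set plus the polymyalgia rheumatica singleton.
#' @param cmap A [cancer_map]; default [default_cancer_map()].
#' @param dialect Column-name mapping; default [default_dialect()].
#' @param ci_level Confidence level for all intervals.
#' @param chi_square_correction Yates correction flag (default FALSE).
#' @param predictor_event Name of the event set used for the predictor and
#'   onset/outcome stages.
#' @param period_a,period_b Report-year windows for the period comparison.
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir,
                       drug_sets = icpi_drug_sets(),
                       event_sets = list(
                         vasculitides = vasculitides_pt_set(),
                         polymyalgia_rheumatica = pmr_pt_set()
                       ),
                       cmap = default_cancer_map(),
                       dialect = default_dialect(),
                       ci_level = 0.95,
                       chi_square_correction = FALSE,
                       predictor_event = "polymyalgia_rheumatica",
                       period_a = 2004:2013,
                       period_b = 2014:2019) {
  stopifnot(ci_level > 0, ci_level < 1)
  if (!predictor_event %in% names(event_sets)) {
    rlang::abort("predictor_event must name one of the event_sets")
  }
  structure(list(input = as.list(input), out_dir = out_dir,
                 drug_sets = drug_sets, event_sets = event_sets,
                 cmap = cmap, dialect = dialect, ci_level = ci_level,
                 chi_square_correction = chi_square_correction,
                 predictor_event = predictor_event,
                 period_a = period_a, period_b = period_b),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised blocks: `input` (four paths), `out_dir`, `drug_sets` (name ->
#' list with `generic_names` and optional `role`), `event_sets` (name ->
#' list of `{code, name}` term entries), `cancer_map` (category -> list of
#' PT strings), `ci_level`, `chi_square_correction`, `predictor_event`,
#' `period_a` / `period_b` (two-element `[from, to]` year ranges).
#' Omitted blocks fall back to the built-in definitions.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(input = y$input, out_dir = y$out_dir)
  if (!is.null(y$drug_sets)) {
    args$drug_sets <- purrr::imap(y$drug_sets, function(d, nm) {
      drug_set(nm, unlist(d$generic_names),
               role_filter = d$role %||% "suspected")
    })
  }
  if (!is.null(y$event_sets)) {
    args$event_sets <- purrr::imap(y$event_sets, function(terms, nm) {
      pt_set(nm, tibble::tibble(
        pt_code = purrr::map_int(terms, ~ as.integer(.x$code %||% NA)),
        pt_name = purrr::map_chr(terms, "name")
      ))
    })
  }
  if (!is.null(y$cancer_map)) args$cmap <- cancer_map(y$cancer_map)
  for (fld in c("ci_level", "chi_square_correction", "predictor_event")) {
    if (!is.null(y[[fld]])) args[[fld]] <- y[[fld]]
  }
  for (fld in c("period_a", "period_b")) {
    if (!is.null(y[[fld]])) args[[fld]] <- y[[fld]][1]:y[[fld]][2]
  }
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-drug characteristics: totals, sex/age margins and cancer categories,
# optionally restricted to cases with a given event.
characteristics_table <- function(analysis, cancer, drug_sets,
                                  event_col = NULL) {
  purrr::map_dfr(drug_sets, function(ds) {
    sel <- analysis[analysis[[paste0("exposed_", ds$name)]], , drop = FALSE]
    if (!is.null(event_col)) sel <- sel[sel[[event_col]], , drop = FALSE]
    cats <- cancer[cancer$case_id %in% sel$case_id, ]
    base <- tibble::tibble(
      drug = ds$name,
      characteristic = c("total", "male", "age_70_plus"),
      n = c(nrow(sel), sum(sel$sex == "male"), sum(sel$older_adult))
    )
    if (nrow(cats)) {
      cc <- dplyr::count(cats, .data$category, name = "n")
      base <- dplyr::bind_rows(base, tibble::tibble(
        drug = ds$name, characteristic = paste0("cancer:", cc$category),
        n = cc$n
      ))
    }
    base
  })
}

#' Run the full signal-detection pipeline
#'
#' Executes load, deduplication, case linkage, demographic exclusion, case
#' definitions, the disproportionality screens (whole event set and
#' per-term), the predictor analysis and the onset/outcome summaries, and
#' writes the output tables plus a JSON manifest with telescoping stage
#' counts, input hashes and warnings.
#'
#' Outputs in `config$out_dir`: `characteristics_all.csv`,
#' `characteristics_<event>.csv` for each event set, `screen_<event>.csv`,
#' `screen_terms.csv` (per-PT singletons), `predictors.csv`,
#' `onset_outcomes.csv`, `load_report.txt`, `manifest.json`.
#'
#' @param config A `run_config`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings <- character()

  db <- read_report_db(config$input, dialect = config$dialect)
  stage_counts <- list(input_cases = nrow(db$demo),
                       input_drug_rows = nrow(db$drug),
                       input_reac_rows = nrow(db$reac))
  db <- dedup_reports(db)
  db <- link_reports(db)
  db <- filter_complete_demo(db)
  stage_counts$after_dedup_drug_rows <- nrow(db$drug) # post link/exclusion
  stage_counts$duplicates_removed <- db$log$dedup
  stage_counts$orphans_dropped <- db$log$orphans
  stage_counts$exclusions <- db$log$filter_report
  stage_counts$analyzed_cases <- nrow(db$demo)
  lr <- load_report(db)
  if (!is.null(lr) && nrow(lr)) {
    warnings <- c(warnings, sprintf("%d malformed rows dropped at load", nrow(lr)))
  }

  analysis <- build_analysis_table(db, config$drug_sets, config$event_sets)
  cancer <- classify_cancer(db, config$cmap)

  readr::write_csv(
    characteristics_table(analysis, cancer, config$drug_sets),
    file.path(config$out_dir, "characteristics_all.csv"), progress = FALSE)
  for (nm in names(config$event_sets)) {
    readr::write_csv(
      characteristics_table(analysis, cancer, config$drug_sets,
                            event_col = paste0("event_", nm)),
      file.path(config$out_dir, paste0("characteristics_", nm, ".csv")),
      progress = FALSE)
  }

  for (nm in names(config$event_sets)) {
    sc <- screen_signals(analysis, config$drug_sets,
                         config$event_sets[nm], level = config$ci_level)
    write_screen_csv(sc, file.path(config$out_dir,
                                   paste0("screen_", nm, ".csv")))
  }
  # per-term screen: one singleton PT set per term of the first event set
  main_set <- config$event_sets[[1]]
  singletons <- purrr::map(seq_len(nrow(main_set$terms)), function(i) {
    pt_set(main_set$terms$pt_name[i], main_set$terms[i, c("pt_code", "pt_name")])
  })
  names(singletons) <- main_set$terms$pt_name
  term_analysis <- build_analysis_table(db, config$drug_sets, singletons)
  term_screen <- screen_signals(term_analysis, config$drug_sets, singletons,
                                level = config$ci_level)
  write_screen_csv(term_screen, file.path(config$out_dir, "screen_terms.csv"))

  pev <- config$event_sets[[config$predictor_event]]
  pred <- predictor_analysis(analysis, config$drug_sets, pev,
                             correct = config$chi_square_correction)
  write_predictor_csv(pred, file.path(config$out_dir, "predictors.csv"))
  if (any(is.na(pred$multi_or))) {
    warnings <- c(warnings,
                  "multivariate estimates unavailable for some cohorts (separation or no events)")
  }

  summaries <- purrr::map(config$drug_sets, onset_outcome_summary,
                          db = db, pset = pev)
  write_onset_csv(summaries, file.path(config$out_dir, "onset_outcomes.csv"))

  period <- yearly_event_counts(db, config$event_sets[[1]],
                                config$period_a, config$period_b)

  write_load_report(db, file.path(config$out_dir, "load_report.txt"))

  manifest <- list(
    package = "pvsignal",
    version = as.character(utils::packageVersion("pvsignal")),
    input_md5 = as.list(tools::md5sum(unlist(config$input))),
    stage_counts = stage_counts,
    period_comparison = list(
      period_a = range(config$period_a), period_b = range(config$period_b),
      counts_a = period$counts_a$n, counts_b = period$counts_b$n,
      u = period$test$u, p_value = period$test$p_value
    ),
    warnings = warnings
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
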