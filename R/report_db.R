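# Four-table spontaneous-report schema: DEMO / DRUG / REAC / HIST.
# All operations keep a stage log on the database object so counts
# (input / duplicates / orphans / exclusions) always reconcile.

sex_levels <- c("male", "female", "unknown")
role_levels <- c("suspected", "concomitant", "interaction")
outcome_levels <- c("recovery", "remission", "no_recovery", "death",
                    "after_effects", "unknown")

# Dedup keys: the least destructive reading of "duplicates were removed" —
# exact tuples on the identifying fields.
drug_dedup_key <- c("case_id", "drug_name", "role")
reac_dedup_key <- c("case_id", "pt_name", "onset_day")
hist_dedup_key <- c("case_id", "primary_disease_pt")

#' Construct a spontaneous-report database
#'
#' Bundles the four linked tables of a JADER-style spontaneous reporting
#' system: `demo` (one row per case: sex, age decade, report year), `drug`
#' (drug exposures with an involvement role), `reac` (adverse events coded
#' as MedDRA preferred terms, with onset day and outcome) and `hist`
#' (primary diseases from the medical history).
#'
#' Ages are decade bins (0, 10, ..., 100); dates are integer day indices so
#' onset arithmetic is exact. Sex is `"male"`, `"female"` or `"unknown"`;
#' drug roles are `"suspected"`, `"concomitant"` or `"interaction"`; event
#' outcomes are one of `"recovery"`, `"remission"`, `"no_recovery"`,
#' `"death"`, `"after_effects"`, `"unknown"`.
#'
#' @param demo Data frame with columns `case_id`, `sex`, `age_decade`,
#'   `report_year` and optionally `report_quarter`.
#' @param drug Data frame with columns `case_id`, `drug_name`, `role` and
#'   optionally `first_admin_day`.
#' @param reac Data frame with columns `case_id`, `pt_name` and optionally
#'   `pt_code`, `onset_day`, `outcome`.
#' @param hist Data frame with columns `case_id`, `primary_disease_pt`.
#' @return A `report_db` object: a list of the four tibbles plus a stage
#'   log that accumulates deduplication, linkage and exclusion counts.
#' @examples
#' db <- report_db(
#'   demo = data.frame(case_id = "c1", sex = "female", age_decade = 70,
#'                     report_year = 2018),
#'   drug = data.frame(case_id = "c1", drug_name = "nivolumab",
#'                     role = "suspected", first_admin_day = 100),
#'   reac = data.frame(case_id = "c1", pt_name = "Polymyalgia rheumatica",
#'                     pt_code = 10036099, onset_day = 140,
#'                     outcome = "recovery"),
#'   hist = data.frame(case_id = "c1",
#'                     primary_disease_pt = "Non-small cell lung cancer")
#' )
#' db
#' @export
report_db <- function(demo, drug, reac, hist) {
  demo <- tibble::as_tibble(demo)
  drug <- tibble::as_tibble(drug)
  reac <- tibble::as_tibble(reac)
  hist <- tibble::as_tibble(hist)

  need <- function(tbl, cols, what) {
    miss <- setdiff(cols, names(tbl))
    if (length(miss)) {
      rlang::abort(paste0(what, " table is missing column(s): ",
                          paste(miss, collapse = ", ")))
    }
  }
  need(demo, c("case_id", "sex", "age_decade", "report_year"), "demo")
  need(drug, c("case_id", "drug_name", "role"), "drug")
  need(reac, c("case_id", "pt_name"), "reac")
  need(hist, c("case_id", "primary_disease_pt"), "hist")

  if (!"report_quarter" %in% names(demo)) demo$report_quarter <- NA_integer_
  if (!"first_admin_day" %in% names(drug)) drug$first_admin_day <- NA_integer_
  if (!"pt_code" %in% names(reac)) reac$pt_code <- NA_integer_
  if (!"onset_day" %in% names(reac)) reac$onset_day <- NA_integer_
  if (!"outcome" %in% names(reac)) reac$outcome <- "unknown"

  demo$case_id <- as.character(demo$case_id)
  drug$case_id <- as.character(drug$case_id)
  reac$case_id <- as.character(reac$case_id)
  hist$case_id <- as.character(hist$case_id)
  demo$sex <- as.character(demo$sex)
  demo$sex[is.na(demo$sex)] <- "unknown"
  demo$age_decade <- as.integer(demo$age_decade)
  demo$report_year <- as.integer(demo$report_year)
  demo$report_quarter <- as.integer(demo$report_quarter)
  drug$first_admin_day <- as.integer(drug$first_admin_day)
  reac$pt_code <- as.integer(reac$pt_code)
  reac$onset_day <- as.integer(reac$onset_day)
  reac$outcome <- as.character(reac$outcome)
  reac$outcome[is.na(reac$outcome)] <- "unknown"

  if (any(!nzchar(demo$case_id) | is.na(demo$case_id))) {
    rlang::abort("demo: case_id must be non-empty")
  }
  if (any(!demo$sex %in% sex_levels)) {
    rlang::abort("demo: sex must be one of male/female/unknown")
  }
  bad_age <- !is.na(demo$age_decade) &
    (demo$age_decade %% 10L != 0L | demo$age_decade < 0L | demo$age_decade > 100L)
  if (any(bad_age)) {
    rlang::abort("demo: age_decade must be a multiple of 10 in [0, 100]")
  }
  if (any(!drug$role %in% role_levels)) {
    rlang::abort("drug: role must be one of suspected/concomitant/interaction")
  }
  if (any(!reac$outcome %in% outcome_levels)) {
    rlang::abort("reac: outcome must be one of the six outcome categories")
  }

  structure(
    list(demo = demo, drug = drug, reac = reac, hist = hist,
         log = list(n_input_cases = nrow(demo))),
    class = "report_db"
  )
}

#' @export
print.report_db <- function(x, ...) {
  cat("<report_db>\n")
  cat(sprintf("  cases: %d   drug rows: %d   event rows: %d   history rows: %d\n",
              nrow(x$demo), nrow(x$drug), nrow(x$reac), nrow(x$hist)))
  lg <- x$log
  if (!is.null(lg$dedup)) {
    cat(sprintf("  duplicates removed: drug %d, reac %d, hist %d\n",
                lg$dedup$drug, lg$dedup$reac, lg$dedup$hist))
  }
  if (!is.null(lg$orphans)) {
    cat(sprintf("  orphan rows dropped: drug %d, reac %d, hist %d\n",
                lg$orphans$drug, lg$orphans$reac, lg$orphans$hist))
  }
  if (!is.null(lg$filter_report)) {
    fr <- lg$filter_report
    cat(sprintf("  exclusions: %d missing sex, %d missing age; %d of %d cases retained\n",
                fr$n_excluded_missing_sex, fr$n_excluded_missing_age,
                fr$n_retained, fr$n_input))
  }
  invisible(x)
}

#' Default CSV column-name mapping
#'
#' The on-disk dialect is UTF-8, comma-separated, with a header row. The
#' mapping gives, per table, the file column name for each internal field,
#' so exports with different headers can be adapted without rewriting files.
#'
#' @return Named list of named character vectors (internal name = file name).
#' @export
default_dialect <- function() {
  list(
    demo = c(case_id = "case_id", sex = "sex", age_decade = "age_decade",
             report_year = "report_year", report_quarter = "report_quarter"),
    drug = c(case_id = "case_id", drug_name = "drug_name", role = "role",
             first_admin_day = "first_admin_day"),
    reac = c(case_id = "case_id", pt_name = "pt_name", pt_code = "pt_code",
             onset_day = "onset_day", outcome = "outcome"),
    hist = c(case_id = "case_id", primary_disease_pt = "primary_disease_pt")
  )
}

# Day columns accept either integer day indices or ISO dates, which are
# converted to days since 1970-01-01; anything else becomes missing.
parse_day_index <- function(x) {
  x <- stringr::str_trim(as.character(x))
  out <- suppressWarnings(as.integer(x))
  iso <- is.na(out) & stringr::str_detect(x, "^\\d{4}-\\d{2}-\\d{2}$")
  if (any(iso, na.rm = TRUE)) {
    iso[is.na(iso)] <- FALSE
    out[iso] <- as.integer(as.Date(x[iso]))
  }
  out
}

parse_enum <- function(x, levels, missing_to = NULL) {
  x <- stringr::str_to_lower(stringr::str_trim(as.character(x)))
  x[x == ""] <- NA_character_
  if (!is.null(missing_to)) x[is.na(x)] <- missing_to
  x
}

#' Read a spontaneous-report database from four CSV files
#'
#' Reads the DEMO/DRUG/REAC/HIST tables, parses enums and day indices, and
#' collects row-level problems (unknown role or outcome tokens) into a load
#' report instead of failing. Blank sex cells become `"unknown"`;
#' unparseable optional fields (age decade, day indices, PT codes) become
#' missing. Rows with an invalid value in a required enum field are dropped
#' and listed, with their row numbers, in the load report.
#'
#' @param paths Named character vector or list with elements `demo`, `drug`,
#'   `reac`, `hist` giving the CSV file paths.
#' @param dialect Column-name mapping as returned by [default_dialect()].
#' @return A [report_db] object; `load_report(db)` returns the per-table
#'   tibble of dropped rows.
#' @seealso [write_report_db()], [load_report()]
#' @export
read_report_db <- function(paths, dialect = default_dialect()) {
  paths <- as.list(paths)
  for (tb in c("demo", "drug", "reac", "hist")) {
    if (is.null(paths[[tb]])) rlang::abort(paste0("paths must include '", tb, "'"))
    if (!file.exists(paths[[tb]])) {
      rlang::abort(paste0("file not found: ", paths[[tb]]))
    }
  }
  read_one <- function(path, map) {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    miss <- setdiff(unname(map), names(raw))
    if (length(miss)) {
      rlang::abort(paste0(basename(path), ": header is missing column(s): ",
                          paste(miss, collapse = ", ")))
    }
    out <- raw[, unname(map), drop = FALSE]
    names(out) <- names(map)
    out
  }
  demo <- read_one(paths$demo, dialect$demo)
  drug <- read_one(paths$drug, dialect$drug)
  reac <- read_one(paths$reac, dialect$reac)
  hist <- read_one(paths$hist, dialect$hist)

  problems <- list()
  note_bad <- function(table, rows, field, values) {
    if (!length(rows)) return()
    problems[[length(problems) + 1L]] <<- tibble::tibble(
      table = table, row = rows, field = field, value = values
    )
  }

  demo$sex <- parse_enum(demo$sex, sex_levels, missing_to = "unknown")
  bad <- which(!demo$sex %in% sex_levels)
  note_bad("demo", bad, "sex", demo$sex[bad])
  if (length(bad)) demo <- demo[-bad, ]
  demo$age_decade <- suppressWarnings(as.integer(demo$age_decade))
  demo$age_decade[!is.na(demo$age_decade) &
                    (demo$age_decade %% 10L != 0L |
                       demo$age_decade < 0L | demo$age_decade > 100L)] <- NA_integer_
  demo$report_year <- suppressWarnings(as.integer(demo$report_year))
  demo$report_quarter <- suppressWarnings(as.integer(demo$report_quarter))

  drug$role <- parse_enum(drug$role, role_levels)
  bad <- which(!drug$role %in% role_levels)
  note_bad("drug", bad, "role", drug$role[bad])
  if (length(bad)) drug <- drug[-bad, ]
  drug$first_admin_day <- parse_day_index(drug$first_admin_day)

  reac$outcome <- parse_enum(reac$outcome, outcome_levels, missing_to = "unknown")
  reac$outcome <- stringr::str_replace_all(reac$outcome, "[ -]", "_")
  bad <- which(!reac$outcome %in% outcome_levels)
  note_bad("reac", bad, "outcome", reac$outcome[bad])
  if (length(bad)) reac <- reac[-bad, ]
  reac$pt_code <- suppressWarnings(as.integer(reac$pt_code))
  reac$onset_day <- parse_day_index(reac$onset_day)

  db <- report_db(demo, drug, reac, hist)
  db$log$load_report <- if (length(problems)) {
    dplyr::bind_rows(problems)
  } else {
    tibble::tibble(table = character(), row = integer(),
                   field = character(), value = character())
  }
  db
}

#' Write a spontaneous-report database to four CSV files
#'
#' Inverse of [read_report_db()]: a write followed by a read yields
#' record-identical tables.
#'
#' @param db A [report_db] object.
#' @param dir Output directory (created if needed).
#' @param dialect Column-name mapping as in [read_report_db()].
#' @return Invisibly, the named vector of file paths written.
#' @export
write_report_db <- function(db, dir, dialect = default_dialect()) {
  stopifnot(inherits(db, "report_db"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(demo = file.path(dir, "demo.csv"), drug = file.path(dir, "drug.csv"),
             reac = file.path(dir, "reac.csv"), hist = file.path(dir, "hist.csv"))
  for (tb in names(paths)) {
    out <- db[[tb]][, names(dialect[[tb]]), drop = FALSE]
    names(out) <- unname(dialect[[tb]])
    readr::write_csv(out, paths[[tb]], progress = FALSE)
  }
  invisible(paths)
}

#' Remove duplicate drug and event rows
#'
#' Drops exact duplicates from the DRUG, REAC and HIST tables. Keys:
#' drug rows on (case_id, drug_name, role); event rows on (case_id,
#' pt_name, onset_day); history rows on (case_id, primary_disease_pt).
#' The number removed per table is recorded in the database log
#' (`dedup_counts()`), and the operation is idempotent.
#'
#' @param db A [report_db] object.
#' @return The database with duplicates removed.
#' @export
dedup_reports <- function(db) {
  stopifnot(inherits(db, "report_db"))
  n0 <- c(drug = nrow(db$drug), reac = nrow(db$reac), hist = nrow(db$hist))
  db$drug <- dplyr::distinct(db$drug, dplyr::across(dplyr::all_of(drug_dedup_key)),
                             .keep_all = TRUE)
  db$reac <- dplyr::distinct(db$reac, dplyr::across(dplyr::all_of(reac_dedup_key)),
                             .keep_all = TRUE)
  db$hist <- dplyr::distinct(db$hist, dplyr::across(dplyr::all_of(hist_dedup_key)),
                             .keep_all = TRUE)
  db$log$dedup <- list(drug = n0[["drug"]] - nrow(db$drug),
                       reac = n0[["reac"]] - nrow(db$reac),
                       hist = n0[["hist"]] - nrow(db$hist))
  db
}

#' Link child tables to DEMO cases
#'
#' Keeps only drug/event/history rows whose `case_id` appears in the DEMO
#' table; dropped orphans are counted in the log (`orphan_counts()`), never
#' fatal. Every DEMO row defines one case, with possibly empty child lists.
#'
#' @param db A [report_db] object, ideally after [dedup_reports()].
#' @return The linked database.
#' @export
link_reports <- function(db) {
  stopifnot(inherits(db, "report_db"))
  ids <- unique(db$demo$case_id)
  n0 <- c(drug = nrow(db$drug), reac = nrow(db$reac), hist = nrow(db$hist))
  db$drug <- dplyr::filter(db$drug, .data$case_id %in% ids)
  db$reac <- dplyr::filter(db$reac, .data$case_id %in% ids)
  db$hist <- dplyr::filter(db$hist, .data$case_id %in% ids)
  db$log$orphans <- list(drug = n0[["drug"]] - nrow(db$drug),
                         reac = n0[["reac"]] - nrow(db$reac),
                         hist = n0[["hist"]] - nrow(db$hist))
  db
}

#' Exclude cases with missing sex or age
#'
#' Spontaneous-report analyses routinely drop cases whose demographics are
#' incomplete. A case is excluded when its sex is not male/female or its
#' age decade is missing; child rows of excluded cases are removed too.
#' Counts are recorded as a filter report (`filter_report()`): cases with
#' unknown sex are counted under missing sex, cases with known sex but
#' missing age under missing age, so the counts reconcile exactly with the
#' retained total. Surviving records are never altered, only membership.
#'
#' @param db A linked [report_db].
#' @return The filtered database.
#' @export
filter_complete_demo <- function(db) {
  stopifnot(inherits(db, "report_db"))
  n_input <- nrow(db$demo)
  missing_sex <- !db$demo$sex %in% c("male", "female")
  missing_age <- !missing_sex & is.na(db$demo$age_decade)
  keep <- !missing_sex & !missing_age
  db$demo <- db$demo[keep, ]
  ids <- db$demo$case_id
  db$drug <- dplyr::filter(db$drug, .data$case_id %in% ids)
  db$reac <- dplyr::filter(db$reac, .data$case_id %in% ids)
  db$hist <- dplyr::filter(db$hist, .data$case_id %in% ids)
  db$log$filter_report <- list(
    n_input = n_input,
    n_excluded_missing_sex = sum(missing_sex),
    n_excluded_missing_age = sum(missing_age),
    n_retained = nrow(db$demo)
  )
  db
}

#' @rdname filter_complete_demo
#' @export
filter_report <- function(db) {
  stopifnot(inherits(db, "report_db"))
  fr <- db$log$filter_report
  if (is.null(fr)) return(NULL)
  tibble::as_tibble(fr)
}

#' @rdname dedup_reports
#' @export
dedup_counts <- function(db) {
  stopifnot(inherits(db, "report_db"))
  if (is.null(db$log$dedup)) return(NULL)
  tibble::as_tibble(db$log$dedup)
}

#' @rdname link_reports
#' @export
orphan_counts <- function(db) {
  stopifnot(inherits(db, "report_db"))
  if (is.null(db$log$orphans)) return(NULL)
  tibble::as_tibble(db$log$orphans)
}

#' @rdname read_report_db
#' @param db A [report_db] object returned by [read_report_db()].
#' @export
load_report <- function(db) {
  stopifnot(inherits(db, "report_db"))
  db$log$load_report
}

#' Is a case an older adult?
#'
#' Older adults are defined as the 70, 80, 90 and 100 age decades (i.e.
#' age 70 or above under decade coding).
#'
#' @param age_decade Integer vector of age decades; must contain no missing
#'   values — run [filter_complete_demo()] first.
#' @return Logical vector.
#' @examples
#' older_adult(c(60, 70, 100))
#' @export
older_adult <- function(age_decade) {
  if (anyNA(age_decade)) {
    rlang::abort("age_decade contains missing values; apply exclusions first")
  }
  age_decade >= 70L
}

#' One row per case with demographics
#'
#' @param db A [report_db].
#' @return Tibble with `case_id`, `sex`, `age_decade`, `older_adult`
#'   (NA when age is missing), `report_year`.
#' @export
case_table <- function(db) {
  stopifnot(inherits(db, "report_db"))
  dplyr::mutate(
    dplyr::select(db$demo, "case_id", "sex", "age_decade", "report_year"),
    older_adult = dplyr::if_else(is.na(.data$age_decade), NA,
                                 .data$age_decade >= 70L)
  )
}

#' Write a plain-text load report
#'
#' Summarises row-level load problems, duplicate removals, orphan drops and
#' demographic exclusions for audit.
#'
#' @param db A [report_db] after the filtering stages.
#' @param path Output text file.
#' @return Invisibly, `path`.
#' @export
write_load_report <- function(db, path) {
  stopifnot(inherits(db, "report_db"))
  lines <- c(sprintf("input cases: %d", db$log$n_input_cases))
  lr <- db$log$load_report
  if (!is.null(lr)) {
    lines <- c(lines, sprintf("rows dropped at load: %d", nrow(lr)))
    if (nrow(lr)) {
      lines <- c(lines, sprintf("  %s row %d: bad %s '%s'",
                                lr$table, lr$row, lr$field, lr$value))
    }
  }
  if (!is.null(db$log$dedup)) {
    lines <- c(lines, sprintf(
      "duplicates removed (exact-tuple key): drug %d, reac %d, hist %d",
      db$log$dedup$drug, db$log$dedup$reac, db$log$dedup$hist))
  }
  if (!is.null(db$log$orphans)) {
    lines <- c(lines, sprintf("orphan rows dropped: drug %d, reac %d, hist %d",
                              db$log$orphans$drug, db$log$orphans$reac,
                              db$log$orphans$hist))
  }
  fr <- db$log$filter_report
  if (!is.null(fr)) {
    lines <- c(lines, sprintf(
      "exclusions: %d missing sex, %d missing age; retained %d of %d",
      fr$n_excluded_missing_sex, fr$n_excluded_missing_age,
      fr$n_retained, fr$n_input))
  }
  writeLines(lines, path)
  invisible(path)
}
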