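# Named PT sets (events of interest), drug sets (exposures of interest,
# suspected role only by default) and cancer classification from history.

#' Normalize a preferred-term or drug-name string
#'
#' Case-folds and collapses internal whitespace so matching is robust to
#' formatting differences; drug names additionally have configured salt
#' suffixes stripped (e.g. "hydrochloride").
#'
#' @param x Character vector.
#' @param salt_suffixes Character vector of trailing words to strip (drug
#'   names only).
#' @return Normalized character vector.
#' @export
normalize_term <- function(x) {
  stringr::str_squish(stringr::str_to_lower(as.character(x)))
}

#' @rdname normalize_term
#' @export
normalize_drug_name <- function(x, salt_suffixes = default_salt_suffixes()) {
  x <- normalize_term(x)
  if (length(salt_suffixes)) {
    pat <- paste0("\\s+(", paste(salt_suffixes, collapse = "|"), ")$")
    x <- stringr::str_remove(x, pat)
  }
  x
}

#' @rdname normalize_term
#' @export
default_salt_suffixes <- function() {
  c("hydrochloride", "sodium", "mesylate", "maleate", "sulfate", "tartrate",
    "besylate", "acetate", "citrate", "phosphate", "hydrate", "dihydrate")
}

#' Define a preferred-term set
#'
#' A named set of MedDRA preferred terms (code + name pairs) describing the
#' events of interest; matching is by exact normalized name, or by numeric
#' code when both sides carry one.
#'
#' @param name Set name.
#' @param terms Data frame with columns `pt_code` (integer, may be NA) and
#'   `pt_name`.
#' @return A `pt_set` object.
#' @export
pt_set <- function(name, terms) {
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("pt_code", "pt_name") %in% names(terms)), nrow(terms) > 0)
  terms$pt_code <- as.integer(terms$pt_code)
  terms$pt_name <- as.character(terms$pt_name)
  terms$pt_norm <- normalize_term(terms$pt_name)
  if (anyDuplicated(terms$pt_norm)) {
    rlang::abort("pt_set: pt_names must be unique within a set")
  }
  structure(list(name = name, terms = terms), class = "pt_set")
}

#' @export
print.pt_set <- function(x, ...) {
  cat(sprintf("<pt_set '%s'> %d preferred terms\n", x$name, nrow(x$terms)))
  invisible(x)
}

#' Define a drug set
#'
#' A named set of generic drug names with an involvement-role filter: only
#' records reported in that role count as exposure. The default role is
#' `"suspected"` — the role that attributes causality of the event to the
#' drug, as opposed to concomitant or interacting medicines.
#'
#' @param name Set name.
#' @param generic_names Character vector of generic names.
#' @param role_filter One of `"suspected"`, `"concomitant"`, `"interaction"`.
#' @return A `drug_set` object.
#' @export
drug_set <- function(name, generic_names, role_filter = "suspected") {
  stopifnot(length(generic_names) > 0)
  role_filter <- match.arg(role_filter, role_levels)
  structure(list(name = name,
                 generic_names = unique(normalize_drug_name(generic_names)),
                 role_filter = role_filter),
            class = "drug_set")
}

#' @export
print.drug_set <- function(x, ...) {
  cat(sprintf("<drug_set '%s'> role=%s: %s\n", x$name, x$role_filter,
              paste(x$generic_names, collapse = ", ")))
  invisible(x)
}

# 51 preferred terms of vasculitides per the 2012 revised International
# Chapel Hill Consensus Conference nomenclature, as coded in MedDRA.
vasculitides_terms <- function() {
  tibble::tribble(
    ~pt_code, ~pt_name,
    10050894L, "Anti-neutrophil cytoplasmic antibody positive vasculitis",
    10002921L, "Aortitis",
    10003230L, "Arteritis",
    10003232L, "Arteritis coronary",
    10004213L, "Behcet's syndrome",
    10068406L, "Capillaritis",
    10081778L, "Central nervous system vasculitis",
    10008087L, "Cerebral arteritis",
    10072726L, "Chronic pigmented purpura",
    10056667L, "Cogan's syndrome",
    10011686L, "Cutaneous vasculitis",
    10012978L, "Diffuse vasculitis",
    10078117L, "Eosinophilic granulomatosis with polyangiitis",
    10015213L, "Erythema induratum",
    10072579L, "Granulomatosis with polyangiitis",
    10071252L, "Haemorrhagic vasculitis",
    10019617L, "Henoch-Schonlein purpura",
    10069440L, "Henoch-Schonlein purpura nephritis",
    10020764L, "Hypersensitivity vasculitis",
    10023320L, "Kawasaki's disease",
    10069698L, "Langerhans' cell histiocytosis",
    10058143L, "Lupus vasculitis",
    10078132L, "MAGIC syndrome",
    10063344L, "Microscopic polyangiitis",
    10066926L, "Ocular vasculitis",
    10036024L, "Polyarteritis nodosa",
    10036099L, "Polymyalgia rheumatica",
    10037457L, "Pulmonary vasculitis",
    10038373L, "Renal arteritis",
    10038546L, "Renal vasculitis",
    10038905L, "Retinal vasculitis",
    10048628L, "Rheumatoid vasculitis",
    10043097L, "Takayasu's arteritis",
    10043207L, "Temporal arteritis",
    10043540L, "Thromboangiitis obliterans",
    10048820L, "Urticarial vasculitis",
    10047097L, "Vascular purpura",
    10047111L, "Vasculitic rash",
    10047115L, "Vasculitis",
    10048319L, "Vasculitis gastrointestinal",
    10047124L, "Vasculitis necrotising",
    10011474L, "Cryoglobulinemic vasculitis",
    10018250L, "Giant cell arteritis",
    10014957L, "Eosinophilic granulomatous vasculitis",
    10028890L, "Necrotizing granulomatous vasculitis",
    10001714L, "Allergic granulomatosis angiitis",
    10047888L, "Wegener's granulomatosis",
    10072580L, "Granulomatous polyangiitis",
    10082959L, "IgA vasculitis",
    10081981L, "Anti-glomerular basement membrane disease",
    10077509L, "Hypocomplementemic urticarial vasculitis syndrome"
  )
}

#' Built-in case definitions
#'
#' `vasculitides_pt_set()` is the 51-term vasculitides definition (2012
#' revised Chapel Hill consensus nomenclature, MedDRA PT codes + names);
#' `pmr_pt_set()` is the polymyalgia rheumatica singleton (PT 10036099),
#' a subset of the vasculitides set; `icpi_drug_sets()` returns one
#' suspected-role drug set per immune checkpoint inhibitor (nivolumab,
#' pembrolizumab, ipilimumab, atezolizumab, durvalumab, avelumab).
#'
#' @return A [pt_set], or a named list of [drug_set] objects.
#' @examples
#' nrow(vasculitides_pt_set()$terms)
#' pmr_pt_set()$terms$pt_code
#' names(icpi_drug_sets())
#' @export
vasculitides_pt_set <- function() {
  pt_set("vasculitides", vasculitides_terms())
}

#' @rdname vasculitides_pt_set
#' @export
pmr_pt_set <- function() {
  pt_set("polymyalgia_rheumatica",
         tibble::tibble(pt_code = 10036099L, pt_name = "Polymyalgia rheumatica"))
}

#' @rdname vasculitides_pt_set
#' @export
icpi_drug_sets <- function() {
  nm <- c("nivolumab", "pembrolizumab", "ipilimumab",
          "atezolizumab", "durvalumab", "avelumab")
  stats::setNames(lapply(nm, function(d) drug_set(d, d)), nm)
}

#' Cancer-category map
#'
#' Maps category names to sets of primary-disease PT strings; categories may
#' overlap, and any non-empty history that matches no category falls back to
#' `"others/uncertain"`. The default map pairs each of the 11 standard
#' oncology categories with its identically-named PT plus common synonyms;
#' it is intentionally approximate and fully overridable.
#'
#' @param categories Named list: category name -> character vector of PT
#'   strings.
#' @return A `cancer_map` object.
#' @export
cancer_map <- function(categories) {
  stopifnot(is.list(categories), length(categories) > 0,
            !is.null(names(categories)))
  categories <- lapply(categories, normalize_term)
  structure(list(categories = categories), class = "cancer_map")
}

#' @rdname cancer_map
#' @export
default_cancer_map <- function() {
  cancer_map(list(
    "non-small cell lung cancer" = c("non-small cell lung cancer",
                                     "lung adenocarcinoma",
                                     "lung squamous cell carcinoma"),
    "head and neck cancer" = c("head and neck cancer",
                               "squamous cell carcinoma of head and neck"),
    "urothelial cancer" = c("urothelial cancer", "bladder cancer",
                            "transitional cell carcinoma"),
    "renal cell carcinoma" = c("renal cell carcinoma", "renal cancer"),
    "melanoma" = c("melanoma", "malignant melanoma"),
    "gastric cancer" = c("gastric cancer", "stomach cancer"),
    "hodgkin lymphoma" = c("hodgkin lymphoma", "hodgkin's disease"),
    "mesothelioma" = c("mesothelioma", "malignant mesothelioma"),
    "myeloma" = c("myeloma", "multiple myeloma", "plasma cell myeloma"),
    "merkel cell carcinoma" = c("merkel cell carcinoma")
  ))
}

#' Flag exposure to a drug set
#'
#' A case is exposed when at least one of its drug records matches a set
#' member under the set's role filter (by default, the drug must be
#' reported as a suspected medicine — a concomitant record does not count).
#'
#' @param db A [report_db].
#' @param dset A [drug_set].
#' @return Tibble `case_id`, `exposed` (one row per case in the database).
#' @export
flag_exposure <- function(db, dset) {
  stopifnot(inherits(db, "report_db"), inherits(dset, "drug_set"))
  hits <- db$drug[normalize_drug_name(db$drug$drug_name) %in% dset$generic_names &
                    db$drug$role == dset$role_filter, "case_id", drop = FALSE]
  tibble::tibble(case_id = db$demo$case_id,
                 exposed = db$demo$case_id %in% hits$case_id)
}

#' Flag and extract events matching a PT set
#'
#' `flag_events()` gives the case-level indicator (any matching event);
#' `event_records()` returns every matching event row, for event-level
#' tallies where a patient with several distinct vasculitides contributes
#' each event.
#'
#' @param db A [report_db].
#' @param pset A [pt_set].
#' @return `flag_events()`: tibble `case_id`, `has_event`;
#'   `event_records()`: the matching REAC rows.
#' @export
flag_events <- function(db, pset) {
  ev <- event_records(db, pset)
  tibble::tibble(case_id = db$demo$case_id,
                 has_event = db$demo$case_id %in% ev$case_id)
}

#' @rdname flag_events
#' @export
event_records <- function(db, pset) {
  stopifnot(inherits(db, "report_db"), inherits(pset, "pt_set"))
  by_name <- normalize_term(db$reac$pt_name) %in% pset$terms$pt_norm
  codes <- pset$terms$pt_code[!is.na(pset$terms$pt_code)]
  by_code <- !is.na(db$reac$pt_code) & db$reac$pt_code %in% codes
  db$reac[by_name | by_code, , drop = FALSE]
}

#' Classify a case's cancer categories from medical history
#'
#' Returns every matching category (overlaps allowed). A case whose history
#' is non-empty but matches nothing is classified `"others/uncertain"`; a
#' case with no history rows gets no category. Deterministic and
#' independent of history-record order.
#'
#' @param db A [report_db].
#' @param map A [cancer_map].
#' @return Tibble `case_id`, `category` (zero or more rows per case).
#' @export
classify_cancer <- function(db, map = default_cancer_map()) {
  stopifnot(inherits(db, "report_db"), inherits(map, "cancer_map"))
  if (nrow(db$hist) == 0) {
    return(tibble::tibble(case_id = character(), category = character()))
  }
  hist <- dplyr::distinct(db$hist, .data$case_id,
                          pt_norm = normalize_term(.data$primary_disease_pt))
  per_cat <- purrr::imap(map$categories, function(terms, cat) {
    hit <- hist[hist$pt_norm %in% terms, "case_id", drop = FALSE]
    if (nrow(hit)) tibble::tibble(case_id = unique(hit$case_id), category = cat)
  })
  matched <- dplyr::bind_rows(per_cat)
  unmatched <- setdiff(unique(hist$case_id), matched$case_id)
  out <- dplyr::bind_rows(
    matched,
    tibble::tibble(case_id = unmatched,
                   category = rep("others/uncertain", length(unmatched)))
  )
  dplyr::arrange(out, .data$case_id, .data$category)
}

#' Case-level analysis table
#'
#' The tidy core of the pipeline: one row per case with demographics plus a
#' logical exposure column per drug set (`exposed_<name>`) and a logical
#' event column per PT set (`event_<name>`). All 2x2 contingency tables and
#' predictor datasets are built from this table by case-level counting.
#'
#' @param db A linked, filtered [report_db].
#' @param drug_sets List of [drug_set] objects (or a single one).
#' @param pt_sets List of [pt_set] objects (or a single one).
#' @return Tibble, one row per case.
#' @export
build_analysis_table <- function(db, drug_sets, pt_sets) {
  stopifnot(inherits(db, "report_db"))
  if (inherits(drug_sets, "drug_set")) drug_sets <- list(drug_sets)
  if (inherits(pt_sets, "pt_set")) pt_sets <- list(pt_sets)
  out <- case_table(db)
  for (ds in drug_sets) {
    out[[paste0("exposed_", ds$name)]] <- flag_exposure(db, ds)$exposed
  }
  for (ps in pt_sets) {
    out[[paste0("event_", ps$name)]] <- flag_events(db, ps)$has_event
  }
  out
}
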