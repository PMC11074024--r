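#' Drug-role vocabulary
#'
#' The eight curator-assigned categories describing the antihistamine's
#' function in a trial. `not_included` covers false positives, e.g. a
#' search term matching a person's name.
#'
#' @return Character vector of the 8 canonical role labels.
#' @export
drug_roles <- function() {
  c("combination", "comparison", "control", "main", "minimal",
    "not_included", "premedication", "rescue_medication")
}

#' Roles excluded from the landscape tables
#'
#' Every table except the per-drug role overview drops trials whose
#' role is minimal, not included, or rescue medication.
#'
#' @return Character vector of excluded role labels.
#' @export
excluded_roles <- function() c("minimal", "not_included", "rescue_medication")

publication_statuses <- function() c("paper", "registry_results", "none")

#' Normalize a drug-role label
#'
#' Trims, lowercases and converts separators so that `"Main "`,
#' `"Not included"` and `"rescue-medication"` all land on the canonical
#' enum values.
#'
#' @param x Character vector of role labels.
#' @return Canonical labels; error if any value is outside the enum.
#' @export
normalize_drug_role <- function(x) {
  v <- gsub("[ -]+", "_", tolower(trimws(x)))
  bad <- setdiff(unique(v), drug_roles())
  if (length(bad) > 0)
    ts_validation_error(sprintf("unknown drug_role value(s): %s",
                                paste(bad, collapse = ", ")))
  v
}

empty_annotation_table <- function() {
  data.table(
    nct_id = character(0), primary_drug = character(0),
    additional_drugs = list(), legacy_search_term = character(0),
    use_case = character(0), drug_role = character(0),
    repurposing = logical(0), publication_status = character(0),
    publication_ref = character(0), notes = character(0))
}

#' Construct a curation annotation
#'
#' The manual payload attached to one trial: which drug of the
#' configured list it is about, the curator-assigned use case (the
#' indication the drug was used for, not necessarily the trial's
#' primary condition), the drug role, whether the trial points toward
#' repurposing, and whether results were published (as a paper, as
#' registry-submitted results, or not at all).
#'
#' Invariants enforced at [set_annotation()] time: the role is one of
#' the eight categories; `publication_status == "paper"` requires a
#' `publication_ref`; the primary drug must not recur among
#' `additional_drugs`; and unless the role is `not_included`, the
#' primary drug must be one of the store's configured drug terms.
#'
#' @param nct_id Trial identifier.
#' @param primary_drug First-listed drug name (grouping key of every
#'   per-drug table); may be blank only for role `not_included`.
#' @param use_case Free-text indication label.
#' @param drug_role One of [drug_roles()] (normalized on input).
#' @param repurposing Logical repurposing flag.
#' @param additional_drugs Further drug names mentioned by the trial.
#' @param legacy_search_term Optional term from earlier per-drug
#'   downloads.
#' @param publication_status `"paper"`, `"registry_results"` or
#'   `"none"`.
#' @param publication_ref Citation or URL; required when status is
#'   `"paper"`.
#' @param notes Optional free text.
#' @return An `annotation` object.
#' @export
annotation <- function(nct_id, primary_drug, use_case, drug_role,
                       repurposing, additional_drugs = character(0),
                       legacy_search_term = NA_character_,
                       publication_status = "none",
                       publication_ref = NA_character_,
                       notes = NA_character_) {
  structure(list(
    nct_id = nct_id, primary_drug = primary_drug,
    additional_drugs = as.character(additional_drugs),
    legacy_search_term = legacy_search_term, use_case = use_case,
    drug_role = normalize_drug_role(drug_role),
    repurposing = isTRUE(repurposing),
    publication_status = publication_status,
    publication_ref = publication_ref, notes = notes),
    class = "annotation")
}

validate_annotation <- function(ann, drug_terms) {
  if (!ann$drug_role %in% drug_roles())
    ts_validation_error(sprintf("drug_role: unknown value \"%s\"", ann$drug_role))
  if (!ann$publication_status %in% publication_statuses())
    ts_validation_error(sprintf("publication_status: unknown value \"%s\"",
                                ann$publication_status))
  if (ann$publication_status == "paper" && is_blank(ann$publication_ref))
    ts_validation_error(
      "publication_ref: required when publication_status is \"paper\"")
  if (!is_blank(ann$primary_drug) &&
      tolower(ann$primary_drug) %in% tolower(ann$additional_drugs))
    ts_validation_error("additional_drugs: must not repeat primary_drug")
  if (ann$drug_role != "not_included") {
    if (is_blank(ann$primary_drug) ||
        !tolower(ann$primary_drug) %in% tolower(drug_terms))
      ts_validation_error(sprintf(
        "primary_drug: \"%s\" is not among the configured drug terms",
        ann$primary_drug))
  }
  invisible(ann)
}

#' Create a trial store
#'
#' The single source of truth downstream of processing: typed study
#' records, the condition and country term dictionaries, and the
#' curation annotations all live here; every analytics routine reads
#' only from the store. Implemented as an environment of data.tables
#' with a single-file JSON backup ([dump_backup()] / [restore_backup()])
#' standing in for the embedded relational database of the original
#' workflow.
#'
#' @param drug_terms Configured drug list annotations are validated
#'   against.
#' @return A `trial_store` object.
#' @export
trial_store <- function(drug_terms = default_drug_terms()) {
  store <- new.env(parent = emptyenv())
  store$drug_terms <- as.character(drug_terms)
  store$records <- empty_record_table()
  store$conditions <- structure(list(kind = "condition", entries = integer(0)),
                                class = "term_dictionary")
  store$countries <- structure(list(kind = "country", entries = integer(0)),
                               class = "term_dictionary")
  store$annotations <- empty_annotation_table()
  class(store) <- "trial_store"
  store
}

#' @export
print.trial_store <- function(x, ...) {
  cat(sprintf("<trial_store> %d records, %d annotations, %d conditions, %d countries\n",
              nrow(x$records), nrow(x$annotations),
              length(x$conditions$entries), length(x$countries$entries)))
  invisible(x)
}

#' Upsert processed records into a store
#'
#' Idempotent upsert keyed on `nct_id`: an existing row is replaced,
#' a new one appended. When given the full result of
#' [process_snapshot()], the term dictionaries are installed too.
#'
#' @param store A [trial_store()].
#' @param records A study-record data.table, or a `process_snapshot()`
#'   result list.
#' @return The store, invisibly (modified in place).
#' @export
upsert_records <- function(store, records) {
  stopifnot(inherits(store, "trial_store"))
  if (is.list(records) && !is.data.frame(records) && !is.null(records$records)) {
    store$conditions <- records$conditions
    store$countries <- records$countries
    records <- records$records
  }
  existing <- store$records
  keep <- existing[!nct_id %in% records$nct_id]
  store$records <- rbind(keep, records)
  invisible(store)
}

#' Fetch one study record from the store
#'
#' @param store A [trial_store()].
#' @param nct_id Trial identifier.
#' @return One-row study-record data.table.
#' @export
get_record <- function(store, nct_id) {
  id <- nct_id
  row <- store$records[store$records$nct_id == id]
  if (nrow(row) == 0)
    ts_not_found_error(sprintf("no record with nct_id \"%s\" in store", id))
  row
}

#' Attach or replace a curation annotation
#'
#' Validates the annotation's invariants against the store's configured
#' drug terms, requires the trial to exist, then replaces any prior
#' annotation for the same `nct_id`.
#'
#' @param store A [trial_store()].
#' @param ann An [annotation()].
#' @return The store, invisibly (modified in place).
#' @export
set_annotation <- function(store, ann) {
  stopifnot(inherits(store, "trial_store"), inherits(ann, "annotation"))
  validate_annotation(ann, store$drug_terms)
  if (!ann$nct_id %in% store$records$nct_id)
    ts_not_found_error(sprintf("no record with nct_id \"%s\" in store", ann$nct_id))
  row <- data.table(
    nct_id = ann$nct_id, primary_drug = ann$primary_drug,
    additional_drugs = list(ann$additional_drugs),
    legacy_search_term = ann$legacy_search_term, use_case = ann$use_case,
    drug_role = ann$drug_role, repurposing = ann$repurposing,
    publication_status = ann$publication_status,
    publication_ref = ann$publication_ref, notes = ann$notes)
  store$annotations <- rbind(store$annotations[nct_id != ann$nct_id], row)
  invisible(store)
}

annotation_csv_header <- function() {
  c("nct_id", "primary_drug", "additional_drugs", "legacy_search_term",
    "use_case", "drug_role", "repurposing", "publication_status",
    "publication_ref", "notes")
}

#' Annotation CSV round-trip
#'
#' Exports the store's annotation set as UTF-8 CSV with the fixed
#' header `nct_id,primary_drug,additional_drugs,legacy_search_term,
#' use_case,drug_role,repurposing,publication_status,publication_ref,
#' notes` (`additional_drugs` semicolon-separated, booleans
#' `true`/`false`), and imports such files back. Import normalizes role
#' labels, validates every row, and commits all rows or none: a single
#' invalid row aborts the import with its row number.
#'
#' @param store A [trial_store()].
#' @param path CSV path.
#' @return The store (import) or `path` (export), invisibly.
#' @export
export_annotations_csv <- function(store, path) {
  ann <- copy(store$annotations)
  setorder(ann, nct_id)
  out <- data.table(
    nct_id = ann$nct_id, primary_drug = ann$primary_drug,
    additional_drugs = vapply(ann$additional_drugs, paste, character(1),
                              collapse = ";"),
    legacy_search_term = ann$legacy_search_term, use_case = ann$use_case,
    drug_role = ann$drug_role,
    repurposing = ifelse(ann$repurposing, "true", "false"),
    publication_status = ann$publication_status,
    publication_ref = ann$publication_ref, notes = ann$notes)
  fwrite(out, path, na = "", quote = TRUE)
  invisible(path)
}

#' @rdname export_annotations_csv
#' @export
import_annotations_csv <- function(store, path) {
  stopifnot(inherits(store, "trial_store"))
  raw <- fread(path, colClasses = "character", na.strings = NULL,
               encoding = "UTF-8")
  missing_cols <- setdiff(annotation_csv_header(), names(raw))
  if (length(missing_cols) > 0)
    ts_format_error(sprintf("annotation CSV is missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  anns <- list()
  errors <- character(0)
  for (i in seq_len(nrow(raw))) {
    r <- raw[i]
    res <- tryCatch({
      blank_na <- function(x) if (!nzchar(x)) NA_character_ else x
      extra <- strsplit(r$additional_drugs, ";", fixed = TRUE)[[1]]
      extra <- extra[nzchar(trimws(extra))]
      rep_flag <- tolower(trimws(r$repurposing))
      if (!rep_flag %in% c("true", "false"))
        ts_validation_error(sprintf("repurposing: \"%s\" is not true/false",
                                    r$repurposing))
      ann <- annotation(
        nct_id = trimws(r$nct_id), primary_drug = trimws(r$primary_drug),
        additional_drugs = trimws(extra),
        legacy_search_term = blank_na(r$legacy_search_term),
        use_case = r$use_case, drug_role = r$drug_role,
        repurposing = rep_flag == "true",
        publication_status = tolower(trimws(r$publication_status)),
        publication_ref = blank_na(r$publication_ref),
        notes = blank_na(r$notes))
      validate_annotation(ann, store$drug_terms)
      if (!ann$nct_id %in% store$records$nct_id)
        ts_not_found_error(sprintf("no record with nct_id \"%s\" in store",
                                   ann$nct_id))
      ann
    }, trialscape_error = function(e) e)
    if (inherits(res, "condition")) {
      errors <- c(errors, sprintf("row %d: %s", i, conditionMessage(res)))
    } else {
      anns[[length(anns) + 1L]] <- res
    }
  }
  if (length(errors) > 0)
    ts_validation_error(paste0(
      "annotation import aborted, no rows committed:\n  ",
      paste(errors, collapse = "\n  ")))
  for (ann in anns) set_annotation(store, ann)
  invisible(store)
}

dict_to_json <- function(dict) {
  list(kind = dict$kind, terms = as.list(names(dict$entries)),
       ids = as.list(unname(dict$entries)))
}

dict_from_json <- function(x) {
  structure(list(kind = x$kind,
                 entries = setNames(as.integer(unlist(x$ids)),
                                    as.character(unlist(x$terms)))),
            class = "term_dictionary")
}

table_to_rows <- function(dt) {
  lapply(seq_len(nrow(dt)), function(i) {
    row <- as.list(dt[i])
    lapply(row, function(v) if (is.list(v)) as.list(v[[1]]) else v)
  })
}

rows_to_table <- function(rows, template) {
  if (length(rows) == 0) return(copy(template))
  int_list_cols <- c("condition_ids", "country_ids")
  rbindlist(lapply(rows, function(r) {
    out <- lapply(names(template), function(col) {
      v <- r[[col]]
      if (is.list(template[[col]])) {
        u <- unlist(v)
        u <- if (col %in% int_list_cols) as.integer(u %||% integer(0))
             else as.character(u %||% character(0))
        return(list(u))
      }
      if (is.null(v)) return(template[[col]][NA_integer_])
      cast <- switch(class(template[[col]])[1],
                     numeric = as.numeric, integer = as.integer,
                     logical = as.logical, as.character)
      cast(v)
    })
    setDT(setNames(out, names(template)))
  }))
}

#' Backup and restore the whole store
#'
#' `dump_backup()` writes everything the store contains — configured
#' drug terms, records, both term dictionaries, annotations — to one
#' self-describing JSON file including the column schema, so the store
#' can be recreated from the file alone. `restore_backup()` rebuilds a
#' store from such a file; a corrupt file raises a format error and
#' produces no partial store.
#'
#' @param store A [trial_store()].
#' @param path Backup file path.
#' @return `dump_backup`: `path` invisibly; `restore_backup`: a new
#'   `trial_store`.
#' @export
dump_backup <- function(store, path) {
  stopifnot(inherits(store, "trial_store"))
  payload <- list(
    format = "trialscape-backup", version = 1L,
    schema = list(records = names(empty_record_table()),
                  annotations = annotation_csv_header()),
    drug_terms = as.list(store$drug_terms),
    records = table_to_rows(store$records),
    conditions = dict_to_json(store$conditions),
    countries = dict_to_json(store$countries),
    annotations = table_to_rows(store$annotations))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA)
  invisible(path)
}

#' @rdname dump_backup
#' @export
restore_backup <- function(path) {
  if (!file.exists(path))
    ts_not_found_error(sprintf("backup file not found: %s", path))
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                      error = function(e) ts_format_error(sprintf(
                        "cannot parse backup file %s: %s", path,
                        conditionMessage(e))))
  if (!identical(payload$format, "trialscape-backup"))
    ts_format_error("not a trialscape backup file (missing format marker)")
  store <- trial_store(drug_terms = unlist(payload$drug_terms) %||% character(0))
  store$records <- rows_to_table(payload$records, empty_record_table())
  store$conditions <- dict_from_json(payload$conditions)
  store$countries <- dict_from_json(payload$countries)
  store$annotations <- rows_to_table(payload$annotations,
                                     empty_annotation_table())
  store
}

raw_field_by_id <- function(snapshot, field) {
  ids <- snapshot_nct_ids(snapshot)
  vals <- vapply(snapshot$records, function(r) {
    v <- r$values[[field]]
    if (length(v) == 0) NA_character_ else paste(v, collapse = "|")
  }, character(1))
  keep <- !is.na(ids) & !duplicated(ids)
  setNames(vals[keep], ids[keep])
}

#' Diff two snapshots for new, updated and removed trials
#'
#' Compares two snapshots of the same query: `new_ids` appear only in
#' the newer snapshot, `removed_ids` only in the older one, and
#' `updated_ids` are present in both with a differing raw
#' `"LastUpdatePostDate"` string (raw on purpose — parsing could mask a
#' dialect change). Swapping the arguments swaps `new_ids` and
#' `removed_ids` and preserves `updated_ids`.
#'
#' @param old,new `ctg_snapshot` objects.
#' @return An `update_report`: list of `new_ids`, `updated_ids`,
#'   `removed_ids` (disjoint, sorted).
#' @export
detect_updates <- function(old, new) {
  stopifnot(inherits(old, "ctg_snapshot"), inherits(new, "ctg_snapshot"))
  old_dates <- raw_field_by_id(old, "LastUpdatePostDate")
  new_dates <- raw_field_by_id(new, "LastUpdatePostDate")
  both <- intersect(names(old_dates), names(new_dates))
  differs <- both[!mapply(identical, old_dates[both], new_dates[both])]
  structure(list(
    new_ids = sort(setdiff(names(new_dates), names(old_dates))),
    updated_ids = sort(differs),
    removed_ids = sort(setdiff(names(old_dates), names(new_dates)))),
    class = "update_report")
}

#' @export
print.update_report <- function(x, ...) {
  cat(sprintf("<update_report> %d new, %d updated, %d removed\n",
              length(x$new_ids), length(x$updated_ids), length(x$removed_ids)))
  invisible(x)
}
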