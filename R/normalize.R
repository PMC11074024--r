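#' Flatten a singleton list field
#'
#' The API wraps scalar fields (like `NCTId`) in one-element arrays;
#' this collapses them. An empty list means the value is absent
#' (`NA`); two or more elements in a declared-singleton field is a
#' shape error naming the field.
#'
#' @param values Character vector (the field's list of strings).
#' @param field Field name, used in the error message.
#' @return Single string or `NA_character_`.
#' @export
flatten_singleton <- function(values, field = "field") {
  if (length(values) == 0) return(NA_character_)
  if (length(values) > 1)
    ts_shape_error(sprintf(
      "field \"%s\" expected at most one value, got %d", field, length(values)))
  as.character(values[[1]])
}

#' Normalize an eligibility age to decimal years
#'
#' The registry reports ages as strings like `"11 Years"` or
#' `"6 Months"`. The string is lowercased, all non-digit characters are
#' deleted to extract the number, and the unit decides the divisor:
#' years as-is, months / 12, weeks / 52, days / 365 (weeks and days
#' occur in real snapshots even though rarer).
#'
#' @param values Character vector of length 0 or 1.
#' @return Age in decimal years, or `NA_real_` when absent.
#' @export
transform_age <- function(values) {
  s <- flatten_singleton(values, "age")
  if (is.na(s)) return(NA_real_)
  low <- tolower(s)
  digits <- gsub("[^0-9]", "", low)
  if (!nzchar(digits))
    ts_parse_error(sprintf("cannot parse age string: \"%s\" (no digits)", s))
  n <- as.numeric(digits)
  if (grepl("month", low)) return(n / 12)
  if (grepl("year", low))  return(n)
  if (grepl("week", low))  return(n / 52)
  if (grepl("day", low))   return(n / 365)
  ts_parse_error(sprintf("cannot parse age string: \"%s\" (unrecognized unit)", s))
}

#' Normalize a registry date to ISO format
#'
#' Registry dates come as `"Month D, YYYY"` or, when the day is not
#' provided, `"Month YYYY"`; the day is then set to the first of the
#' month. Output is always `"YYYY-MM-DD"` (e.g. `"2000-08-06"` for
#' 6 August 2000) and is checked to be a valid calendar date.
#'
#' @param values Character vector of length 0 or 1.
#' @return ISO date string or `NA_character_` when absent.
#' @export
transform_date <- function(values) {
  s <- flatten_singleton(values, "date")
  if (is.na(s)) return(NA_character_)
  s <- trimws(s)
  m <- regmatches(s, regexec("^([A-Za-z]+)\\s+(?:(\\d{1,2}),\\s*)?(\\d{4})$", s))[[1]]
  if (length(m) == 0)
    ts_parse_error(sprintf("cannot parse date string: \"%s\"", s))
  month <- match(tolower(m[2]), tolower(month.name))
  if (is.na(month))
    ts_parse_error(sprintf("cannot parse date string: \"%s\" (unknown month)", s))
  day <- if (nzchar(m[3])) as.integer(m[3]) else 1L
  iso <- sprintf("%04d-%02d-%02d", as.integer(m[4]), month, day)
  if (is.na(as.Date(iso, format = "%Y-%m-%d")))
    ts_parse_error(sprintf("date string \"%s\" is not a valid calendar date", s))
  iso
}

#' Map a registry sex/gender value onto the closed vocabulary
#'
#' Case-insensitive mapping onto `{all, female, male}`; anything else —
#' including a missing value — becomes `unknown`.
#'
#' @param value Single string or `NA`.
#' @return One of `"all"`, `"female"`, `"male"`, `"unknown"`.
#' @export
normalize_sex <- function(value) {
  if (is.na(value)) return("unknown")
  v <- tolower(trimws(value))
  if (v %in% c("all", "female", "male")) v else "unknown"
}

#' Build a term dictionary over a list-valued field
#'
#' Scans the record stream for distinct values of a list-valued field
#' (conditions, location countries) and assigns sequential integer IDs
#' in first-occurrence order: just a number increased by 1 for each new
#' term. IDs are exactly `1..K`, the mapping is a bijection, and
#' re-running on the same stream reproduces it exactly.
#'
#' @param records List of raw study records.
#' @param field List-valued field name, e.g. `"Conditions"` or
#'   `"LocationCountry"`.
#' @param kind Dictionary kind label; defaults from the field name.
#' @return A `term_dictionary`: list with `kind` and `entries` (named
#'   integer vector, term -> ID).
#' @export
build_term_dictionary <- function(records, field,
                                  kind = switch(field,
                                                Conditions = "condition",
                                                LocationCountry = "country",
                                                field)) {
  entries <- integer(0)
  for (rec in records) {
    vals <- if (inherits(rec, "raw_study_record")) rec$values[[field]] else rec[[field]]
    for (v in vals) {
      if (!v %in% names(entries)) {
        entries[[v]] <- length(entries) + 1L
      }
    }
  }
  structure(list(kind = kind, entries = entries), class = "term_dictionary")
}

term_ids <- function(dict, terms) {
  unname(dict$entries[terms])
}

term_names <- function(dict, ids) {
  nm <- names(dict$entries) %||% character(0)
  nm[match(ids, dict$entries)]
}

empty_record_table <- function() {
  data.table(
    nct_id = character(0), brief_title = character(0),
    official_title = character(0), brief_summary = character(0),
    sex = character(0), min_age_years = numeric(0), max_age_years = numeric(0),
    overall_status = character(0), start_date = character(0),
    completion_date = character(0), first_posted_date = character(0),
    last_update_date = character(0), condition_ids = list(),
    country_ids = list(), intervention_names = list())
}

# Parse and validate one raw record into a plain list of typed fields.
# Throws a classed condition on any rule violation; process_snapshot
# collects these per record instead of failing the run.
parse_study_record <- function(rec) {
  v <- rec$values
  nct_id <- flatten_singleton(v[["NCTId"]], "NCTId")
  if (is.na(nct_id) || !grepl(nct_pattern, nct_id))
    ts_validation_error(sprintf("invalid NCTId: \"%s\"", nct_id))
  min_age <- transform_age(v[["MinimumAge"]])
  max_age <- transform_age(v[["MaximumAge"]])
  if (!is.na(min_age) && !is.na(max_age) && min_age > max_age)
    ts_validation_error(sprintf(
      "minimum age (%g y) exceeds maximum age (%g y)", min_age, max_age))
  list(
    nct_id = nct_id,
    brief_title = flatten_singleton(v[["BriefTitle"]], "BriefTitle"),
    official_title = flatten_singleton(v[["OfficialTitle"]], "OfficialTitle"),
    brief_summary = flatten_singleton(v[["BriefSummary"]], "BriefSummary"),
    sex = normalize_sex(flatten_singleton(v[["Gender"]], "Gender")),
    min_age_years = min_age,
    max_age_years = max_age,
    overall_status = flatten_singleton(v[["OverallStatus"]], "OverallStatus"),
    start_date = transform_date(v[["StartDate"]]),
    completion_date = transform_date(v[["CompletionDate"]]),
    first_posted_date = transform_date(v[["StudyFirstPostDate"]]),
    last_update_date = transform_date(v[["LastUpdatePostDate"]]),
    conditions = as.character(v[["Conditions"]] %||% character(0)),
    countries = as.character(v[["LocationCountry"]] %||% character(0)),
    intervention_names = as.character(v[["InterventionName"]] %||% character(0)))
}

#' Process a snapshot into typed study records
#'
#' Runs every raw record through the transformer stack (singleton
#' flattening, age and date normalization, sex vocabulary mapping),
#' validates it (NCT pattern, min age less than or equal to max age,
#' calendar-valid dates), builds condition and country term
#' dictionaries over the surviving records, and resolves each record's
#' terms to dictionary IDs. Per-record failures are reported, never
#' fatal.
#'
#' @param snapshot A `ctg_snapshot`.
#' @return List with `records` (data.table of typed study records, one
#'   row per surviving record), `conditions` and `countries` (term
#'   dictionaries), and `report` (data.table of skipped records:
#'   `rank`, `nct_id`, `reason`).
#' @export
process_snapshot <- function(snapshot) {
  stopifnot(inherits(snapshot, "ctg_snapshot"))
  parsed <- list()
  skip_rank <- integer(0); skip_id <- character(0); skip_reason <- character(0)
  for (rec in snapshot$records) {
    res <- tryCatch(parse_study_record(rec), trialscape_error = function(e) e)
    if (inherits(res, "condition")) {
      skip_rank <- c(skip_rank, rec$rank)
      skip_id <- c(skip_id, rec$values[["NCTId"]][1] %||% NA_character_)
      skip_reason <- c(skip_reason, conditionMessage(res))
    } else {
      parsed[[length(parsed) + 1L]] <- res
    }
  }
  cond_dict <- build_term_dictionary(
    lapply(parsed, function(p) list(Conditions = p$conditions)), "Conditions",
    kind = "condition")
  ctry_dict <- build_term_dictionary(
    lapply(parsed, function(p) list(LocationCountry = p$countries)),
    "LocationCountry", kind = "country")

  records <- if (length(parsed) == 0) empty_record_table() else rbindlist(
    lapply(parsed, function(p) {
      data.table(
        nct_id = p$nct_id, brief_title = p$brief_title,
        official_title = p$official_title, brief_summary = p$brief_summary,
        sex = p$sex, min_age_years = p$min_age_years,
        max_age_years = p$max_age_years, overall_status = p$overall_status,
        start_date = p$start_date, completion_date = p$completion_date,
        first_posted_date = p$first_posted_date,
        last_update_date = p$last_update_date,
        condition_ids = list(term_ids(cond_dict, p$conditions)),
        country_ids = list(term_ids(ctry_dict, p$countries)),
        intervention_names = list(p$intervention_names))
    }))
  list(records = records, conditions = cond_dict, countries = ctry_dict,
       report = data.table(rank = skip_rank, nct_id = skip_id,
                           reason = skip_reason))
}

#' Export typed study records as a flat CSV
#'
#' One row per trial, ISO dates, multi-valued columns (conditions,
#' countries, interventions) joined with semicolons — an inspection
#' surface, not the storage format.
#'
#' @param processed Result of [process_snapshot()], or a store.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_records_csv <- function(processed, path) {
  records <- processed$records
  conditions <- processed$conditions
  countries <- processed$countries
  flat <- copy(records)
  flat[, conditions := vapply(condition_ids, function(ids)
    paste(term_names(conditions, ids), collapse = ";"), character(1))]
  flat[, countries := vapply(country_ids, function(ids)
    paste(term_names(countries, ids), collapse = ";"), character(1))]
  flat[, interventions := vapply(intervention_names, paste,
                                 character(1), collapse = ";")]
  flat[, c("condition_ids", "country_ids", "intervention_names") := NULL]
  fwrite(flat, path)
  invisible(path)
}
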