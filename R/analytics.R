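#' Summary tables
#'
#' Every analytics routine returns a `summary_table`: a long-format
#' data.table of group-key columns plus value column(s), tagged with
#' `value_kind` (`count`, `ratio` or `mean`). Key tuples are unique,
#' ratios lie in `[0, 1]`, counts are non-negative integers. Routines
#' additionally attach an `excluded` attribute reporting how many
#' records they left out and why — records are never silently dropped.
#'
#' @param dt data.table of rows.
#' @param group_keys Ordered character vector of key column names.
#' @param value_kind One of `"count"`, `"ratio"`, `"mean"`.
#' @return The data.table with class `summary_table` and attributes
#'   `group_keys`, `value_kind`.
#' @keywords internal
new_summary_table <- function(dt, group_keys, value_kind) {
  stopifnot(all(group_keys %in% names(dt)))
  if (nrow(dt) > 0 && anyDuplicated(dt, by = group_keys) > 0)
    ts_validation_error("summary table key tuples must be unique")
  value_cols <- setdiff(names(dt), group_keys)
  if (value_kind == "ratio") {
    for (vc in value_cols) {
      v <- dt[[vc]]
      if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
        ts_validation_error("ratios must lie in [0, 1]")
    }
  }
  if (value_kind == "count") {
    for (vc in value_cols) {
      v <- dt[[vc]]
      if (any(v < 0 | v != floor(v), na.rm = TRUE))
        ts_validation_error("counts must be non-negative integers")
    }
  }
  setattr(dt, "group_keys", group_keys)
  setattr(dt, "value_kind", value_kind)
  setattr(dt, "class", c("summary_table", class(dt)))
  dt[]
}

set_excluded <- function(tbl, ...) {
  setattr(tbl, "excluded", list(...))
  tbl
}

#' Write a summary table as CSV
#'
#' Long-format UTF-8 CSV with stable column order — the hand-off layer
#' toward external plotting tools.
#'
#' @param tbl A `summary_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_table <- function(tbl, path) {
  fwrite(tbl, path, na = "")
  invisible(path)
}

annotated_records <- function(store) {
  merge(store$records, store$annotations, by = "nct_id", sort = FALSE)
}

#' Restrict the store to repurposing-relevant trials
#'
#' Joins records with their annotations and drops the roles excluded
#' from every landscape table but the role overview: minimal,
#' not included, rescue medication. Unannotated records are excluded
#' too and counted, never silently dropped.
#'
#' @param store A [trial_store()].
#' @return data.table of record + annotation columns, with attribute
#'   `excluded`: `n_unannotated` and `n_role_excluded`.
#' @export
filter_relevant <- function(store) {
  ann <- annotated_records(store)
  out <- ann[!drug_role %in% excluded_roles()]
  setattr(out, "excluded",
          list(n_unannotated = nrow(store$records) - nrow(ann),
               n_role_excluded = nrow(ann) - nrow(out)))
  out[]
}

#' Per-drug role counts (role overview)
#'
#' Absolute number of trials grouped by primary drug and drug role —
#' the one table in which the excluded roles (minimal, not included,
#' rescue medication) are still visible when `include_all_roles = TRUE`.
#'
#' @param store A [trial_store()].
#' @param include_all_roles Keep the excluded roles (default `TRUE`,
#'   matching the overview chart).
#' @return `summary_table` with keys `(primary_drug, drug_role)` and a
#'   count `value`.
#' @export
counts_by_drug_and_role <- function(store, include_all_roles = TRUE) {
  base <- if (include_all_roles) annotated_records(store) else filter_relevant(store)
  tbl <- base[, .(value = .N), by = .(primary_drug, drug_role)]
  setorder(tbl, primary_drug, drug_role)
  tbl <- new_summary_table(tbl, c("primary_drug", "drug_role"), "count")
  set_excluded(tbl, n_unannotated = nrow(store$records) - nrow(annotated_records(store)))
}

#' Timeline of trial counts per year
#'
#' Absolute number of relevant trials per calendar year, split by
#' primary drug, keyed either on the study start date or on the date
#' the study was first posted on the registry.
#'
#' @param store A [trial_store()].
#' @param date_field `"start"` or `"first_posted"`.
#' @return `summary_table` with keys `(year, primary_drug)` and a count
#'   `value`; attribute `excluded$n_missing_date` counts relevant
#'   trials lacking the date.
#' @export
timeline <- function(store, date_field = c("start", "first_posted")) {
  date_field <- match.arg(date_field)
  rel <- filter_relevant(store)
  col <- switch(date_field, start = "start_date",
                first_posted = "first_posted_date")
  rel[, year := as.integer(substr(get(col), 1, 4))]
  with_date <- rel[!is.na(year)]
  tbl <- with_date[, .(value = .N), by = .(year, primary_drug)]
  setorder(tbl, year, primary_drug)
  tbl <- new_summary_table(tbl, c("year", "primary_drug"), "count")
  set_excluded(tbl, n_missing_date = nrow(rel) - nrow(with_date),
               n_unannotated = attr(rel, "excluded")$n_unannotated,
               n_role_excluded = attr(rel, "excluded")$n_role_excluded)
}

#' Registration lag per first-posted year
#'
#' For relevant trials carrying both a start date and a first-posted
#' date, bins trials by first-posted year and reports, per bin, the
#' number of trials whose start year differs from the posted year
#' (`n_differing`) and the mean lag in years over exactly those
#' differing trials (`mean_lag = mean(first_posted_year - start_year)`,
#' positive = post-registration). Bins where no trial differs keep
#' `n_differing = 0` and an `NA` mean.
#'
#' @param store A [trial_store()].
#' @return `summary_table` with key `(first_posted_year)` and value
#'   columns `n_differing`, `mean_lag`.
#' @export
registration_lag <- function(store) {
  rel <- filter_relevant(store)
  both <- rel[!is.na(start_date) & !is.na(first_posted_date)]
  both[, `:=`(start_year = as.integer(substr(start_date, 1, 4)),
              first_posted_year = as.integer(substr(first_posted_date, 1, 4)))]
  tbl <- both[, {
    lag <- first_posted_year - start_year
    diff <- lag[lag != 0L]
    .(n_differing = length(diff),
      mean_lag = if (length(diff) > 0) mean(diff) else NA_real_)
  }, by = .(first_posted_year)]
  setorder(tbl, first_posted_year)
  tbl <- new_summary_table(tbl, "first_posted_year", "mean")
  set_excluded(tbl, n_missing_date = nrow(rel) - nrow(both))
}

per_drug_ratio <- function(base, key_col) {
  counts <- base[, .(n = .N), by = c("primary_drug", key_col)]
  counts[, value := n / sum(n), by = primary_drug]
  counts[, n := NULL]
  setorderv(counts, c("primary_drug", key_col))
  new_summary_table(counts, c("primary_drug", key_col), "ratio")
}

#' Status distribution per drug
#'
#' For each drug, the distribution of overall registry statuses as a
#' ratio between 0 and 1; per-drug ratios sum to 1.
#'
#' @param store A [trial_store()].
#' @return `summary_table` with keys `(primary_drug, overall_status)`
#'   and a ratio `value`.
#' @export
status_distribution <- function(store) {
  per_drug_ratio(filter_relevant(store), "overall_status")
}

#' Age groups intersected by an eligibility interval
#'
#' Registry convention: child 0-17, adult 18-64, older adult 65+. A
#' trial belongs to every group its `[min, max]` eligibility interval
#' intersects; an absent minimum counts as 0, an absent maximum as
#' unbounded.
#'
#' @param min_age,max_age Ages in decimal years (may be `NA`).
#' @return Label like `"child"`, `"adult+older_adult"` or
#'   `"child+adult+older_adult"` in fixed group order.
#' @export
age_group_label <- function(min_age, max_age) {
  lo <- ifelse(is.na(min_age), 0, min_age)
  hi <- ifelse(is.na(max_age), Inf, max_age)
  mapply(function(lo, hi) {
    groups <- c(if (lo < 18) "child",
                if (lo < 65 && hi >= 18) "adult",
                if (hi >= 65) "older_adult")
    paste(groups, collapse = "+")
  }, lo, hi)
}

#' Age-group distribution per drug
#'
#' Maps each relevant trial's eligibility interval onto the set of age
#' groups it intersects ([age_group_label()]) and reports, per drug,
#' the ratio of trials per group combination.
#'
#' @param store A [trial_store()].
#' @return `summary_table` with keys `(primary_drug, age_group)` and a
#'   ratio `value`.
#' @export
age_group_distribution <- function(store) {
  rel <- filter_relevant(store)
  rel[, age_group := age_group_label(min_age_years, max_age_years)]
  per_drug_ratio(rel, "age_group")
}

#' Sex-eligibility distribution per drug
#'
#' Ratio of trials open to all, female-only and male-only participants,
#' per drug.
#'
#' @param store A [trial_store()].
#' @return `summary_table` with keys `(primary_drug, sex)` and a ratio
#'   `value`.
#' @export
sex_distribution <- function(store) {
  per_drug_ratio(filter_relevant(store), "sex")
}

#' Use-case counts split by drug and repurposing flag
#'
#' Absolute number of relevant trials per curator-assigned use case,
#' split by primary drug and repurposing flag. Use cases are ordered by
#' descending total count, ties broken lexicographically for
#' reproducibility.
#'
#' @param store A [trial_store()].
#' @return `summary_table` with keys `(use_case, primary_drug,
#'   repurposing)` and a count `value`.
#' @export
usecase_table <- function(store) {
  rel <- filter_relevant(store)
  tbl <- rel[, .(value = .N), by = .(use_case, primary_drug, repurposing)]
  totals <- tbl[, .(total = sum(value)), by = use_case]
  tbl <- merge(tbl, totals, by = "use_case", sort = FALSE)
  setorder(tbl, -total, use_case, primary_drug, repurposing)
  tbl[, total := NULL]
  new_summary_table(tbl, c("use_case", "primary_drug", "repurposing"), "count")
}

#' Trials per country, counted once per study
#'
#' Number of distinct relevant trials with at least one location in a
#' country: a study with many sites in the same country increases that
#' country's count by one only (so site totals can far exceed study
#' counts).
#'
#' @param store A [trial_store()].
#' @return `summary_table` with key `(country)` and a count `value`,
#'   ordered by descending count then name.
#' @export
country_counts <- function(store) {
  rel <- filter_relevant(store)
  pairs <- rel[, .(country_id = unique(unlist(country_ids))), by = nct_id]
  pairs <- pairs[!is.na(country_id)]
  tbl <- pairs[, .(value = .N), by = .(country_id)]
  tbl <- data.table(country = term_names(store$countries, tbl$country_id),
                    value = tbl$value)
  setorder(tbl, -value, country)
  new_summary_table(tbl, "country", "count")
}

#' Publication-bias cross-tab
#'
#' Restricted to trials marked as repurposing: cross-tabulates overall
#' registry status against publication status (paper,
#' registry-submitted results, or none).
#'
#' @param store A [trial_store()].
#' @return `summary_table` with keys `(overall_status,
#'   publication_status)` and a count `value`.
#' @export
publication_crosstab <- function(store) {
  rel <- filter_relevant(store)
  rep <- rel[repurposing == TRUE]
  tbl <- rep[, .(value = .N), by = .(overall_status, publication_status)]
  setorder(tbl, overall_status, publication_status)
  new_summary_table(tbl, c("overall_status", "publication_status"), "count")
}

#' Classic-use synonym list for the triage funnel
#'
#' The use cases counted as the funnel's "classic: bioequivalence"
#' bucket; matching is case-insensitive on the leading word, so
#' `"taste [form and preference]"` maps to `"taste"`.
#'
#' @return Character vector of classic use-case terms.
#' @export
classic_use_terms <- function() {
  c("bioequivalence", "bioavailability", "pharmacokinetics", "taste")
}

matches_classic_use <- function(use_case, terms = classic_use_terms()) {
  low <- tolower(trimws(use_case))
  Reduce(`|`, lapply(terms, function(t) grepl(paste0("^", t, "\\b"), low)),
         accumulate = FALSE)
}

#' Repurposing triage funnel
#'
#' Staged filtering of the relevant trials: the total; trials not
#' marked as repurposing, split into the classic bucket (use case
#' bioequivalence / bioavailability / pharmacokinetics / taste) versus
#' every other classic use case; trials marked as repurposing; and
#' repurposing trials whose results were published as a paper.
#' Conservation holds by construction: `total == classic_use_case +
#' classic_use_case_other + repurposing`; unannotated and role-excluded
#' counts are reported in the `excluded` attribute.
#'
#' @param store A [trial_store()].
#' @param classic_terms Synonym list for the classic bucket.
#' @return `summary_table` with key `(stage)` and a count `value`, in
#'   funnel order: total, classic_use_case, classic_use_case_other,
#'   repurposing, repurposing_published.
#' @export
triage_funnel <- function(store, classic_terms = classic_use_terms()) {
  rel <- filter_relevant(store)
  n_total <- nrow(rel)
  is_rep <- rel$repurposing
  is_classic <- !is_rep & matches_classic_use(rel$use_case, classic_terms)
  tbl <- data.table(
    stage = c("total", "classic_use_case", "classic_use_case_other",
              "repurposing", "repurposing_published"),
    value = c(n_total, sum(is_classic), sum(!is_rep & !is_classic),
              sum(is_rep),
              sum(is_rep & rel$publication_status == "paper")))
  tbl <- new_summary_table(tbl, "stage", "count")
  set_excluded(tbl,
               n_unannotated = attr(rel, "excluded")$n_unannotated,
               n_role_excluded = attr(rel, "excluded")$n_role_excluded)
}

#' Run one named analytics table
#'
#' Dispatch wrapper used by the command-line front end.
#'
#' @param store A [trial_store()].
#' @param name Table name: one of `roles`, `timeline_start`,
#'   `timeline_first_posted`, `lag`, `status`, `age`, `sex`, `usecase`,
#'   `countries`, `publication`, `funnel`.
#' @return A `summary_table`.
#' @export
run_table <- function(store, name) {
  switch(name,
         roles = counts_by_drug_and_role(store),
         timeline_start = timeline(store, "start"),
         timeline_first_posted = timeline(store, "first_posted"),
         lag = registration_lag(store),
         status = status_distribution(store),
         age = age_group_distribution(store),
         sex = sex_distribution(store),
         usecase = usecase_table(store),
         countries = country_counts(store),
         publication = publication_crosstab(store),
         funnel = triage_funnel(store),
         ts_validation_error(sprintf(
           "unknown table \"%s\"; available: roles, timeline_start, timeline_first_posted, lag, status, age, sex, usecase, countries, publication, funnel",
           name)))
}
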