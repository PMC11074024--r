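check_weight_map <- function(w, name) {
  if (length(w) == 0 || is.null(names(w)) || any(!nzchar(names(w))))
    ts_validation_error(sprintf("%s must be a named weight map", name))
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    ts_validation_error(sprintf("%s weights must be non-negative and sum to 1", name))
  invisible(w)
}

check_prob <- function(p, name) {
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1)
    ts_validation_error(sprintf("%s must be a probability in [0, 1]", name))
  invisible(p)
}

#' Synthetic-fixture configuration
#'
#' Declares the composition of a generated registry snapshot: how many
#' records, which drugs, the categorical mixes for role / status / sex
#' / use case / age archetype / publication status, the lag-year
#' distribution, the per-record quirk probabilities (ages in months,
#' dates missing the day, multi-country site lists, false-positive
#' records where a search term matches a person's name, planted-invalid
#' records), and the country site mix. Defaults emulate the observed
#' landscape of second-generation antihistamine trials: roughly 14% of
#' use cases point toward repurposing, completed is the dominant
#' status, 90-95% of trials are open to all sexes, and the United
#' States dominates the site list.
#'
#' @param n_records Number of records to generate.
#' @param seed Integer seed; every record draws from its own stream
#'   keyed on `(seed, rank)`, so adding records never perturbs others.
#' @param drug_terms Drug names records are spread over.
#' @param role_mix,status_mix,sex_mix,usecase_mix,age_mix,pub_mix Named
#'   categorical weight maps, each summing to 1.
#' @param repurposing_use_cases Use cases whose trials carry the
#'   repurposing flag.
#' @param lag_years Weight map over integer registration lags in years.
#' @param country_mix Weight map over site countries.
#' @param p_month_age Probability that an eligible minimum age is
#'   expressed in months instead of years.
#' @param p_partial_date Probability that a start date omits the day.
#' @param p_multi_country Probability that a record lists multiple
#'   sites.
#' @param p_false_positive Probability of a false-positive record (a
#'   trade-name synonym matching a person's name; annotated role
#'   `not_included`).
#' @param p_invalid Probability of a planted-invalid record (minimum
#'   age above maximum age), skipped at processing time.
#' @param start_years Integer range start years are drawn from.
#' @return A `fixture_config` object.
#' @export
fixture_config <- function(
    n_records = 300L,
    seed = 1L,
    drug_terms = default_drug_terms(),
    role_mix = c(main = 0.35, comparison = 0.18, combination = 0.14,
                 control = 0.08, premedication = 0.06, minimal = 0.05,
                 rescue_medication = 0.04, not_included = 0.10),
    status_mix = c("Completed" = 0.55, "Recruiting" = 0.10,
                   "Unknown status" = 0.12, "Terminated" = 0.08,
                   "Withdrawn" = 0.05, "Active, not recruiting" = 0.05,
                   "Not yet recruiting" = 0.05),
    sex_mix = c(All = 0.92, Male = 0.06, Female = 0.02),
    usecase_mix = c("allergic rhinitis" = 0.32, "urticaria" = 0.18,
                    "bioequivalence" = 0.18, "bioavailability" = 0.07,
                    "pharmacokinetics" = 0.06,
                    "taste [form and preference]" = 0.05,
                    "asthma" = 0.04, "infusion-associated reactions" = 0.03,
                    "G-CSF-related bone pain" = 0.02,
                    "androgenetic alopecia" = 0.02, "COVID-19" = 0.015,
                    "exercise physiology" = 0.01,
                    "neuromyelitis optica" = 0.005),
    repurposing_use_cases = c("asthma", "infusion-associated reactions",
                              "G-CSF-related bone pain",
                              "androgenetic alopecia", "COVID-19",
                              "exercise physiology", "neuromyelitis optica"),
    age_mix = c("child" = 0.10, "adult" = 0.55, "child+adult" = 0.05,
                "adult+older_adult" = 0.20,
                "child+adult+older_adult" = 0.10),
    pub_mix = c(paper = 0.24, registry_results = 0.16, none = 0.60),
    lag_years = c("0" = 0.55, "1" = 0.20, "2" = 0.08, "3" = 0.05,
                  "4" = 0.04, "5" = 0.03, "6" = 0.03, "7" = 0.02),
    country_mix = c("United States" = 0.35, "Canada" = 0.10,
                    "Germany" = 0.09, "France" = 0.06,
                    "United Kingdom" = 0.06, "India" = 0.06,
                    "China" = 0.05, "Japan" = 0.05,
                    "Korea, Republic of" = 0.04, "Netherlands" = 0.03,
                    "Italy" = 0.03, "Spain" = 0.03, "Brazil" = 0.02,
                    "Mexico" = 0.02, "Australia" = 0.01),
    p_month_age = 0.15,
    p_partial_date = 0.25,
    p_multi_country = 0.30,
    p_false_positive = 0.04,
    p_invalid = 0.03,
    start_years = 2000:2019) {
  cfg <- list(
    n_records = as.integer(n_records), seed = as.integer(seed),
    drug_terms = drug_terms, role_mix = role_mix, status_mix = status_mix,
    sex_mix = sex_mix, usecase_mix = usecase_mix,
    repurposing_use_cases = repurposing_use_cases, age_mix = age_mix,
    pub_mix = pub_mix, lag_years = lag_years, country_mix = country_mix,
    p_month_age = p_month_age, p_partial_date = p_partial_date,
    p_multi_country = p_multi_country,
    p_false_positive = p_false_positive, p_invalid = p_invalid,
    start_years = as.integer(start_years))
  if (cfg$n_records < 0) ts_validation_error("n_records must be >= 0")
  if (length(cfg$drug_terms) == 0) ts_validation_error("drug_terms must be non-empty")
  for (nm in c("role_mix", "status_mix", "sex_mix", "usecase_mix", "age_mix",
               "pub_mix", "lag_years", "country_mix"))
    check_weight_map(cfg[[nm]], nm)
  if (!all(names(cfg$role_mix) %in% drug_roles()))
    ts_validation_error("role_mix names must be drug-role labels")
  for (nm in c("p_month_age", "p_partial_date", "p_multi_country",
               "p_false_positive", "p_invalid"))
    check_prob(cfg[[nm]], nm)
  structure(cfg, class = "fixture_config")
}

# Run expr under a deterministic per-record RNG stream keyed on
# (seed, rank), restoring the caller's RNG state afterwards. Inserting
# a record never perturbs another record's draws.
with_record_rng <- function(seed, rank, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(((seed %% 59999L) * 30011L + (rank %% 65521L) * 17L) %% 2147483629L)
  expr
}

draw_cat <- function(mix) {
  sample(names(mix), 1L, prob = unname(mix))
}

month_name_of <- function(m) month.name[m]

# The complete per-record plan: every planted fact about one synthetic
# record, drawn from the record's own stream. Both the snapshot builder
# and the annotation generator derive from this single function, so the
# two artifacts cannot drift apart.
record_plan <- function(config, rank) {
  with_record_rng(config$seed, rank, {
    nct_id <- sprintf("NCT99%06d", rank)
    false_positive <- runif(1) < config$p_false_positive
    invalid <- !false_positive && runif(1) < config$p_invalid
    drug <- sample(config$drug_terms, 1L)
    role <- if (false_positive) "not_included" else draw_cat(config$role_mix)
    use_case <- if (false_positive) "false positive match"
                else draw_cat(config$usecase_mix)
    repurposing <- !false_positive && use_case %in% config$repurposing_use_cases
    publication <- if (repurposing) draw_cat(config$pub_mix) else "none"
    status <- draw_cat(config$status_mix)
    sex <- draw_cat(config$sex_mix)

    age_group <- draw_cat(config$age_mix)
    month_eligible <- age_group %in% c("child", "child+adult")
    month_age <- month_eligible && runif(1) < config$p_month_age
    ages <- switch(age_group,
      "child" = list(min = if (month_age) "6 Months" else "2 Years",
                     max = "17 Years"),
      "adult" = list(min = "18 Years", max = "64 Years"),
      "child+adult" = list(min = if (month_age) "144 Months" else "12 Years",
                           max = "64 Years"),
      "adult+older_adult" = list(min = "18 Years", max = character(0)),
      "child+adult+older_adult" = list(min = character(0), max = character(0)))
    if (invalid) ages <- list(min = "18 Years", max = "6 Months")

    start_year <- sample(config$start_years, 1L)
    start_month <- sample(12L, 1L)
    start_day <- sample(28L, 1L)
    partial_date <- runif(1) < config$p_partial_date
    start_str <- if (partial_date)
      sprintf("%s %d", month_name_of(start_month), start_year)
    else
      sprintf("%s %d, %d", month_name_of(start_month), start_day, start_year)
    lag <- as.integer(draw_cat(config$lag_years))
    posted_year <- start_year + lag
    posted_month <- sample(12L, 1L)
    posted_str <- sprintf("%s %d, %d", month_name_of(posted_month),
                          sample(28L, 1L), posted_year)
    completion_str <- sprintf("%s %d, %d", month_name_of(sample(12L, 1L)),
                              sample(28L, 1L), start_year + 1L)
    last_update_str <- sprintf("%s %d, %d", month_name_of(sample(12L, 1L)),
                               sample(28L, 1L), 2022L)

    primary_country <- draw_cat(config$country_mix)
    multi_country <- runif(1) < config$p_multi_country
    sites <- primary_country
    if (multi_country) {
      extra <- replicate(sample(3L, 1L), draw_cat(config$country_mix))
      sites <- c(sites, extra)
    }

    conditions <- if (false_positive) "Chronic Cough" else {
      base <- tools::toTitleCase(use_case)
      if (runif(1) < 0.3) c(base, "Hypersensitivity") else base
    }
    interventions <- if (false_positive) "NV-101" else {
      iv <- drug
      if (runif(1) < 0.4) iv <- c(iv, "Placebo")
      iv
    }
    brief_title <- if (false_positive)
      sprintf("Study of NV-101 in Chronic Cough (PI: A. Allegra)")
    else sprintf("%s for %s", drug, use_case)
    summary_txt <- if (false_positive)
      "Evaluation of the investigational agent NV-101; principal investigator Dr. Allegra."
    else sprintf("Evaluation of %s in %s.", tolower(drug), use_case)

    list(rank = rank, nct_id = nct_id, false_positive = false_positive,
         invalid = invalid, drug = drug, role = role, use_case = use_case,
         repurposing = repurposing, publication = publication,
         status = status, sex = sex, age_group = age_group,
         month_eligible = month_eligible, month_age = month_age,
         ages = ages, start_year = start_year, start_str = start_str,
         partial_date = partial_date, lag = lag, posted_year = posted_year,
         posted_str = posted_str, completion_str = completion_str,
         last_update_str = last_update_str, sites = sites,
         multi_country = multi_country, conditions = conditions,
         interventions = interventions, brief_title = brief_title,
         summary_txt = summary_txt)
  })
}

plan_to_raw_record <- function(plan) {
  new_raw_record(plan$rank, list(
    NCTId = plan$nct_id,
    OfficialTitle = paste("A Study:", plan$brief_title),
    BriefTitle = plan$brief_title,
    BriefSummary = plan$summary_txt,
    Conditions = plan$conditions,
    Gender = plan$sex,
    MaximumAge = plan$ages$max,
    MinimumAge = plan$ages$min,
    OverallStatus = plan$status,
    StartDate = plan$start_str,
    CompletionDate = plan$completion_str,
    LastUpdatePostDate = plan$last_update_str,
    StudyFirstPostDate = plan$posted_str,
    LocationCountry = plan$sites,
    LocationFacility = paste("Site", seq_along(plan$sites)),
    InterventionName = plan$interventions))
}

# Plain-loop tallies over the planted per-record facts. Deliberately
# base R (no data.table grouping) so the ground truth is an independent
# path from the analytics implementation it certifies.
tally_counts <- function(df, cols, value_col = "value") {
  if (nrow(df) == 0) {
    out <- df[, cols, drop = FALSE]
    out[[value_col]] <- integer(0)
    return(out)
  }
  key <- do.call(paste, c(df[cols], sep = "\x1f"))
  tab <- table(key)
  parts <- strsplit(names(tab), "\x1f", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- cols
  for (col in cols) {
    if (is.numeric(df[[col]])) out[[col]] <- as.numeric(out[[col]])
    if (is.logical(df[[col]])) out[[col]] <- as.logical(out[[col]])
    if (is.integer(df[[col]])) out[[col]] <- as.integer(out[[col]])
  }
  out[[value_col]] <- as.integer(unname(c(tab)))
  out[do.call(order, out[cols]), , drop = FALSE]
}

tally_ratio <- function(df, col) {
  out <- tally_counts(df, c("drug", col))
  totals <- vapply(out$drug, function(d) sum(out$value[out$drug == d]),
                   numeric(1))
  out$value <- out$value / totals
  out
}

compute_ground_truth <- function(plans, config) {
  to_df <- function(field, cast = as.character) {
    cast(vapply(plans, function(p) as.character(p[[field]]), character(1)))
  }
  df <- data.frame(
    rank = to_df("rank", as.integer), nct_id = to_df("nct_id"),
    false_positive = to_df("false_positive", as.logical),
    invalid = to_df("invalid", as.logical), drug = to_df("drug"),
    role = to_df("role"), use_case = to_df("use_case"),
    repurposing = to_df("repurposing", as.logical),
    publication = to_df("publication"), status = to_df("status"),
    sex = tolower(to_df("sex")), age_group = to_df("age_group"),
    month_eligible = to_df("month_eligible", as.logical),
    month_age = to_df("month_age", as.logical),
    start_year = to_df("start_year", as.integer),
    partial_date = to_df("partial_date", as.logical),
    lag = to_df("lag", as.integer),
    posted_year = to_df("posted_year", as.integer),
    multi_country = to_df("multi_country", as.logical),
    stringsAsFactors = FALSE)
  df$countries <- lapply(plans, function(p) unique(p$sites))

  valid <- df[!df$invalid, , drop = FALSE]
  rel <- valid[!valid$role %in% excluded_roles(), , drop = FALSE]

  # registration lag: per posted year, trials with differing years and
  # their mean lag
  lag_tab <- NULL
  if (nrow(rel) > 0) {
    years <- sort(unique(rel$posted_year))
    lag_tab <- data.frame(first_posted_year = years,
                          n_differing = NA_integer_, mean_lag = NA_real_)
    for (i in seq_along(years)) {
      lags <- rel$lag[rel$posted_year == years[i]]
      diffs <- lags[lags != 0L]
      lag_tab$n_differing[i] <- length(diffs)
      lag_tab$mean_lag[i] <- if (length(diffs) > 0) mean(diffs) else NA_real_
    }
  } else {
    lag_tab <- data.frame(first_posted_year = integer(0),
                          n_differing = integer(0), mean_lag = numeric(0))
  }

  # country counts: once per study
  ctab <- table(unlist(lapply(seq_len(nrow(rel)), function(i) rel$countries[[i]])))
  country_tab <- data.frame(country = as.character(names(ctab) %||% character(0)),
                            value = as.integer(unname(c(ctab))),
                            stringsAsFactors = FALSE)
  country_tab <- country_tab[order(-country_tab$value, country_tab$country), ,
                             drop = FALSE]

  rep_rel <- rel[rel$repurposing, , drop = FALSE]
  classic_terms <- c("bioequivalence", "bioavailability", "pharmacokinetics",
                     "taste [form and preference]")
  n_rel <- nrow(rel)
  n_classic <- sum(!rel$repurposing & rel$use_case %in% classic_terms)
  n_classic_other <- sum(!rel$repurposing & !rel$use_case %in% classic_terms)
  funnel <- data.frame(
    stage = c("total", "classic_use_case", "classic_use_case_other",
              "repurposing", "repurposing_published"),
    value = c(n_rel, n_classic, n_classic_other, nrow(rep_rel),
              sum(rep_rel$publication == "paper")),
    stringsAsFactors = FALSE)

  list(
    per_record = df,
    planted_invalid = sum(df$invalid),
    n_false_positive = sum(df$false_positive),
    n_relevant = n_rel,
    n_role_excluded = nrow(valid) - n_rel,
    n_countries = length(unique(unlist(valid$countries))),
    tables = list(
      role_counts = tally_counts(
        data.frame(primary_drug = valid$drug, drug_role = valid$role),
        c("primary_drug", "drug_role")),
      timeline_start = tally_counts(
        data.frame(year = rel$start_year, primary_drug = rel$drug),
        c("year", "primary_drug")),
      timeline_first_posted = tally_counts(
        data.frame(year = rel$posted_year, primary_drug = rel$drug),
        c("year", "primary_drug")),
      lag = lag_tab,
      status_ratio = tally_ratio(
        data.frame(drug = rel$drug, overall_status = rel$status,
                   stringsAsFactors = FALSE), "overall_status"),
      age_ratio = tally_ratio(
        data.frame(drug = rel$drug, age_group = rel$age_group,
                   stringsAsFactors = FALSE), "age_group"),
      sex_ratio = tally_ratio(
        data.frame(drug = rel$drug, sex = rel$sex,
                   stringsAsFactors = FALSE), "sex"),
      usecase_counts = tally_counts(
        data.frame(use_case = rel$use_case, primary_drug = rel$drug,
                   repurposing = rel$repurposing, stringsAsFactors = FALSE),
        c("use_case", "primary_drug", "repurposing")),
      country_counts = country_tab,
      publication_crosstab = tally_counts(
        data.frame(overall_status = rep_rel$status,
                   publication_status = rep_rel$publication,
                   stringsAsFactors = FALSE),
        c("overall_status", "publication_status")),
      funnel = funnel))
}

#' Generate a synthetic registry snapshot with ground truth
#'
#' Deterministic under the configured seed: builds `n_records` raw
#' records in the registry JSON dialect — singleton fields wrapped in
#' lists, ages as `"N Years"` / `"N Months"` strings, start dates
#' sometimes missing the day, multi-country site lists, occasional
#' false-positive records where a trade-name synonym appears only as a
#' person's name — together with a `GroundTruth` object tabulating
#' exactly what every analytics table should recover.
#'
#' @param config A [fixture_config()].
#' @return List of `snapshot` (a `ctg_snapshot`) and `truth` (list:
#'   `per_record`, `tables`, `planted_invalid`, `n_relevant`,
#'   `n_role_excluded`, `n_false_positive`, `n_countries`).
#' @export
generate_snapshot <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  plans <- lapply(seq_len(config$n_records),
                  function(r) record_plan(config, r))
  records <- lapply(plans, plan_to_raw_record)
  snap <- new_snapshot(records, length(records),
                       build_query(config$drug_terms),
                       retrieved_at = "2023-01-02T00:00:00+0000")
  list(snapshot = snap, truth = compute_ground_truth(plans, config))
}

#' Generate an old/new snapshot pair with planted differences
#'
#' The second snapshot extends the first by `n_new` fresh records and
#' changes the raw `LastUpdatePostDate` of `n_updated` existing ones,
#' mirroring the drift a registry shows between two harvests (the
#' observed scale: a few dozen updates and a dozen new entries over
#' half a year).
#'
#' @param config A [fixture_config()].
#' @param n_new Number of added records.
#' @param n_updated Number of records with a changed update date.
#' @return List of `old`, `new` (both `ctg_snapshot`) and `truth`
#'   (list: `new_ids`, `updated_ids`).
#' @export
generate_snapshot_pair <- function(config, n_new, n_updated) {
  stopifnot(inherits(config, "fixture_config"))
  if (n_updated > config$n_records)
    ts_validation_error("n_updated cannot exceed n_records")
  old <- generate_snapshot(config)$snapshot

  cfg2 <- config
  cfg2$n_records <- config$n_records + as.integer(n_new)
  new <- generate_snapshot(cfg2)$snapshot

  updated_ranks <- with_record_rng(config$seed, 0L,
                                   sort(sample(config$n_records, n_updated)))
  updated_ids <- character(0)
  for (r in updated_ranks) {
    rec <- new$records[[r]]
    day <- with_record_rng(config$seed + 1L, r, sample(28L, 1L))
    rec$values[["LastUpdatePostDate"]] <-
      sprintf("August %d, 2023", day)  # base snapshots date from 2022
    new$records[[r]] <- rec
    updated_ids <- c(updated_ids, rec$values[["NCTId"]])
  }
  new_ids <- vapply(new$records[seq_len(n_new) + config$n_records],
                    function(r) r$values[["NCTId"]], character(1))
  list(old = old, new = new,
       truth = list(new_ids = sort(new_ids), updated_ids = sort(updated_ids)))
}

#' Generate the annotation set matching a synthetic snapshot
#'
#' Re-derives each record's plan from `(seed, rank)` and emits one
#' annotation per record that survives processing (planted-invalid
#' records are skipped, since they never reach the store).
#' False-positive records get role `not_included`.
#'
#' @param snapshot A generated `ctg_snapshot`.
#' @param config The [fixture_config()] that produced it.
#' @return data.table in the annotation-store schema.
#' @export
generate_annotations <- function(snapshot, config) {
  stopifnot(inherits(snapshot, "ctg_snapshot"),
            inherits(config, "fixture_config"))
  rows <- list()
  for (rec in snapshot$records) {
    plan <- record_plan(config, rec$rank)
    if (plan$invalid) next
    rows[[length(rows) + 1L]] <- data.table(
      nct_id = plan$nct_id, primary_drug = plan$drug,
      additional_drugs = list(character(0)),
      legacy_search_term = if (plan$false_positive) plan$drug else NA_character_,
      use_case = plan$use_case, drug_role = plan$role,
      repurposing = plan$repurposing, publication_status = plan$publication,
      publication_ref = if (plan$publication == "paper")
        sprintf("https://doi.example/10.9999/%s", tolower(plan$nct_id))
      else NA_character_,
      notes = NA_character_)
  }
  if (length(rows) == 0) return(empty_annotation_table())
  rbindlist(rows)
}

#' Apply a generated annotation table to a store
#'
#' Convenience loop over [set_annotation()].
#'
#' @param store A [trial_store()].
#' @param ann_dt data.table in the annotation-store schema (e.g. from
#'   [generate_annotations()]).
#' @return The store, invisibly.
#' @export
apply_annotations <- function(store, ann_dt) {
  for (i in seq_len(nrow(ann_dt))) {
    r <- ann_dt[i]
    set_annotation(store, annotation(
      nct_id = r$nct_id, primary_drug = r$primary_drug,
      additional_drugs = r$additional_drugs[[1]],
      legacy_search_term = r$legacy_search_term, use_case = r$use_case,
      drug_role = r$drug_role, repurposing = r$repurposing,
      publication_status = r$publication_status,
      publication_ref = r$publication_ref, notes = r$notes))
  }
  invisible(store)
}
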