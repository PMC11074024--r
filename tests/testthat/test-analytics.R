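# One handcrafted record per drug role, annotated accordingly.
role_store <- function() {
  roles <- drug_roles()
  tiny_store(lapply(seq_along(roles), raw_rec),
             annotations = lapply(seq_along(roles), function(i)
               ann_args(sprintf("NCT%08d", i), role = roles[i])))
}

test_that("filter_relevant drops exactly the excluded roles", {
  store <- role_store()
  rel <- filter_relevant(store)
  expect_equal(nrow(rel), 5L)                      # 8 roles minus 3 excluded
  expect_length(intersect(rel$drug_role, excluded_roles()), 0)
  expect_equal(attr(rel, "excluded")$n_role_excluded, 3L)
  # all-main store: identity
  store2 <- tiny_store(lapply(1:4, raw_rec),
                       annotations = lapply(1:4, function(i)
                         ann_args(sprintf("NCT%08d", i))))
  expect_equal(nrow(filter_relevant(store2)), 4L)
  # unannotated records are counted, not silently dropped
  store3 <- tiny_store(lapply(1:4, raw_rec),
                       annotations = list(ann_args("NCT00000001")))
  expect_equal(attr(filter_relevant(store3), "excluded")$n_unannotated, 3L)
})

test_that("counts_by_drug_and_role counts (drug, role) cells", {
  store <- tiny_store(lapply(1:2, raw_rec), annotations = list(
    ann_args("NCT00000001", role = "main"),
    ann_args("NCT00000002", role = "control")))
  tbl <- counts_by_drug_and_role(store)
  expect_table_equal(tbl, data.frame(
    primary_drug = "Cetirizine", drug_role = c("control", "main"),
    value = c(1L, 1L)))
  # include_all_roles = TRUE is the only view keeping excluded roles
  all_roles <- counts_by_drug_and_role(role_store(), include_all_roles = TRUE)
  expect_setequal(all_roles$drug_role, drug_roles())
  only_rel <- counts_by_drug_and_role(role_store(), include_all_roles = FALSE)
  expect_length(intersect(only_rel$drug_role, excluded_roles()), 0)
  # empty store -> empty table
  expect_equal(nrow(counts_by_drug_and_role(trial_store())), 0L)
})

test_that("timeline groups by year and reports missing dates", {
  store <- tiny_store(list(
    raw_rec(1, StartDate = "May 1, 2005"),
    raw_rec(2, StartDate = "June 2005"),
    raw_rec(3, StartDate = character(0))),
    annotations = lapply(1:3, function(i) ann_args(sprintf("NCT%08d", i))))
  tbl <- timeline(store, "start")
  expect_table_equal(tbl, data.frame(year = 2005L, primary_drug = "Cetirizine",
                                     value = 2L))
  expect_equal(attr(tbl, "excluded")$n_missing_date, 1L)
})

test_that("registration_lag bins by first-posted year over differing trials", {
  store <- tiny_store(list(
    raw_rec(1, StartDate = "March 1, 2003", StudyFirstPostDate = "July 9, 2009"),
    raw_rec(2, StartDate = "March 1, 2010", StudyFirstPostDate = "July 9, 2010")),
    annotations = lapply(1:2, function(i) ann_args(sprintf("NCT%08d", i))))
  tbl <- registration_lag(store)
  r2009 <- tbl[tbl$first_posted_year == 2009]
  expect_equal(r2009$n_differing, 1L)
  expect_equal(r2009$mean_lag, 6.0)
  r2010 <- tbl[tbl$first_posted_year == 2010]
  expect_equal(r2010$n_differing, 0L)              # same-year trial
  expect_true(is.na(r2010$mean_lag))
})

test_that("status_distribution is a per-drug ratio summing to 1", {
  store <- tiny_store(list(
    raw_rec(1), raw_rec(2), raw_rec(3),
    raw_rec(4, OverallStatus = "Terminated")),
    annotations = lapply(1:4, function(i) ann_args(sprintf("NCT%08d", i))))
  tbl <- status_distribution(store)
  expect_equal(tbl[overall_status == "Completed", value], 0.75)
  expect_equal(tbl[overall_status == "Terminated", value], 0.25)
  expect_equal(sum(tbl$value), 1, tolerance = 1e-9)
})

test_that("age_group_label intersects the eligibility interval", {
  expect_identical(age_group_label(18, 64), "adult")
  expect_identical(age_group_label(NA, NA), "child+adult+older_adult")
  expect_identical(age_group_label(0, 17), "child")
  expect_identical(age_group_label(12, 64), "child+adult")
  expect_identical(age_group_label(18, NA), "adult+older_adult")
  expect_identical(age_group_label(70, NA), "older_adult")
  expect_identical(age_group_label(0.5, 11), "child")
})

test_that("sex_distribution ratios per drug", {
  store <- tiny_store(list(raw_rec(1), raw_rec(2, Gender = "Female")),
                      annotations = lapply(1:2, function(i)
                        ann_args(sprintf("NCT%08d", i))))
  tbl <- sex_distribution(store)
  expect_equal(tbl$value, c(0.5, 0.5))
})

test_that("usecase_table orders by descending total, ties lexicographic", {
  store <- tiny_store(lapply(1:6, raw_rec), annotations = list(
    ann_args("NCT00000001", use_case = "urticaria"),
    ann_args("NCT00000002", use_case = "urticaria"),
    ann_args("NCT00000003", use_case = "urticaria"),
    ann_args("NCT00000004", use_case = "asthma", repurposing = TRUE),
    ann_args("NCT00000005", use_case = "alopecia", repurposing = TRUE),
    ann_args("NCT00000006", use_case = "covid", repurposing = TRUE)))
  tbl <- usecase_table(store)
  expect_identical(tbl$use_case[1], "urticaria")   # count 3 first
  expect_identical(tbl$use_case[-1], sort(c("asthma", "alopecia", "covid")))
})

test_that("country_counts counts each study once per country", {
  store <- tiny_store(list(
    raw_rec(1, LocationCountry = c("United States", "United States",
                                   "United States", "Canada")),
    raw_rec(2, LocationCountry = character(0))),
    annotations = lapply(1:2, function(i) ann_args(sprintf("NCT%08d", i))))
  tbl <- country_counts(store)
  expect_table_equal(tbl, data.frame(country = c("Canada", "United States"),
                                     value = c(1L, 1L)))
  # no locations at all -> empty
  store2 <- tiny_store(list(raw_rec(1, LocationCountry = character(0))),
                       annotations = list(ann_args("NCT00000001")))
  expect_equal(nrow(country_counts(store2)), 0L)
})

test_that("publication_crosstab restricts to repurposing trials", {
  store <- tiny_store(lapply(1:3, raw_rec), annotations = list(
    ann_args("NCT00000001", repurposing = TRUE, pub = "paper",
             ref = "doi:x", use_case = "asthma"),
    ann_args("NCT00000002", repurposing = FALSE, pub = "paper", ref = "doi:y"),
    ann_args("NCT00000003", repurposing = FALSE)))
  tbl <- publication_crosstab(store)
  expect_equal(nrow(tbl), 1L)
  expect_identical(tbl$overall_status, "Completed")
  expect_identical(tbl$publication_status, "paper")
  expect_equal(tbl$value, 1L)
  # no repurposing trials -> empty
  store2 <- tiny_store(list(raw_rec(1)),
                       annotations = list(ann_args("NCT00000001")))
  expect_equal(nrow(publication_crosstab(store2)), 0L)
})

test_that("triage_funnel stages follow the filtering definitions", {
  store <- tiny_store(lapply(1:4, raw_rec), annotations = list(
    ann_args("NCT00000001", use_case = "asthma", repurposing = TRUE,
             pub = "paper", ref = "doi:z"),
    ann_args("NCT00000002", use_case = "alopecia", repurposing = TRUE),
    ann_args("NCT00000003", use_case = "bioequivalence"),
    ann_args("NCT00000004", use_case = "allergic rhinitis")))
  tbl <- triage_funnel(store)
  expect_identical(tbl$stage,
                   c("total", "classic_use_case", "classic_use_case_other",
                     "repurposing", "repurposing_published"))
  expect_equal(tbl$value, c(4L, 1L, 1L, 2L, 1L))
  # the bracketed taste label maps into the classic bucket
  store2 <- tiny_store(list(raw_rec(1)), annotations = list(
    ann_args("NCT00000001", use_case = "Taste [form and preference]")))
  expect_equal(triage_funnel(store2)$value, c(1L, 1L, 0L, 0L, 0L))
  # all repurposing -> classic buckets zero
  store3 <- tiny_store(lapply(1:2, raw_rec), annotations = lapply(1:2,
    function(i) ann_args(sprintf("NCT%08d", i), use_case = "asthma",
                         repurposing = TRUE)))
  expect_equal(triage_funnel(store3)$value, c(2L, 0L, 0L, 2L, 0L))
})

seeded_store <- function(n = 150, seed = 23) {
  cfg <- fixture_config(n_records = n, seed = seed)
  gen <- generate_snapshot(cfg)
  store <- trial_store(cfg$drug_terms)
  upsert_records(store, process_snapshot(gen$snapshot))
  apply_annotations(store, generate_annotations(gen$snapshot, cfg))
  list(store = store, truth = gen$truth)
}

test_that("ratio tables sum to 1 per drug (property)", {
  store <- seeded_store()$store
  for (tbl in list(status_distribution(store), age_group_distribution(store),
                   sex_distribution(store))) {
    sums <- tapply(tbl$value, tbl$primary_drug, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("count tables agree with a brute-force loop oracle (property)", {
  store <- seeded_store()$store
  pairs <- store_pairs(store)
  want <- brute_count(pairs, function(p)
    list(p$ann$use_case, p$ann$primary_drug, p$ann$repurposing),
    c("use_case", "primary_drug", "repurposing"))
  want$repurposing <- as.logical(want$repurposing)
  expect_table_equal(usecase_table(store), want,
                     by = c("use_case", "primary_drug", "repurposing"))

  pairs_all <- store_pairs(store, include_all_roles = TRUE)
  want_roles <- brute_count(pairs_all, function(p)
    list(p$ann$primary_drug, p$ann$drug_role),
    c("primary_drug", "drug_role"))
  expect_table_equal(counts_by_drug_and_role(store), want_roles)
})

test_that("country value never exceeds the number of trials", {
  store <- seeded_store()$store
  tbl <- country_counts(store)
  expect_true(all(tbl$value <= nrow(store$records)))
})

test_that("identical stores export byte-identical CSVs (determinism)", {
  s1 <- seeded_store(); s2 <- seeded_store()
  for (name in c("roles", "funnel", "countries", "status", "lag")) {
    p1 <- withr::local_tempfile(fileext = ".csv")
    p2 <- withr::local_tempfile(fileext = ".csv")
    export_table(run_table(s1$store, name), p1)
    export_table(run_table(s2$store, name), p2)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("run_table rejects unknown table names", {
  expect_error(run_table(trial_store(), "nope"),
               class = "trialscape_validation_error")
})
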