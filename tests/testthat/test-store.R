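test_that("upsert_records is an idempotent upsert keyed on nct_id", {
  store <- tiny_store(lapply(1:3, raw_rec))
  before <- copy(store$records)
  upsert_records(store, before)                    # identical second upsert
  expect_equal(nrow(store$records), 3L)
  expect_identical(sort(store$records$nct_id), sort(before$nct_id))
  # replacing one record updates in place
  snap <- tiny_snapshot(list(raw_rec(1, OverallStatus = "Terminated")))
  upsert_records(store, process_snapshot(snap)$records)
  expect_equal(nrow(store$records), 3L)
  expect_identical(get_record(store, "NCT00000001")$overall_status,
                   "Terminated")
})

test_that("get_record raises a not-found error for unknown IDs", {
  store <- tiny_store(list(raw_rec(1)))
  expect_error(get_record(store, "NCT99999999"),
               class = "trialscape_not_found_error")
})

test_that("store cardinality matches the generator count", {
  gen <- generate_snapshot(fixture_config(n_records = 137, seed = 8,
                                          p_invalid = 0))
  store <- trial_store()
  upsert_records(store, process_snapshot(gen$snapshot))
  expect_equal(nrow(store$records), 137L)
})

test_that("set_annotation stores, replaces and validates", {
  store <- tiny_store(list(raw_rec(1)))
  set_annotation(store, annotation(
    "NCT00000001", "Cetirizine", use_case = "asthma", drug_role = "main",
    repurposing = TRUE, publication_status = "none"))
  expect_equal(nrow(store$annotations), 1L)
  expect_true(store$annotations$repurposing)
  # replacement, not accumulation
  set_annotation(store, annotation(
    "NCT00000001", "Loratadine", use_case = "urticaria", drug_role = "control",
    repurposing = FALSE))
  expect_equal(nrow(store$annotations), 1L)
  expect_identical(store$annotations$drug_role, "control")

  # paper without a reference violates the invariant
  expect_error(set_annotation(store, annotation(
    "NCT00000001", "Cetirizine", use_case = "asthma", drug_role = "main",
    repurposing = TRUE, publication_status = "paper")),
    "publication_ref", class = "trialscape_validation_error")
  # not_included may leave primary_drug blank
  expect_silent(set_annotation(store, annotation(
    "NCT00000001", "", use_case = "false positive", drug_role = "not_included",
    repurposing = FALSE)))
  # otherwise primary_drug must be a configured term
  expect_error(set_annotation(store, annotation(
    "NCT00000001", "Aspirin", use_case = "pain", drug_role = "main",
    repurposing = FALSE)),
    "configured drug terms", class = "trialscape_validation_error")
  # primary must not recur among additional drugs
  expect_error(set_annotation(store, annotation(
    "NCT00000001", "Cetirizine", additional_drugs = c("cetirizine"),
    use_case = "asthma", drug_role = "main", repurposing = FALSE)),
    class = "trialscape_validation_error")
  # unknown trial
  expect_error(set_annotation(store, annotation(
    "NCT99999999", "Cetirizine", use_case = "asthma", drug_role = "main",
    repurposing = FALSE)),
    class = "trialscape_not_found_error")
})

test_that("drug-role labels normalize from messy CSV spellings", {
  expect_identical(normalize_drug_role("Main "), "main")
  expect_identical(normalize_drug_role("Not included"), "not_included")
  expect_identical(normalize_drug_role("rescue-medication"), "rescue_medication")
  expect_error(normalize_drug_role("protagonist"),
               class = "trialscape_validation_error")
})

test_that("annotation CSV round-trip is lossless including optional fields", {
  store <- tiny_store(lapply(1:3, raw_rec), annotations = list(
    ann_args("NCT00000001", role = "main", repurposing = TRUE, pub = "paper",
             ref = "https://doi.org/10.1000/x", use_case = "asthma",
             additional_drugs = c("Loratadine", "Fexofenadine"),
             legacy_search_term = "cetirizine", notes = "note, with comma"),
    ann_args("NCT00000002", role = "control"),
    ann_args("NCT00000003", drug = "", role = "not_included",
             use_case = "false positive")))
  path <- withr::local_tempfile(fileext = ".csv")
  export_annotations_csv(store, path)
  expect_identical(names(read.csv(path, check.names = FALSE)),
                   trialscape:::annotation_csv_header())

  store2 <- tiny_store(lapply(1:3, raw_rec))
  import_annotations_csv(store2, path)
  setorder(store$annotations, nct_id); setorder(store2$annotations, nct_id)
  expect_equal(store2$annotations, store$annotations, ignore_attr = TRUE)
})

test_that("annotation import normalizes roles and is all-or-nothing", {
  store <- tiny_store(lapply(1:2, raw_rec))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(trialscape:::annotation_csv_header(), collapse = ","),
    'NCT00000001,Cetirizine,,,urticaria,Main ,false,none,,',
    'NCT00000002,Cetirizine,,,urticaria,main,false,paper,,'), path)
  # row 2 invalid (paper without ref): zero rows committed, row named
  expect_error(import_annotations_csv(store, path), "row 2",
               class = "trialscape_validation_error")
  expect_equal(nrow(store$annotations), 0L)

  writeLines(c(
    paste(trialscape:::annotation_csv_header(), collapse = ","),
    'NCT00000001,Cetirizine,,,urticaria,Main ,false,none,,'), path)
  import_annotations_csv(store, path)
  expect_identical(store$annotations$drug_role, "main")
})

test_that("backup dump/restore is a lossless round-trip", {
  gen <- generate_snapshot(fixture_config(n_records = 60, seed = 4))
  store <- trial_store()
  upsert_records(store, process_snapshot(gen$snapshot))
  apply_annotations(store, generate_annotations(gen$snapshot,
                                                fixture_config(n_records = 60,
                                                               seed = 4)))
  path <- withr::local_tempfile(fileext = ".json")
  dump_backup(store, path)
  back <- restore_backup(path)
  expect_equal(back$records, store$records, ignore_attr = TRUE)
  expect_identical(back$conditions, store$conditions)
  expect_identical(back$countries, store$countries)
  expect_equal(back$annotations, store$annotations, ignore_attr = TRUE)
  expect_identical(back$drug_terms, store$drug_terms)

  # empty store round-trips too
  empty <- trial_store()
  dump_backup(empty, path)
  expect_equal(nrow(restore_backup(path)$records), 0L)
})

test_that("restore of a corrupted dump fails without side effects", {
  store <- tiny_store(list(raw_rec(1)))
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{ this is not json", path)
  expect_error(restore_backup(path), class = "trialscape_format_error")
  writeLines('{"format": "something-else"}', path)
  expect_error(restore_backup(path), class = "trialscape_format_error")
  expect_equal(nrow(store$records), 1L)            # original untouched
})

test_that("detect_updates classifies new, updated and removed IDs", {
  snap <- tiny_snapshot(lapply(1:3, raw_rec))
  same <- detect_updates(snap, snap)
  expect_length(same$new_ids, 0); expect_length(same$updated_ids, 0)
  expect_length(same$removed_ids, 0)

  newer <- tiny_snapshot(list(
    raw_rec(1),
    raw_rec(2, LastUpdatePostDate = "August 1, 2023"),   # changed
    raw_rec(3),
    raw_rec(4, nct_id = "NCT00000099")))                 # added
  rep <- detect_updates(snap, newer)
  expect_identical(rep$new_ids, "NCT00000099")
  expect_identical(rep$updated_ids, "NCT00000002")
  expect_length(rep$removed_ids, 0)

  # antisymmetry: swapping arguments swaps new/removed, keeps updated
  swapped <- detect_updates(newer, snap)
  expect_identical(swapped$new_ids, rep$removed_ids)
  expect_identical(swapped$removed_ids, rep$new_ids)
  expect_identical(swapped$updated_ids, rep$updated_ids)
})
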