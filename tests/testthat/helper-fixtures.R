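# Builders for tiny handcrafted records, snapshots and stores, plus the
# brute-force loop oracles the analytics tests are checked against.

raw_rec <- function(rank, nct_id = sprintf("NCT%08d", rank), ...) {
  defaults <- list(
    NCTId = nct_id, OfficialTitle = "An Official Title",
    BriefTitle = "A Title", BriefSummary = "A summary.",
    Conditions = "Urticaria", Gender = "All", MaximumAge = "64 Years",
    MinimumAge = "18 Years", OverallStatus = "Completed",
    StartDate = "March 5, 2010", CompletionDate = "March 5, 2011",
    LastUpdatePostDate = "June 1, 2020", StudyFirstPostDate = "April 2, 2010",
    LocationCountry = "Germany", LocationFacility = "Site 1",
    InterventionName = "Cetirizine")
  override <- list(...)
  for (nm in names(override)) defaults[[nm]] <- override[[nm]]
  trialscape:::new_raw_record(rank, defaults)
}

tiny_snapshot <- function(records, query = "Cetirizine") {
  trialscape:::new_snapshot(records, length(records), query,
                            retrieved_at = "2023-01-02T00:00:00+0000")
}

# A store populated from handcrafted raw records; annotations supplied
# as a list of argument lists forwarded to annotation().
tiny_store <- function(records, annotations = list(),
                       drug_terms = default_drug_terms()) {
  snap <- tiny_snapshot(records)
  store <- trial_store(drug_terms)
  upsert_records(store, process_snapshot(snap))
  for (a in annotations) set_annotation(store, do.call(annotation, a))
  store
}

ann_args <- function(nct_id, drug = "Cetirizine", use_case = "urticaria",
                     role = "main", repurposing = FALSE, pub = "none",
                     ref = NA_character_, ...) {
  c(list(nct_id = nct_id, primary_drug = drug, use_case = use_case,
         drug_role = role, repurposing = repurposing,
         publication_status = pub, publication_ref = ref), list(...))
}

# Summary-table comparison: plain data.frame, sorted by the given
# columns, row names dropped.
sorted_df <- function(x, by = names(x)) {
  df <- as.data.frame(x)
  df <- df[do.call(order, df[by]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

expect_table_equal <- function(got, want, by = attr(got, "group_keys")) {
  expect_equal(sorted_df(got, by), sorted_df(want, by),
               ignore_attr = TRUE, tolerance = 1e-12)
}

# Brute-force oracle: loop over (record, annotation) pairs read from
# the store one by one, no grouped operations.
store_pairs <- function(store, include_all_roles = FALSE) {
  pairs <- list()
  for (i in seq_len(nrow(store$records))) {
    rec <- store$records[i]
    hit <- NULL
    for (j in seq_len(nrow(store$annotations))) {
      if (store$annotations$nct_id[j] == rec$nct_id) hit <- store$annotations[j]
    }
    if (is.null(hit)) next
    if (!include_all_roles && hit$drug_role %in% excluded_roles()) next
    pairs[[length(pairs) + 1L]] <- list(rec = rec, ann = hit)
  }
  pairs
}

brute_count <- function(pairs, keyfun, keynames) {
  counter <- list()
  for (p in pairs) {
    k <- keyfun(p)
    if (is.null(k)) next
    id <- paste(vapply(k, as.character, character(1)), collapse = "\x1f")
    if (is.null(counter[[id]])) counter[[id]] <- list(key = k, n = 0L)
    counter[[id]]$n <- counter[[id]]$n + 1L
  }
  rows <- lapply(counter, function(e) {
    row <- as.data.frame(setNames(e$key, keynames), stringsAsFactors = FALSE)
    row$value <- e$n
    row
  })
  if (length(rows) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(keynames)),
                                  keynames))
    out$value <- integer(0)
    return(out)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
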