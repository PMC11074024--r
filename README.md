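# trialscape

Landscape analytics for drug-repurposing triage on clinical-trial
registry metadata.

## The problem

Second-generation H1-receptor antagonists (cetirizine, levocetirizine,
fexofenadine, loratadine, desloratadine) are cheap, safe and
well-studied — prime candidates for repurposing toward indications
outside allergy. The registry at clinicaltrials.gov is the natural
starting point for asking *which* new indications are actually being
trialled, but its records are messy: scalar fields arrive wrapped in
one-element arrays, ages come as `"11 Years"` or `"6 Months"` strings,
dates sometimes omit the day, a trial lists one location row per site,
and a search term can match a person's name instead of a drug (the
trade name *Allegra* is also a given name). Separating a true
repurposing signal from this noise takes a reproducible ETL pipeline
plus manual curation.

`trialscape` packages that pipeline for R:

1. **ingest** — build the OR-combined search expression, page through
   the classic `study_fields` JSON endpoint in rank windows of at most
   1000 records (or read a saved snapshot file — the offline default),
   validate NCT IDs (`NCT` + 8 digits), deduplicate.
2. **normalize** — flatten singleton arrays; normalize ages to decimal
   years (months ÷ 12, weeks ÷ 52, days ÷ 365); normalize dates to
   `YYYY-MM-DD` with the day defaulting to the 1st; map the sex
   vocabulary; assign sequential integer IDs (1, 2, 3, …) to distinct
   conditions and countries in first-occurrence order.
3. **curation store** — a single source of truth for records and
   curator annotations: primary drug, free-text use case, one of eight
   drug roles (combination, comparison, control, main, minimal,
   not included, premedication, rescue medication), a repurposing
   flag, and publication status (paper / registry results / none).
   Annotations round-trip through a CSV; the whole store round-trips
   through a single-file JSON backup; two snapshots can be diffed for
   new / updated / removed trials.
4. **analytics** — the landscape tables: per-drug role counts,
   start-year and first-posted timelines, registration lag
   (mean of `first_posted_year − start_year` over trials whose years
   differ, per posted year), status / age-group / sex distributions as
   per-drug ratios, once-per-study country counts, the publication-bias
   cross-tab over repurposing trials, and the triage funnel
   (total → classic use vs. repurposing → published). All tables except
   the role overview exclude trials whose role is minimal,
   not included, or rescue medication.
5. **synthetic fixtures** — a seeded generator of registry-dialect
   snapshots with known ground truth (every record draws from its own
   `(seed, rank)` stream), so the entire pipeline is testable with no
   network access.

## Worked example

```r
library(trialscape)

cfg <- fixture_config(n_records = 300, seed = 42)   # synthetic registry
gen <- generate_snapshot(cfg)

store <- trial_store(cfg$drug_terms)
upsert_records(store, process_snapshot(gen$snapshot))
apply_annotations(store, generate_annotations(gen$snapshot, cfg))

triage_funnel(store)
#>                     stage value
#> 1:                  total   233
#> 2:       classic_use_case    93
#> 3: classic_use_case_other   102
#> 4:            repurposing    38
#> 5:  repurposing_published     6
```

Of the 300 generated records, 6 are planted-invalid (skipped at
processing) and 61 carry an excluded drug role, leaving 233 relevant
trials; 93 of the rest study a classic pharmacology question
(bioequivalence / bioavailability / pharmacokinetics / taste), 102
another classic indication, 38 point toward repurposing, and results
were published as a paper for 6 of those. The same store yields the
other tables, e.g. once-per-study country counts:

```r
head(country_counts(store), 3)
#>          country value
#> 1: United States    85
#> 2:        Canada    48
#> 3:       Germany    31
```

and the registration-lag series:

```r
registration_lag(store)[first_posted_year %in% 2008:2010]
#>    first_posted_year n_differing mean_lag
#> 1:              2008           6 3.333333
#> 2:              2009           4 4.750000
#> 3:              2010           9 2.222222
```

Every table equals the generator's planted ground truth exactly — that
recovery property is what the test suite asserts.

## Command line

```sh
Rscript inst/cli/trialscape.R simulate --seed 5 --n 300 --out snap.json --csv ann.csv
Rscript inst/cli/trialscape.R process  --snapshot snap.json --store store.json
Rscript inst/cli/trialscape.R annotate-import --store store.json --csv ann.csv
Rscript inst/cli/trialscape.R analyze  --store store.json --table funnel --out funnel.csv
Rscript inst/cli/trialscape.R check-updates --old snap.json --snapshot snap2.json --out diff.json
```

`download` reads a saved snapshot by default; network access requires
the explicit `--live` flag.

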