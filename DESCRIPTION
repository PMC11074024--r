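Package: trialscape
Title: Registry Landscape Analytics for Drug Repurposing Triage
Version: 0.1.0
Authors@R:
    person("Trialscape", "Maintainers", email = "maintainers@trialscape.invalid",
           role = c("aut", "cre"))
Description: Semi-automated pipeline for landscape analysis of clinical-trial
    registry metadata in support of drug-repurposing triage. Harvests study
    records from the classic clinicaltrials.gov 'study_fields' JSON endpoint
    (or saved snapshot files), normalizes the registry's messy fields (ages in
    years/months strings, dates with missing day components, singleton values
    wrapped in lists), manages manual curation annotations (drug role, use
    case, repurposing flag, publication status) via a CSV round-trip, and
    computes the full battery of landscape tables: per-drug role counts,
    start-year and first-posted timelines, registration lag, status, age-group
    and sex distributions, country aggregation, publication-bias cross-tabs,
    and the repurposing triage funnel. Includes a seeded synthetic-snapshot
    generator with ground-truth composition so every stage is testable
    offline.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
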