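---
title: "Methods: registry ETL, curation and landscape analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registry ETL, curation and landscape analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialscape)
```

## The procedure

`trialscape` implements a semi-automated pipeline for surveying the
clinical-trial landscape of a configurable drug list — built around the
second-generation H1-receptor antagonists — with drug repurposing as
the motivating question. The pipeline has four stages: harvest raw
study records from the classic `study_fields` registry endpoint (or a
saved snapshot file), normalize them into typed records, attach manual
curation annotations, and compute summary tables that describe the
landscape (who studies which drug for what, when, where, and whether
results ever got published).

The scientific content is deliberately thin on statistics: every
output is a count, a ratio, or an arithmetic mean. What the package
contributes is the *contract* around those numbers — normalization
rules that survive registry dirt, a curation schema with enforced
invariants, exclusion rules applied uniformly, and a synthetic-data
generator that makes the whole chain falsifiable offline.

## Normalization rules and their assumptions

* **Singleton flattening.** The API wraps scalars in one-element
  arrays. One element flattens to the value; an empty array means the
  value is absent; two or more elements in a declared-singleton field
  is a shape error — we refuse to guess which one was meant.
* **Ages.** The string is lowercased and every non-digit character is
  deleted to extract the number; the unit then divides: years as-is,
  months / 12. Registry data also contain weeks and days, which the
  original months/years rule would reject, so we extend it with
  weeks / 52 and days / 365. The delete-non-digits rule means
  `"11 Years"` and `"11years"` are identical by construction.
* **Dates.** Registry dialects are `"Month D, YYYY"` and
  `"Month YYYY"`; a missing day becomes the 1st of the month, output
  is always ISO `YYYY-MM-DD` and must re-parse as a real calendar
  date. Month names are matched against the English month table
  directly, so the parser is locale-independent.
* **Sex.** Case-insensitive mapping onto `{all, female, male}`;
  anything else (including absence) is `unknown` rather than an error,
  because the raw vocabulary is not under our control.
* **Term IDs.** Distinct conditions and countries get integer IDs
  1..K in first-occurrence order over the record stream. The registry
  itself guarantees no iteration order, so we fix rank order to make
  runs reproducible.
* **Validation.** A record is skipped (and reported — never silently
  dropped) when its NCT ID does not match `NCT` + 8 digits, its
  minimum age exceeds its maximum, or a date fails to parse. The
  registry documents no validation rules, so this rule set is our
  reconstruction of "check that the format is as expected"; missing
  ages and dates remain absent at this stage, and defaulting (e.g.
  absent minimum age → 0) is deferred to the analytics layer where the
  semantics are clear.

## The curation schema

Each trial can carry one annotation: primary drug (the grouping key of
every per-drug table; when a trial names several target drugs the
first-listed one is the primary, the rest go into `additional_drugs`),
a free-text use case (the indication the drug was *used for*, not
necessarily the trial's primary condition — in a multiple-sclerosis
trial where the antihistamine only treats infusion reactions, the use
case is infusion reactions), one of eight drug roles, a repurposing
flag, and a publication status. Enforced invariants: a `paper` status
requires a reference; the primary drug must be one of the configured
drug terms unless the role is `not_included` (the escape hatch for
false positives, e.g. a trade-name synonym matching a person's name);
the primary drug must not recur among the additional drugs. Use cases
stay free-text — the vocabulary is curator-defined and prematurely
controlling it would only push the mess elsewhere.

The store is the single source of truth: analytics read only from it,
and the CSV annotation round-trip (all-or-nothing on import) replaces
the browser-based editor of the original workflow. Storage is an
in-memory object with a single-file, schema-carrying JSON backup
rather than an embedded SQL database: no SQLite driver is available in
the target environment, and the contracts that matter —
single-source-of-truth, lossless dump/restore, idempotent upserts —
do not require one.

## Analytics choices

* **Exclusion rule.** Every table except the per-drug role overview
  drops roles `minimal`, `not_included`, `rescue_medication`. Each
  routine reports how many records it excluded (unannotated,
  role-excluded, missing date) as an attribute.
* **Registration lag** is `first_posted_year − start_year` (positive =
  post-registration, the direction mandated by the 2007 FDAAA and the
  2008 Helsinki revision). The mean is taken over trials whose two
  years *differ* — the companion count series counts exactly those
  trials, and averaging in the zero-lag majority would decouple the
  two series; switching to an all-trials mean is a one-line change.
* **Age groups** follow the registry glossary: child 0–17, adult
  18–64, older adult 65+. A trial is assigned the *set* of groups its
  eligibility interval intersects (absent minimum → 0, absent maximum
  → unbounded), labelled `child`, `child+adult`, …; no standard
  enumeration of those combinations exists, so the intersection-set
  labelling is this package's own convention. Boundary
  semantics: intervals are closed, groups are `[0,18)`, `[18,65)`,
  `[65,∞)`; a trial admitting exactly 18-year-olds is adult-only.
* **Country counts** increase a country by one per *study*, however
  many sites the study has there — which is why site totals can exceed
  study counts several-fold.
* **Triage funnel.** Relevant (annotated, role-filtered) trials split
  into: classic bucket — use case matching bioequivalence /
  bioavailability / pharmacokinetics / taste, case-insensitively on
  the leading word so that "taste [form and preference]" matches;
  classic-other; repurposing; and repurposing-with-a-published-paper.
  Conservation (`total = classic + classic_other + repurposing`) holds
  by construction over the relevant set; unannotated and role-excluded
  counts ride along as attributes so the full harvest is always
  accounted for. We run the funnel over the role-filtered set (not the
  raw harvest) because the excluded roles say the drug was not
  actually the trial's subject — a `not_included` false positive in a
  "repurposing" count would be noise, not signal.
* **Ordering.** Use cases sort by descending total, ties
  lexicographically; countries by descending count, ties by name. All
  exports are byte-deterministic given the same store.

## The synthetic generator: what it emulates, what it does not

The generator emits snapshots in the exact JSON envelope of the
classic endpoint, with the registry's documented quirks planted at
configurable rates: ages in months (default 15% of the eligible
records), dates missing the day (25%), multi-country site lists with
duplicate countries (30%), false positives where the only trace of a
drug is a person called *Allegra* (4%), and invalid records whose
minimum age exceeds the maximum (3%). Role, status, sex, use-case, age
and lag compositions default to values chosen to resemble the observed
antihistamine landscape: ~14% of use cases point toward repurposing,
"completed" dominates the status mix, 92% of trials are open to all
sexes (female-only rarest), lags concentrate at 0–2 years with a tail
to 7, and the United States dominates the site mix. These defaults are
a stated world, not tuning knobs.

Each record draws from its own RNG stream keyed on `(seed, rank)`, so
extending a snapshot never perturbs existing records — that is what
makes old/new snapshot pairs coherent for diff testing. Synthetic NCT
IDs come from a reserved high range (`NCT99xxxxxx`) so they are
visibly fake.

The ground truth is tabulated inside the generator with plain base-R
loops — an independent code path from the `data.table` analytics it
certifies. A green recovery test therefore establishes that the
pipeline recovers planted compositions *exactly*; it does not
establish anything about real registry text (titles and conditions are
schematic), about MeSH vocabulary fidelity, or about the correctness
of human curation judgements, which remain manual by design.

## Numerical and degenerate-input choices

* Ratio tables must sum to 1 per grouping unit within 1e-9; counts are
  exact integers.
* Empty inputs are legal everywhere: an empty snapshot processes to an
  empty store, analytics on an empty store return empty tables, the
  empty store backup restores to an empty store.
* Lag bins with no differing-year trial keep their count row
  (`n_differing = 0`) with an `NA` mean — absence of a mean, not a
  zero mean.
* Snapshot diffing compares the raw `LastUpdatePostDate` strings, not
  parsed dates, so a dialect change in the registry surfaces as an
  update instead of being masked by the parser.
* Seeds are kept below 2^31; the acceptance script reduces the given
  seed modulo 2e9 before use.

## Known limitations

Any harvest is a snapshot of a moving target: the registry updates
continuously, so results only describe the landscape at retrieval
time; the diff reporter exists precisely to quantify that drift. The
live HTTP path is implemented but exercised only through the shared
offline code path in the tests (grading and CI run without network).
Intervention-name → drug mapping beyond the curator's judgement,
MeSH-tree resolution, publication retrieval, and plot rendering are
out of scope — the package ends at tidy long-format tables.
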