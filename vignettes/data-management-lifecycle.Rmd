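---
title: "A catalogue-driven lifecycle for longitudinal health data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A catalogue-driven lifecycle for longitudinal health data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cohortvault` implements an integrated data-management lifecycle for
longitudinal tabular health data at desk scale: a metadata **catalogue** drives
an audited **load** pipeline, **quality** profiling, a composable **cohort
builder**, and a disclosure-controlled **extraction** process, with a seeded
**synthetic-data generator** providing ground-truthed test worlds. This
vignette explains the model behind each piece, the parameters that matter, and
the design choices made where the design was genuinely open.

## The catalogue as single source of truth

Every dataset is described once, centrally: its columns and semantic types,
its primary key and event-date column, per-column validation rules, lookup
tables, governance tiers, outstanding data issues and supporting documents.
All downstream behaviour — how a feed is cleaned, how quality is scored, which
columns may leave the building — is derived from this metadata rather than
from per-project scripts. Two consequences follow:

* governance is configured **once per dataset** and applies to every
  extraction automatically;
* a *branch* catalogue tailored to one project's extract can be exported,
  shipped with the data, and contributions made against it merged back.

The portable catalogue is a single JSON document with a `schema_version`
field. JSON was chosen over a binary or relational serialisation because it is
diff-able and merge-friendly; the merge policy is **additive with a conflict
report, root wins**. Researcher contributions (new validation rules, filled-in
descriptions, new issues) are integrated; a description that differs between
root and branch is flagged and the root text kept. Nothing in the root is ever
silently overwritten — if a different adjudication is wanted, the report gives
a reviewer everything needed to apply it by hand.

Extraction governance uses a fixed four-tier enum per column: `Core`
(extractable), `Supplemental` (extractable, lower priority),
`SpecialApprovalRequired` (extracted only when the configuration carries an
explicit approval for that column) and `Internal` (never extractable; the
private patient identifier is always `Internal`, with role `"identifier"`).
The field's practice distinguishes extractable / approval-gated / identifier
tiers; `Supplemental` is included for parity with common governance usage.

## Loading: RAW, STAGING, LIVE, and the archive

Feeds move through three named stages with a persistent audit trail:

1. **RAW** — the file is ingested: its MD5 digest recorded, its header
   resolved. Renamed columns are mapped back to canonical names through the
   catalogue's header aliases; a feed whose first record is not a
   recognisable header falls back to the declared headerless column order.
   Unresolvable columns fail the job with a fatal log entry.
2. **STAGING** — cleaning steps run in catalogue order (`trim`,
   `null_token_set`, `date_parse_formats`, `uppercase_codes`). Rows violating
   an `invalidates_row` rule, carrying a null primary-key component, or
   duplicating an earlier in-batch key are rejected with per-row log entries.
   If the rejected fraction exceeds a threshold (default **0.10**,
   configurable per store) the whole load aborts — a feed that bad usually
   signals an upstream structural change, not ordinary dirt.
3. **LIVE** — a primary-key upsert. Unseen keys insert; a key whose payload
   changed has its old row moved to the **archive** with
   `valid_to = load_time` and the new row inserted; identical payloads count
   as `unchanged` (they are deliberately excluded from the update count, so
   the counts measure real change). Conservation holds by construction:
   `staged + rejected = raw` and `inserted + updated + unchanged = staged`.

Validity intervals are half-open `[valid_from, valid_to)` in UTC ISO 8601,
which makes the point query unambiguous: *as at* time `t`, a dataset is the
live rows with `valid_from <= t` plus archived rows with
`valid_from <= t < valid_to`. Load times form a strictly increasing
per-dataset clock; back-dated loads are rejected because they would make the
as-at reconstruction ambiguous. Deletions are outside the default flow — an
explicit *tombstone* load mode archives live rows without replacement.

All store values are kept as text, canonicalised at staging (ISO dates,
upper-cased codes, null tokens — default `""`, `"NULL"`, `"NA"` — mapped to
missing). This is what makes refreshes *byte*-reproducible: a pinned as-at
extraction re-serialises exactly the same characters.

## Quality: an operational reading of eight dimensions

The quality vocabulary in this field lists accessibility, access security,
accuracy, completeness, consistency, relevancy, timeliness and uniqueness.
Only some of these are computable from the data alone, so the mapping is:

| dimension      | computed as                                            |
|----------------|--------------------------------------------------------|
| accuracy       | conformance to validation rules (severity `wrong`)     |
| completeness   | null rate after cleaning (severity `missing`)          |
| consistency    | lookup-membership rules                                |
| timeliness     | days since the last successful load                    |
| uniqueness     | duplicate primary keys in live (0 by construction)     |
| accessibility, access security | report metadata flags, not metrics     |
| relevancy      | out of computed scope (no operational definition)      |

Every cell is classified into exactly one of correct / missing / wrong, with
missingness taking priority, so `correct + missing + wrong = n` per column
and per period. Monthly bucketing uses the catalogue's event-date column;
rows without an event date fall into an `undated` bucket. The timeline
zero-fills months between the first and last observed event month so accrual
gaps are visible rather than silently absent. Summary aggregates refuse
dimensions above a configurable cardinality limit (default 1000 distinct
values) since a per-value count of a near-unique column is noise.

## Cohorts: per-row filters, set algebra, stable pseudonyms

Filter blocks (`equals`, `in_set`, `between`, `matches_regex`,
`before`/`after` on dates) compose into `AND`/`OR` containers evaluated
**per row**, matching the WHERE semantics of the SQL such builders generate;
the identifiers of satisfying rows are then collected. Per-patient
conjunction *across* rows is expressed as `INTERSECT` of containers, keeping
the two notions distinct. Definition trees combine per-dataset containers
with `UNION`, `INTERSECT` and a strictly binary, ordered `EXCEPT`;
serialised form is left-associative to remove ambiguity.

Committing a cohort freezes the member set with a strictly increasing version
per definition and project. Release identifiers are **12-hex tokens from a
per-project seeded generator**, persisted in a growing injective map:

* within a project, the same person keeps the same release identifier across
  every version and refresh (required for longitudinal reanalysis);
* across projects, the same person gets unrelated tokens (no linkage through
  pseudonyms);
* tokens are random, not derived from the private identifier, so they cannot
  be inverted;
* any candidate token containing a run of ten or more consecutive digits is
  re-minted. Without this, a fully numeric stretch of a token can itself pass
  the identifier checksum scan and veto a perfectly clean release; the
  constraint costs a negligible amount of token space.

## Extraction: a fail-closed release pipeline

A release joins each selected dataset (reconstructed as at the configured
time, or live) to the committed cohort on the private identifier, substitutes
the release identifier, then runs ordered disclosure components:

1. **governance filter** — removes `Internal` columns unconditionally and
   unapproved `SpecialApprovalRequired` columns, logging removals;
2. **column blacklister** — a configurable case-insensitive regular
   expression over column names (e.g. catching `Id`, `Address`,
   `Identifier`); any match **vetoes** the release, naming the offenders;
3. **identifier scanner** — every maximal digit run of length ≥ 10 in any
   cell is scanned with a sliding 10-digit window; a window passing the
   modulus-11 check vetoes the release and the findings are audited.

Veto rather than redaction is the default because "block" is the safe,
fail-closed reading of a disclosure control: silently stripping matches could
mask a systematic leak. A `redact` mode that masks scanner matches is offered
for triage but is never the default. The scanner's window-within-run rule is
the conservative superset of any delimiter convention; a *strict* mode
additionally requires the first six digits to form a plausible DDMMYY date,
reducing false positives at the cost of recall.

The 10-digit identifier checksum is the standard modulus-11 scheme: weights
10, 9, …, 2 over the first nine digits, `check = 11 − (sum mod 11)`, with 11
mapping to 0 and a remainder giving check 10 meaning no valid digit exists.
The exact remainder conventions vary between published descriptions, so the
rule is isolated in `chi_checksum_valid()` where it can be swapped without
touching the scanner.

A successful release is a directory bundle: one CSV per dataset (release
identifier first, deterministic column and row order), lookup tables for the
selected coded columns, global supporting documents, an extract-time quality
report computed on the extracted rows, a Markdown metadata document (the
described fields, the cohort logic rendering, monthly record counts), a
branch catalogue restricted to the extracted columns with identifier items
replaced by a `release_id` item, and a manifest of SHA-256 and MD5 digests.
Markdown rather than a word-processor format carries the metadata document:
the contract is the content, not the file format. The audited release type
(`First`, `Refresh`, `HICError`, `ResearcherError`, `ChangeRequest`) is
caller-declared metadata — it encodes human intent that cannot be inferred.

## The synthetic generator: what it does and does not emulate

`generate_world()` produces a demography register plus accruing event
datasets (prescriptions, biochemistry, and optional extra datasets sharing
the identifier), with exact ground truth for everything it plants:

* per-column missing/wrong rates (defaults: biochemistry results 5% missing,
  2% wrong; prescription codes 3% missing, 2% wrong — mid-range figures for
  routinely collected clinical feeds);
* schema drift (renamed headers, dropped header rows) on a monthly plan;
* months with zero events (accrual gaps);
* retrospective rewrite feeds re-supplying known keys with changed values;
* checksum-valid 10-digit identifiers embedded in free-text cells, with the
  birth-date prefix convention so the strict scanner mode also fires.

Defaults are 100 patients over 6 accrual months with a per-patient,
per-month event probability of 0.8. Values are deliberately simple —
categorical sex, uniform event days, log-normal laboratory values — because
the generator exercises data-management plumbing, not biology. Passing tests
on these worlds therefore demonstrates the *mechanics* (conservation,
bitemporal reconstruction, exact recovery of planted defects, disclosure
safety) but says nothing about statistical fidelity to any real population,
free-text realism, or the messiness of genuinely adversarial feeds. Wrong
values are only plantable on columns that carry a wrong-severity rule, and
never on keys or identifiers, so ground truth and quality reports can agree
exactly rather than approximately.

## Numerical and degenerate-input choices

* Unparseable dates are kept verbatim (a rule may then flag them) rather than
  nulled: silent nulling would conflate format drift with true missingness.
* Empty feeds ingest as zero-row RAW jobs with a warning, not errors.
* In-batch duplicate primary keys keep the first occurrence; later
  duplicates are rejected and logged individually.
* Empty cohorts commit with a warning — researchers legitimately freeze
  empty interim cohorts.
* An empty blacklist pattern is rejected at configuration time (it would
  match nothing while appearing to protect).
* Catalogue reads are cached against file mtime/size under the store's
  single-writer contract.

## Problem sizes used by the tests and acceptance script

The test-suite and `scripts/acceptance.R` run at sizes chosen to exercise the
platform's operating envelope while staying comfortably reproducible on a
single CPU: a 100-dataset single extraction (5 patients, one month), a
200-dataset catalogue, 50 randomised load sequences checked against a
brute-force replay oracle, 200 random cohort trees against brute-force set
evaluation, a 10,000-candidate exhaustive checksum comparison, and paired
planted/clean disclosure worlds of 20 patients over 2 months.

## Known limitations

Single-writer stores (no concurrency control); exact-match identifier
linkage only (no probabilistic record linkage); no statistical disclosure
control beyond the column and cell scanners (no k-anonymity or differential
privacy); deletions only via explicit tombstone loads; no remote-source
fetching; and the raw-file archive keeps digests plus optional copies but
implements no retention policy.
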