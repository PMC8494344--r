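---
title: "Processing field-sampling and isolation data with sampleflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing field-sampling and isolation data with sampleflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sampleflow` processes the data trail of a substrate-based ecological
survey: barcoded collections made in the field with a mobile
data-collection app, specimens isolated from those collections in the
laboratory, and species identifications entered into a genotyping sheet
after molecular-barcode sequencing. This vignette explains the procedures
the package implements, the parameters that control them, and the design
choices behind them.

## The data model

Five CSV files are exported per project, named
`<prefix>_field_sampling.csv`, `<prefix>_field_sampling_sample_photo.csv`,
`<prefix>_isolation.csv`, `<prefix>_isolation_s_labeled_plates.csv`, and
`<prefix>_isolation_photos.csv`. A field-sampling row is one collection
event, keyed by a C-label scanned from the collection bag, with
environmental readings (ambient and substrate temperature, humidity,
altitude) and the GPS fix taken when the record was created. Photo rows
carry a second GPS fix from the device camera plus a precision estimate in
meters (`exif_gps_dop`; smaller is better). Isolation rows link back to
collections through the platform's unique alphanumeric record identifiers,
and each isolated specimen occupies one S-labeled plate row. All raw cells
are read verbatim as text (UTF-8, RFC 4180, empty string = missing);
processing adds typed `*_proc` columns and boolean `flag_*` columns and
never rewrites a raw value. The three isolation files are optional as a
trio — a project that never reached the isolation stage is still valid — but
a partial trio is refused rather than silently dropping laboratory data.

## Temperature handling

Probes are sometimes left in Fahrenheit mode. Any reading strictly above
`fahrenheit_threshold` (default 40, in raw degrees) is converted to Celsius
as `(x − 32) × 5⁄9` and flagged. The boundary value stays: a true 40 °C
substrate is hot but possible, while 40 °F ≈ 4.4 °C is a plausible cold
morning, so only values above the threshold are unambiguous. Because the
rule is a heuristic, every conversion is surfaced by
`check_temperatures()` with its original value, and `fix_temperatures()`
can revert it (restoring the raw value exactly) or blank a reading that is
simply wrong. Repairs are programmatic-only and append to an audit table —
flags never vanish silently.

`check_temperatures()` also reports runs of at least `run_length_min`
(default 3) identical consecutive readings per series. "Consecutive" is
defined over collections ordered by collection date, then time, then record
id; ordering is otherwise unstated in the export, and this choice makes
reruns deterministic. Runs are detected globally over the project rather
than per device or per day, the simpler reading of "sequential
collections"; with identical-value matching a cross-day false positive
requires the same 0.1-degree reading three times in a row, which is exactly
the situation worth reviewing anyway. The default of 3 balances sensitivity
against the real possibility of two genuinely equal consecutive readings.

Extreme-value screens are deliberately wide and configurable: ambient and
substrate ranges default to [−10, 50] °C and altitude to [−100, 5500] m.
These are plausibility bounds for temperate-to-tropical fieldwork, not
statistical outlier rules; out-of-range values are flagged, never removed,
because field data must survive to review. Altitude has no unit heuristic —
a foot/meter confusion cannot be distinguished numerically in the common
elevation range — so it is range-flagged only.

## Labels

C- and S-labels are normalized by trimming and upper-casing, then validated
against configurable grammars (defaults `^C-[0-9]+$`, `^S-[0-9]+$`,
inferred from the printed label style `C-3205`). Normalization-only
deviations (`" c-3205 "`) are repaired without a flag; structural ones
(`C3205`) are flagged misformatted. Duplicate flags are computed
project-wide after normalization and mark every member of a duplicate
group, since any member might be the wrong one.

## Joining

`join_fulcrum()` builds the long table in a fixed order: collections to
isolations on record identifiers; best-photo selection; location
resolution; S-label expansion; project-wide flags. The result has one row
per S-label, and exactly one row for any collection without specimens —
including collections with an isolation record but no S-labels, which keep
their row with a null S-label so no collection is lost. The best photo is
the one with the smallest GPS precision estimate; a missing estimate sorts
as infinitely imprecise, and ties break on lexicographic photo record id
(the export does not define an order, and determinism matters more than
which of two equally precise fixes wins). Photo GPS is preferred over
record GPS for the final location because records are often created away
from the site; `location_source` records which was used, and is `"none"`
only when both fixes are absent. Orphan isolations — referencing a
collection id absent from the field data — are retained and flagged, since
deleting laboratory data on a referential hiccup is worse than reviewing
it; duplicated collection record ids, by contrast, violate the platform's
uniqueness contract and abort the join.

## Geographic annotation

`annotate_fulcrum()` matches each resolved location against user-supplied
GeoJSON polygons. Containment is even–odd ray casting, implemented directly
(the primitive is small enough that owning it beats a geometry-stack
dependency) with three decisions: boundary points count as inside, so a
sample on a trail edge annotates to the trail; hole rings exclude their
interior but their boundary still counts; and antimeridian-crossing
polygons are unsupported — a documented limitation irrelevant to
island-scale features. The first containing feature in file order becomes
`location`, mirroring first-hit overlay behavior, while `locations_all`
keeps every match for overlapping features. The implementation is tested
against an independent winding-number oracle on random polygons (10⁴
point–polygon pairs in the acceptance suite) and cross-checked against
`sp::point.in.polygon`.

## Genotypes

The genotyping sheet is ingested from a local CSV/TSV export with either
the general schema (`project_id`, `s_label`, `species_id`,
`possible_new_sp`, `strain_name`) or the nematode schema adding
proliferation and ITS2/SSU genotype columns. A `1` in `possible_new_sp`
means the alignment suggests a new species; blank parses as `FALSE`.
`check_genotypes()` is report-only: sheet-internal label and completeness
flags (the "improper S-label" criterion reuses the S-label grammar) plus
the two set differences between sheet and field S-labels.
`join_geno_fulc()` is a left join preserving row count; a duplicated sheet
key deterministically takes its first occurrence and flags the rows. The
processed table persists as CSV plus a JSON sidecar of column types — a
portable substitute for binary serialization.

## Photos and the report

`proc_photos()` copies each collection's best photo byte-for-byte under its
C-label name and writes an aspect-preserving thumbnail (longest side ≤ 300
px by default — small enough for report popups, large enough to recognize a
substrate). Duplicate C-labels get `_2`, `_3` suffixes rather than
overwriting. Only the best photo per collection is processed, since the
report needs one image per pin.

`generate_report()` assembles a single self-contained HTML file from text
templates: metadata, summary tables, a pin map, and per-species Tukey box
plots of ambient temperature, substrate temperature, humidity, and
elevation. Pins are colored by the specimen-presence category (red =
present, blue = absent, orange = tracks only, grey = unknown). The map and
plots are inline SVG on an equirectangular lon/lat canvas with no external
tiles, which keeps the artifact offline-renderable and — with
`deterministic = TRUE`, which derives the timestamp from the table rather
than the clock — byte-identical across runs, a property the test suite
relies on. Tukey hinges are computed by the median-of-halves convention
(each half includes the overall median when the count is odd); whiskers
reach the most extreme points within 1.5 × IQR of the hinges. An editable
R Markdown template is also written to `scripts/` as a starting point for
custom write-ups.

## The synthetic-project generator

`fixture_spec()` + `generate_project()` produce a complete project from a
single seed: plausible Hawaiian-island coordinates (the default bounding
region boxes Kauai), ambient temperatures U(16, 30) °C and substrate
U(10, 35) °C at 0.1° resolution, humidity U(40, 95) %, altitude
U(5, 1200) m, photo precision lognormal(log 5, 0.5) m, an isolation for 85%
of collections and 0–3 S-labels per isolation. Injected anomalies are drawn
so recovery is exact by construction: Fahrenheit values from U(60, 110) are
always above the threshold; stuck runs are placed on consecutive
collections with their neighbors nudged if they happen to match, keeping
each injected run maximal; label anomalies use disjoint record sets. The
returned manifest lists every injected defect and predicts every expected
flag, which is what the flag-recovery tests compare against at
precision/recall 1.0.

What the generator does *not* emulate: ecological covariance between
environmental variables, GPS error structure beyond white jitter, EXIF
metadata inside the JPEGs (photo GPS travels in the photo CSV, so stub
solid-color JPEGs suffice), handwriting-style label typos beyond the
dash-dropped pattern, or multi-device clock skew. Passing tests therefore
demonstrate the mechanics of flagging, joining, and reporting — not that
the default screens are well-calibrated for any particular climate or
taxon; users should expect to tune `processing_config()` ranges to their
region.

## Problem sizes and numerical notes

The test suite exercises projects of 3–50 collections and property checks
of 10⁴ containment pairs and 10³ box-plot samples — sizes at which every
oracle can be brute-forced while covering all code paths; the pipeline
itself is linear in rows and handles realistically larger projects without
adjustment. Degenerate inputs are defined: empty photo sets yield no best
photo rather than an error; an all-missing series is an error for box-plot
statistics but a silent no-op for run detection; a zero-located project
produces a report with a map placeholder. Temperature equality in run
detection is exact string-formatted equality (readings are probe-quantized,
so epsilon comparison would only mask distinct values), and the
revert-after-conversion round trip is exact to floating-point
(tested at 1e−9).

## The workflow entry point

`run_workflow()` chains read → process → join → annotate → genotype →
photos → report over a project directory, logging per-stage flag counts.
Its interface is deliberately R-level — the package's users already work in
R, so the thirteen exported operations (`workflow_functions()`) plus this
driver are the command surface, configured by arguments rather than a shell
CLI. Anomalies never abort a run: the point of the pipeline is to carry
flagged data to a human review, so only referential-integrity violations
are fatal. Requesting a stage without its prerequisite (for example
`report` without `join`) raises an ordering error naming the missing stage.
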