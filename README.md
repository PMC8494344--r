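# sampleflow

Ecological surveys of organisms too small to identify in the field — wild
nematodes are the motivating case — work by collecting barcoded substrate
samples in nature, isolating specimens from those samples in the laboratory,
and identifying the isolates later with molecular barcodes. Each step
produces its own records: field-sampling events keyed by a **C-label**
(collection label), laboratory isolations with per-specimen **S-labels**,
photo files with GPS metadata, and a genotyping sheet mapping S-labels to
species names. `sampleflow` is an R toolkit for turning the CSV exports of a
mobile geographic data-collection platform plus that genotyping sheet into
one clean, flagged, georeferenced long table and a browsable HTML report.

For field teams and their data managers, the package:

- creates and reads a fixed project directory layout
  (`data/raw/fulcrum`, `data/processed/fulcrum`, `reports`, ...);
- standardizes dates, times, labels, and coordinates, and converts
  temperature readings above a threshold (default **40**, strictly greater)
  from Fahrenheit to Celsius as `(x − 32) × 5⁄9`, flagging every conversion
  for review, revert, or removal with a full audit trail;
- flags stuck temperature probes (runs of ≥ 3 identical consecutive
  readings over the time-ordered collections), extreme temperatures and
  altitudes, and duplicated / missing / misformatted labels;
- joins collections to isolations and S-labels (one row per specimen, one
  row per specimen-free collection), picking the photo with the smallest
  GPS precision estimate (`exif_gps_dop`, meters) per collection and
  preferring its GPS fix over the record-time fix;
- annotates each located collection with the user's GeoJSON polygon
  features (islands, trails, parks) via boundary-inclusive even–odd
  ray-casting containment;
- joins species identifications from the genotyping sheet, renames and
  thumbnails photos by C-label, and renders a self-contained HTML report
  with a colored pin map and per-species Tukey box plots of the
  environmental parameters.

A seeded synthetic-project generator (`fixture_spec()` /
`generate_project()`) emits complete example projects — five CSVs, stub
JPEGs, genotyping sheet, GeoJSON — plus a ground-truth manifest of every
injected anomaly, so the whole pipeline is testable offline.

## Worked example

```r
library(sampleflow)

root <- file.path(tempdir(), "readme")
layout <- make_directory_structure(root)

spec <- fixture_spec(n_collections = 30, seed = 17,
                     fahrenheit_rate = 0.1,
                     stuck_run_spec = list(n_runs = 1, length = 3))
manifest <- generate_project(spec, layout)

bundle    <- read_fulcrum(layout)
processed <- proc_fulcrum(bundle)
check_temperatures(processed)
#> <temperature_report>
#> Fahrenheit-to-Celsius conversions (review and revert if wrong):
#>                        fulcrum_id c_label                 field raw_value converted_value
#>  97dc997c9a3fb2a893ddd01b9893c688  C-0105 substrate_temperature      72.9        22.72222
#> Identical consecutive readings (possible stuck probe):
#>                  field run                       fulcrum_id c_label value
#>  substrate_temperature   1 223f081267904a02e4c4ebb44078c86e  C-0120  31.7
#>  substrate_temperature   1 e815c2866a86b63c826c89517c225288  C-0121  31.7
#>  substrate_temperature   1 4c40ea43cebc17150c75c363dbd1bcb3  C-0122  31.7
```

One substrate reading of 72.9 was treated as Fahrenheit and converted to
22.7 °C (review it; `fix_temperatures()` reverts it if it really was
Celsius), and collections C-0120..C-0122 recorded the identical 31.7 °C
three times in a row — a probable stuck probe.

```r
joined <- join_fulcrum(processed)
check_join(joined)
#> <join_report> 6 flag(s) in 2 categories:
#>                             flag    source_file n                 labels
#>  substrate_temperature_converted field_sampling 1                 C-0105
#>        substrate_temperature_run field_sampling 5 C-0120; C-0121; C-0122

annotated <- annotate_fulcrum(joined, read_features(attr(manifest, "features_path")))
genos <- read_genotypes(attr(manifest, "sheet_path"), "general")
final <- join_geno_fulc(genos, annotated, layout)
final <- proc_photos(final, layout)
summarize_collections(final)
#> <collection_summary>
#>   collections: 30 | with photos: 30 | isolations: 25 | S-labels: 29
#>   species: Caenorhabditis briggsae = 5, Caenorhabditis elegans = 7,
#>            Caenorhabditis tropicalis = 4, Oscheius tipulae = 10 (+3 un-genotyped)
#>   flags: substrate_temperature_converted = 1, substrate_temperature_run = 5

generate_report(final, layout, deterministic = TRUE)
# -> <root>/reports/collection_report.html
```

The run-flag count of 5 in `check_join()` is at row (specimen) level: the
three flagged collections expand to five S-label rows. `run_workflow(root,
sheet = ...)` chains the same stages in one call.

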