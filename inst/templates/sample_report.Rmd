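---
title: "Collection project report"
output: html_document
params:
  final_table: "data/processed/fulcrum/joined_collections.csv"
---

This is an editable template for a project summary. The canonical,
self-contained HTML report is produced by `sampleflow::generate_report()`;
use this document as a starting point for a customized write-up.

```{r setup, include = FALSE}
knitr::opts_chunk$set(echo = FALSE)
library(sampleflow)
library(dplyr)
final <- readr::read_csv(params$final_table, show_col_types = FALSE)
```

## Summary

```{r summary}
# Rebuild the joined-collection class so summary helpers apply.
class(final) <- c("final_table", "joined_collection", class(final))
summarize_collections(final)
```

## Collections

```{r collections}
final %>%
  distinct(collection_id, .keep_all = TRUE) %>%
  select(c_label, collection_date, latitude, longitude, location_source) %>%
  head(20)
```

## Specimens

```{r specimens}
final %>%
  filter(!is.na(s_label)) %>%
  select(s_label, c_label, any_of("species_id")) %>%
  head(20)
```
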