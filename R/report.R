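#' Summarize a collection project
#'
#' Counts are computed over distinct keys: collections by collection record
#' id, isolations by isolation record id, specimens by S-label. Per-species
#' S-label counts partition the genotyped specimens, with the remainder
#' reported as un-genotyped.
#'
#' @param final A `final_table` (a plain `joined_collection` also works;
#'   species counts are then empty).
#' @return A list of class `collection_summary` with `n_collections`,
#'   `n_with_photos`, `n_isolations`, `n_s_labels`, `species_counts` (named
#'   integer vector), `n_ungenotyped`, `date_range`, and `flag_counts`.
#' @export
summarize_collections <- function(final) {
  has_species <- "species_id" %in% names(final)
  colls <- final %>% distinct(.data$collection_id, .keep_all = TRUE)
  specimens <- final %>%
    filter(!is.na(.data$s_label)) %>%
    distinct(.data$s_label, .keep_all = TRUE)

  species_counts <- if (has_species && nrow(specimens) > 0) {
    tab <- table(specimens$species_id[!is.na(specimens$species_id)])
    setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }

  flag_cols <- grep("^flag_", names(final), value = TRUE)
  flag_counts <- vapply(
    final[flag_cols],
    function(col) sum(dplyr::coalesce(col, FALSE)),
    integer(1)
  )

  structure(
    list(
      n_collections = nrow(colls),
      n_with_photos = sum(!is.na(colls$best_photo_id)),
      n_isolations = dplyr::n_distinct(final$isolation_id, na.rm = TRUE),
      n_s_labels = nrow(specimens),
      species_counts = species_counts,
      n_ungenotyped = nrow(specimens) - sum(species_counts),
      date_range = if (all(is.na(colls$collection_date))) c(NA, NA) else
        range(colls$collection_date, na.rm = TRUE),
      flag_counts = flag_counts[flag_counts > 0]
    ),
    class = "collection_summary"
  )
}

#' @export
print.collection_summary <- function(x, ...) {
  cat("<collection_summary>\n")
  cat("  collections:", x$n_collections,
      "| with photos:", x$n_with_photos,
      "| isolations:", x$n_isolations,
      "| S-labels:", x$n_s_labels, "\n")
  if (length(x$species_counts) > 0) {
    cat("  species:",
        paste(names(x$species_counts), x$species_counts,
              sep = " = ", collapse = ", "),
        sprintf("(+%d un-genotyped)", x$n_ungenotyped), "\n")
  }
  if (length(x$flag_counts) > 0) {
    cat("  flags:",
        paste(sub("^flag_", "", names(x$flag_counts)), x$flag_counts,
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tukey box-plot statistics
#'
#' Five-number box-plot statistics using Tukey's hinge convention: the
#' hinges are the medians of the lower and upper halves of the sorted data
#' (each half including the overall median when the count is odd). Whiskers
#' extend to the most extreme observations within 1.5 interquartile ranges
#' of the hinges; everything beyond is returned as outliers.
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @return A list with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`, and `n`.
#' @examples
#' tukey_boxplot_stats(1:9)
#' tukey_boxplot_stats(c(1, 2, 3, 4, 100))
#' @export
tukey_boxplot_stats <- function(values) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (n == 0) {
    abort("No non-missing values to summarize.", class = "sampleflow_empty_stats")
  }
  med <- median(x)
  half <- ceiling(n / 2)             # halves share the middle point when odd
  q1 <- median(x[seq_len(half)])
  q3 <- median(x[seq(n - half + 1, n)])
  iqr <- q3 - q1
  lo_fence <- q1 - 1.5 * iqr
  hi_fence <- q3 + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  list(
    median = med, q1 = q1, q3 = q3,
    whisker_lo = min(inside), whisker_hi = max(inside),
    outliers = x[x < lo_fence | x > hi_fence],
    n = n
  )
}

# Map pin colors by specimen-presence category (report legend).
sampleflow_pin_colors <- c(
  present = "#d73027", absent = "#4575b4", tracks_only = "#fdae61",
  unknown = "#999999"
)

# The four environmental parameters shown as per-species box plots.
sampleflow_env_params <- c(
  ambient_temperature = "Ambient temperature (°C)",
  substrate_temperature = "Substrate temperature (°C)",
  ambient_humidity = "Ambient humidity (%)",
  altitude = "Elevation (m)"
)

#' Generate the HTML collection report
#'
#' Writes a single self-contained HTML file to the project's `reports`
#' directory containing: a metadata section (who collected and when, taken
#' from the table, never the clock when `deterministic = TRUE`), summary
#' tables, a pin map of every collection with a resolved location (pins
#' colored red for specimens present, blue for absent, orange for tracks
#' only, grey for unknown, each with a popup title listing the C-label and
#' any species), and per-species Tukey box plots of ambient temperature,
#' substrate temperature, ambient humidity, and elevation. The map and the
#' plots are inline SVG, so the report opens in any browser with no network
#' access and, under `deterministic = TRUE`, is byte-identical across runs
#' on the same table. An editable report template is also copied into the
#' project's `scripts` directory.
#'
#' @param final A `final_table` (or annotated `joined_collection`).
#' @param layout The [project_layout()].
#' @param deterministic When `TRUE`, the generation timestamp is derived
#'   from the latest collection date in the table instead of the clock.
#' @return The path to the written HTML file, invisibly.
#' @export
generate_report <- function(final, layout, deterministic = FALSE) {
  stopifnot(inherits(layout, "project_layout"))
  if (!dir.exists(layout$reports)) dir.create(layout$reports, recursive = TRUE)
  if (!dir.exists(layout$scripts)) dir.create(layout$scripts, recursive = TRUE)

  template_src <- system.file("templates", "sample_report.Rmd",
                              package = "sampleflow")
  if (nzchar(template_src)) {
    file.copy(template_src, file.path(layout$scripts, "sample_report.Rmd"),
              overwrite = TRUE)
  }

  summary <- summarize_collections(final)
  generated_at <- if (deterministic) {
    if (all(is.na(summary$date_range))) "unknown date" else
      paste("project dates", summary$date_range[1], "to", summary$date_range[2])
  } else {
    format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  }

  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>Collection report</title>\n",
    "<style>body{font-family:sans-serif;margin:2em;}",
    "table{border-collapse:collapse;}td,th{border:1px solid #ccc;",
    "padding:4px 8px;text-align:left;}h2{margin-top:1.5em;}",
    ".legend span{margin-right:1.2em;}</style>\n</head>\n<body>\n",
    "<h1>Collection report</h1>\n",
    "<p>Generated: ", generated_at, "</p>\n",
    report_metadata_section(final, summary),
    report_summary_section(summary),
    report_map_section(final),
    report_boxplot_section(final),
    "</body>\n</html>\n"
  )

  path <- file.path(layout$reports, "collection_report.html")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df) {
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  body <- apply(df, 1, function(row) {
    paste0("<tr>", paste0("<td>", html_escape(ifelse(is.na(row), "", row)),
                          "</td>", collapse = ""), "</tr>")
  })
  paste0("<table>\n", head, "\n", paste(body, collapse = "\n"), "\n</table>\n")
}

report_metadata_section <- function(final, summary) {
  collectors <- if ("collection_by" %in% names(final)) {
    sort(unique(final$collection_by[!is.na(final$collection_by)]))
  } else {
    character(0)
  }
  paste0(
    "<h2>Project metadata</h2>\n<ul>\n",
    "<li>Collection dates: ",
    if (all(is.na(summary$date_range))) "unknown" else
      paste(summary$date_range[1], "to", summary$date_range[2]),
    "</li>\n",
    if (length(collectors) > 0) {
      paste0("<li>Collected by: ",
             html_escape(paste(collectors, collapse = ", ")), "</li>\n")
    } else "",
    "</ul>\n"
  )
}

report_summary_section <- function(summary) {
  counts <- tibble(
    quantity = c("Collections", "Collections with photos", "Isolations",
                 "S-labels (specimens)", "Un-genotyped S-labels"),
    count = c(summary$n_collections, summary$n_with_photos,
              summary$n_isolations, summary$n_s_labels, summary$n_ungenotyped)
  )
  species <- if (length(summary$species_counts) > 0) {
    html_table(tibble(
      species = names(summary$species_counts),
      `S-labels` = summary$species_counts
    ))
  } else {
    "<p>No species identifications available.</p>\n"
  }
  flags <- if (length(summary$flag_counts) > 0) {
    html_table(tibble(
      flag = sub("^flag_", "", names(summary$flag_counts)),
      rows = summary$flag_counts
    ))
  } else {
    "<p>No anomalies flagged.</p>\n"
  }
  paste0(
    "<h2>Summary</h2>\n", html_table(counts),
    "<h3>Specimens by species</h3>\n", species,
    "<h3>Flagged anomalies</h3>\n", flags
  )
}

report_map_section <- function(final) {
  pins <- final %>%
    distinct(.data$collection_id, .keep_all = TRUE) %>%
    filter(.data$location_source != "none")
  if (nrow(pins) == 0) {
    return(paste0(
      "<h2>Collection map</h2>\n",
      "<p class=\"map-placeholder\">No collections with a resolved GPS ",
      "location; map omitted.</p>\n"
    ))
  }
  species_by_coll <- final %>%
    filter(!is.na(.data$s_label)) %>%
    group_by(.data$collection_id) %>%
    summarise(species = paste(sort(unique(stats::na.omit(
      if ("species_id" %in% names(final)) .data$species_id else character(0)
    ))), collapse = ", "))
  pins <- pins %>% left_join(species_by_coll, by = "collection_id")

  lon_rng <- grow_range(range(pins$longitude))
  lat_rng <- grow_range(range(pins$latitude))
  w <- 720; h <- 480
  px <- function(lon) (lon - lon_rng[1]) / diff(lon_rng) * (w - 40) + 20
  py <- function(lat) h - ((lat - lat_rng[1]) / diff(lat_rng) * (h - 40) + 20)

  circles <- purrr::pmap_chr(
    list(pins$longitude, pins$latitude, pins$c_label, pins$worms_on_sample,
         dplyr::coalesce(pins$species, "")),
    function(lon, lat, c_label, cat, species) {
      col <- sampleflow_pin_colors[[cat]]
      title <- paste0(
        if (is.na(c_label)) "(no C-label)" else c_label,
        if (nzchar(species)) paste0(" | ", species) else "",
        sprintf(" | %.5f, %.5f", lat, lon)
      )
      sprintf(
        paste0('<circle class="map-pin" cx="%.1f" cy="%.1f" r="6" ',
               'fill="%s" stroke="#333" data-category="%s" ',
               'data-c-label="%s"><title>%s</title></circle>'),
        px(lon), py(lat), col, cat,
        html_escape(ifelse(is.na(c_label), "", c_label)), html_escape(title)
      )
    }
  )
  legend <- paste0(
    "<p class=\"legend\">",
    "<span style=\"color:#d73027\">● specimens present</span>",
    "<span style=\"color:#4575b4\">● none found</span>",
    "<span style=\"color:#fdae61\">● tracks only</span>",
    "<span style=\"color:#999999\">● unknown</span></p>\n"
  )
  popups <- report_pin_popups(pins)
  paste0(
    "<h2>Collection map</h2>\n", legend,
    "<p>Offline schematic map (equirectangular lon/lat scatter); ",
    "coordinates are WGS84 decimal degrees.</p>\n",
    sprintf("<svg class=\"pin-map\" width=\"%d\" height=\"%d\" ", w, h),
    "style=\"background:#eef3ee;border:1px solid #ccc\">\n",
    paste(circles, collapse = "\n"), "\n</svg>\n", popups
  )
}

report_pin_popups <- function(pins) {
  items <- purrr::pmap_chr(
    list(pins$c_label, pins$worms_on_sample, pins$latitude, pins$longitude,
         dplyr::coalesce(pins$species, ""),
         if ("thumbnail_path" %in% names(pins)) pins$thumbnail_path else
           rep(NA_character_, nrow(pins))),
    function(c_label, cat, lat, lon, species, thumb) {
      paste0(
        "<li><b>", html_escape(ifelse(is.na(c_label), "(no C-label)", c_label)),
        "</b> — ", cat,
        sprintf(" (%.5f, %.5f)", lat, lon),
        if (nzchar(species)) paste0("; species: ", html_escape(species)) else "",
        if (!is.na(thumb)) paste0(
          " <img src=\"", html_escape(thumb), "\" height=\"60\" alt=\"",
          html_escape(ifelse(is.na(c_label), "photo", c_label)), "\"/>"
        ) else "",
        "</li>"
      )
    }
  )
  paste0("<h3>Collections</h3>\n<ul class=\"pin-popups\">\n",
         paste(items, collapse = "\n"), "\n</ul>\n")
}

grow_range <- function(r, frac = 0.05) {
  if (diff(r) == 0) r + c(-0.001, 0.001) else r + diff(r) * frac * c(-1, 1)
}

report_boxplot_section <- function(final) {
  if (!"species_id" %in% names(final) ||
      all(is.na(final$species_id))) {
    return(paste0(
      "<h2>Environmental parameters by species</h2>\n",
      "<p class=\"no-species\">No species identifications available; ",
      "box plots omitted.</p>\n"
    ))
  }
  specimens <- final %>%
    filter(!is.na(.data$s_label), !is.na(.data$species_id)) %>%
    distinct(.data$s_label, .keep_all = TRUE)
  sections <- purrr::imap_chr(sampleflow_env_params, function(label, param) {
    groups <- specimens %>%
      filter(!is.na(.data[[param]])) %>%
      group_by(.data$species_id) %>%
      summarise(stats = list(tukey_boxplot_stats(.data[[param]])))
    if (nrow(groups) == 0) {
      return(paste0("<h3>", html_escape(label),
                    "</h3>\n<p>No data recorded.</p>\n"))
    }
    paste0("<h3>", html_escape(label), "</h3>\n",
           svg_boxplots(groups$species_id, groups$stats))
  })
  paste0("<h2>Environmental parameters by species</h2>\n",
         paste(sections, collapse = "\n"))
}

# Horizontal Tukey box plots, one row per species, drawn as inline SVG.
svg_boxplots <- function(species, stats_list) {
  vals <- unlist(lapply(stats_list, function(s)
    c(s$whisker_lo, s$whisker_hi, s$outliers, s$median)))
  rng <- grow_range(range(vals))
  w <- 640; row_h <- 46; pad_l <- 180
  h <- length(species) * row_h + 30
  sx <- function(v) (v - rng[1]) / diff(rng) * (w - pad_l - 30) + pad_l
  rows <- purrr::imap_chr(stats_list, function(s, i) {
    cy <- (i - 1) * row_h + 30
    out_pts <- paste(vapply(s$outliers, function(v) {
      sprintf('<circle cx="%.1f" cy="%d" r="3" fill="none" stroke="#444"/>',
              sx(v), cy)
    }, character(1)), collapse = "")
    paste0(
      sprintf('<text x="8" y="%d" font-size="12">%s (n=%d)</text>',
              cy + 4, html_escape(species[i]), s$n),
      sprintf('<line x1="%.1f" y1="%d" x2="%.1f" y2="%d" stroke="#444"/>',
              sx(s$whisker_lo), cy, sx(s$q1), cy),
      sprintf('<line x1="%.1f" y1="%d" x2="%.1f" y2="%d" stroke="#444"/>',
              sx(s$q3), cy, sx(s$whisker_hi), cy),
      sprintf(paste0('<rect class="boxplot-box" x="%.1f" y="%d" ',
                     'width="%.1f" height="24" fill="#a6cee3" stroke="#333"/>'),
              sx(s$q1), cy - 12, max(sx(s$q3) - sx(s$q1), 0.5)),
      sprintf('<line x1="%.1f" y1="%d" x2="%.1f" y2="%d" stroke="#111" stroke-width="2"/>',
              sx(s$median), cy - 12, sx(s$median), cy + 12),
      out_pts
    )
  })
  axis <- sprintf(
    paste0('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="#999"/>',
           '<text x="%d" y="%d" font-size="11">%.3g</text>',
           '<text x="%d" y="%d" font-size="11" text-anchor="end">%.3g</text>'),
    pad_l, h - 12, w - 30, h - 12,
    pad_l, h - 1, rng[1], w - 30, h - 1, rng[2]
  )
  paste0(sprintf('<svg width="%d" height="%d">', w, h), "\n",
         paste(rows, collapse = "\n"), "\n", axis, "\n</svg>\n")
}
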