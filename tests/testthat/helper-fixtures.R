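# Shared fixtures and independent oracles for the test suite.

# Generate a synthetic project in a self-cleaning temp dir.
local_project <- function(..., env = parent.frame()) {
  root <- withr::local_tempdir(.local_envir = env)
  layout <- make_directory_structure(root)
  spec <- fixture_spec(...)
  manifest <- generate_project(spec, layout)
  list(root = root, layout = layout, spec = spec, manifest = manifest)
}

# Write a hand-crafted project from explicit tables (all-character tibbles).
write_manual_project <- function(layout, field_sampling, sample_photo,
                                 isolation = NULL, plates = NULL,
                                 iso_photos = NULL, prefix = "nematode") {
  p <- function(role) file.path(layout$raw_fulcrum, paste0(prefix, "_", role, ".csv"))
  readr::write_csv(field_sampling, p("field_sampling"), na = "")
  readr::write_csv(sample_photo, p("field_sampling_sample_photo"), na = "")
  if (!is.null(isolation)) {
    readr::write_csv(isolation, p("isolation"), na = "")
    readr::write_csv(plates, p("isolation_s_labeled_plates"), na = "")
    readr::write_csv(iso_photos, p("isolation_photos"), na = "")
  }
  invisible(layout)
}

# Minimal valid field-sampling rows.
manual_fs <- function(n, c_label = sprintf("C-%04d", seq_len(n)),
                      date = rep("2019-07-03", n),
                      time = sprintf("08:%02d:00", seq_len(n) %% 60),
                      substrate = sprintf("%.1f", 20 + seq_len(n) / 10),
                      ambient = sprintf("%.1f", 22 + seq_len(n) / 10),
                      lat = sprintf("%.6f", 22 + seq_len(n) / 1000),
                      lon = sprintf("%.6f", -159.5 + seq_len(n) / 1000)) {
  tibble::tibble(
    fulcrum_id = sprintf("coll%04d", seq_len(n)),
    c_label = c_label, date = date, time = time,
    sample_photo = sprintf("photo%04d", seq_len(n)),
    gridsect = "no",
    substrate_temperature = substrate,
    ambient_temperature_c = ambient,
    ambient_humidity = sprintf("%.1f", 60 + seq_len(n)),
    gps_altitude = sprintf("%.1f", 100 + seq_len(n)),
    latitude = lat, longitude = lon
  )
}

manual_photos <- function(fs, dop = rep("3.0", nrow(fs))) {
  tibble::tibble(
    fulcrum_id = sprintf("phot%04d", seq_len(nrow(fs))),
    fulcrum_parent_id = fs$fulcrum_id,
    sample_photo = fs$sample_photo,
    exif_gps_latitude = fs$latitude,
    exif_gps_longitude = fs$longitude,
    exif_gps_dop = dop
  )
}

# --- independent oracles ---

# Winding-number point-in-polygon (single closed-or-open ring, lon/lat matrix).
winding_number_inside <- function(lon, lat, ring) {
  n <- nrow(ring)
  wn <- 0
  is_left <- function(x0, y0, x1, y1, x, y) {
    (x1 - x0) * (y - y0) - (x - x0) * (y1 - y0)
  }
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    x0 <- ring[i, 1]; y0 <- ring[i, 2]
    x1 <- ring[j, 1]; y1 <- ring[j, 2]
    if (y0 <= lat) {
      if (y1 > lat && is_left(x0, y0, x1, y1, lon, lat) > 0) wn <- wn + 1
    } else {
      if (y1 <= lat && is_left(x0, y0, x1, y1, lon, lat) < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# Random simple (star-shaped) polygon around a centre.
random_polygon <- function(n_vertices = 12, centre = c(0, 0), radius = 1) {
  angles <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, 0.3 * radius, radius)
  cbind(centre[1] + r * cos(angles), centre[2] + r * sin(angles))
}

as_feature <- function(ring, name = "test") {
  list(name = name, polygons = list(list(ring)))
}

# Brute-force maximal-run scan (values in already-ordered sequence).
brute_force_runs <- function(values, k) {
  flagged <- rep(FALSE, length(values))
  i <- 1
  while (i <= length(values)) {
    j <- i
    while (j < length(values) && !is.na(values[j + 1]) && !is.na(values[i]) &&
           values[j + 1] == values[i]) {
      j <- j + 1
    }
    if (!is.na(values[i]) && j - i + 1 >= k) flagged[i:j] <- TRUE
    i <- j + 1
  }
  flagged
}

# Exhaustive Tukey box-plot oracle: hinges from stats::fivenum, outliers by
# direct scan.
oracle_tukey <- function(x) {
  x <- sort(x[!is.na(x)])
  fn <- stats::fivenum(x)
  iqr <- fn[4] - fn[2]
  lo <- fn[2] - 1.5 * iqr
  hi <- fn[4] + 1.5 * iqr
  list(
    median = fn[3], q1 = fn[2], q3 = fn[4],
    whisker_lo = min(x[x >= lo]), whisker_hi = max(x[x <= hi]),
    outliers = x[x < lo | x > hi]
  )
}

# Distinct collection ids carrying a flag in a joined table.
flagged_collections <- function(joined, flag) {
  unique(joined$collection_id[dplyr::coalesce(joined[[flag]], FALSE)])
}
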