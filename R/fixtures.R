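#' Specify a synthetic sampling project
#'
#' Describes a complete synthetic project — the five export CSVs, stub JPEG
#' photos, a genotyping sheet, and GeoJSON annotation polygons — together
#' with the anomalies to inject. Rates are per-candidate-record
#' probabilities; the default project is clean (all anomaly rates zero) so
#' that every downstream flag observed on a generated project is traceable
#' to the ground-truth manifest. A single integer seed determines the output
#' byte-for-byte.
#'
#' @param prefix Export-file prefix (default `"nematode"`).
#' @param n_collections Number of field-sampling records.
#' @param isolation_rate Fraction of collections receiving an isolation
#'   record.
#' @param s_labels_per_isolation Named probability vector over S-label counts
#'   per isolation.
#' @param photos_per_collection Named probability vector over photo counts
#'   per collection.
#' @param fahrenheit_rate Fraction of collections whose ambient or substrate
#'   reading is replaced by a Fahrenheit value drawn from \[60, 110\], so
#'   every injected value is unambiguously above the default conversion
#'   threshold.
#' @param stuck_run_spec `NULL`, or `list(n_runs =, length =)` describing
#'   runs of identical consecutive substrate readings to inject.
#' @param duplicate_c_label_rate,missing_c_label_rate,misformat_c_label_rate
#'   Collection-label anomaly rates.
#' @param missing_s_label_rate,misformat_s_label_rate,duplicate_s_label_rate
#'   Isolation-label anomaly rates (over S-label plate rows).
#' @param missing_photo_rate Fraction of collections with no photo record.
#' @param sheet_anomaly_rates List with `duplicate_s_label`,
#'   `missing_species`, `missing_strain`, and `unknown_s_label` rates for
#'   the genotyping sheet.
#' @param geno_rate Fraction of clean S-labels that receive a sheet row.
#' @param bounding_region `c(lon_min, lat_min, lon_max, lat_max)` for
#'   generated coordinates (default: the island of Kauai).
#' @param dop_meanlog,dop_sdlog Log-normal parameters for the photo GPS
#'   precision estimate in meters.
#' @param include_isolation Write the three isolation CSVs (default `TRUE`;
#'   `FALSE` emulates a field-sampling-only project).
#' @param write_photo_files Write the stub JPEG files (can be disabled when
#'   only the tables are needed).
#' @param schema Genotyping-sheet schema, `"general"` or `"nematode"`.
#' @param seed Integer seed governing all randomness.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(prefix = "nematode",
                         n_collections = 30,
                         isolation_rate = 0.85,
                         s_labels_per_isolation = c("0" = 0.15, "1" = 0.40,
                                                    "2" = 0.30, "3" = 0.15),
                         photos_per_collection = c("1" = 0.6, "2" = 0.3,
                                                   "3" = 0.1),
                         fahrenheit_rate = 0,
                         stuck_run_spec = NULL,
                         duplicate_c_label_rate = 0,
                         missing_c_label_rate = 0,
                         misformat_c_label_rate = 0,
                         missing_s_label_rate = 0,
                         misformat_s_label_rate = 0,
                         duplicate_s_label_rate = 0,
                         missing_photo_rate = 0,
                         sheet_anomaly_rates = list(duplicate_s_label = 0,
                                                    missing_species = 0,
                                                    missing_strain = 0,
                                                    unknown_s_label = 0),
                         geno_rate = 0.9,
                         bounding_region = c(lon_min = -159.80, lat_min = 21.85,
                                             lon_max = -159.28, lat_max = 22.25),
                         dop_meanlog = log(5), dop_sdlog = 0.5,
                         include_isolation = TRUE,
                         write_photo_files = TRUE,
                         schema = c("general", "nematode"),
                         seed = 1L) {
  schema <- match.arg(schema)
  rates <- c(
    isolation_rate = isolation_rate, fahrenheit_rate = fahrenheit_rate,
    duplicate_c_label_rate = duplicate_c_label_rate,
    missing_c_label_rate = missing_c_label_rate,
    misformat_c_label_rate = misformat_c_label_rate,
    missing_s_label_rate = missing_s_label_rate,
    misformat_s_label_rate = misformat_s_label_rate,
    duplicate_s_label_rate = duplicate_s_label_rate,
    missing_photo_rate = missing_photo_rate,
    geno_rate = geno_rate,
    unlist(sheet_anomaly_rates)
  )
  if (any(rates < 0 | rates > 1)) {
    abort(paste0("Rate(s) outside [0, 1]: ",
                 paste(names(rates)[rates < 0 | rates > 1], collapse = ", ")),
          class = "sampleflow_spec_error")
  }
  stopifnot(n_collections >= 1, abs(sum(s_labels_per_isolation) - 1) < 1e-8,
            abs(sum(photos_per_collection) - 1) < 1e-8)
  structure(
    list(
      prefix = prefix, n_collections = as.integer(n_collections),
      isolation_rate = isolation_rate,
      s_labels_per_isolation = s_labels_per_isolation,
      photos_per_collection = photos_per_collection,
      fahrenheit_rate = fahrenheit_rate, stuck_run_spec = stuck_run_spec,
      duplicate_c_label_rate = duplicate_c_label_rate,
      missing_c_label_rate = missing_c_label_rate,
      misformat_c_label_rate = misformat_c_label_rate,
      missing_s_label_rate = missing_s_label_rate,
      misformat_s_label_rate = misformat_s_label_rate,
      duplicate_s_label_rate = duplicate_s_label_rate,
      missing_photo_rate = missing_photo_rate,
      sheet_anomaly_rates = sheet_anomaly_rates, geno_rate = geno_rate,
      bounding_region = bounding_region,
      dop_meanlog = dop_meanlog, dop_sdlog = dop_sdlog,
      include_isolation = include_isolation,
      write_photo_files = write_photo_files,
      schema = schema, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

# 32-hex-character record id in the style of the platform's export ids.
make_record_ids <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(c(0:9, letters[1:6]), 32, replace = TRUE), collapse = "")
  }, character(1))
}

draw_counts <- function(n, probs) {
  as.integer(sample(names(probs), n, replace = TRUE, prob = probs))
}

#' Generate a synthetic project on disk
#'
#' Writes a complete project under `layout` according to `spec`: the export
#' CSVs in `data/raw/fulcrum`, one small valid JPEG per photo record in
#' `data/raw/fulcrum/photos` (stub solid-color images; photo GPS metadata
#' travels in the photo CSV, not in EXIF), a genotyping sheet CSV at the
#' project root, and a GeoJSON file with two nested island/trail polygons in
#' `data/raw/annotate`. Returns the ground-truth anomaly manifest: one row
#' per injected defect with the file, record id, field, injected value, and
#' true value, sufficient to predict every expected downstream flag. The
#' same spec and seed produce byte-identical output.
#'
#' @param spec A [fixture_spec()].
#' @param layout A [project_layout()] whose directories exist (see
#'   [make_directory_structure()]).
#' @return A tibble of class `anomaly_manifest` with attributes
#'   `sheet_path`, `features_path`, and `prefix`.
#' @export
generate_project <- function(spec, layout) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(layout, "project_layout"))
  withr::with_seed(spec$seed, generate_project_impl(spec, layout))
}

generate_project_impl <- function(spec, layout) {
  n <- spec$n_collections
  br <- spec$bounding_region
  manifest <- list()
  note <- function(anomaly, file, record_id, field, injected, truth) {
    manifest[[length(manifest) + 1]] <<- tibble(
      anomaly = anomaly, file = file, record_id = record_id, field = field,
      injected_value = as.character(injected), true_value = as.character(truth)
    )
  }

  # --- field-sampling records, chronologically ordered by construction ---
  ids <- make_record_ids(n)
  start <- as.POSIXct("2019-07-03 07:00:00", tz = "UTC")
  stamps <- sort(start + round(runif(n, 0, 12 * 86400)))
  fs <- tibble(
    fulcrum_id = ids,
    created_by = sample(c("sampler_a@example.org", "sampler_b@example.org"),
                        n, replace = TRUE),
    date = format(stamps, "%Y-%m-%d"),
    time = format(stamps, "%H:%M:%S"),
    c_label = sprintf("C-%04d", seq_len(n) + 100L),
    gridsect = "no",
    substrate_temperature = sprintf("%.1f", runif(n, 10, 35)),
    ambient_temperature_c = sprintf("%.1f", runif(n, 16, 30)),
    ambient_humidity = sprintf("%.1f", runif(n, 40, 95)),
    gps_altitude = sprintf("%.1f", runif(n, 5, 1200)),
    latitude = sprintf("%.6f", runif(n, br["lat_min"], br["lat_max"])),
    longitude = sprintf("%.6f", runif(n, br["lon_min"], br["lon_max"]))
  )
  fs_file <- paste0(spec$prefix, "_field_sampling.csv")

  # stuck-probe runs on consecutive substrate readings
  run_members <- integer(0)
  if (!is.null(spec$stuck_run_spec)) {
    len <- spec$stuck_run_spec$length
    starts_pool <- seq_len(max(0, n - len + 1))
    for (r in seq_len(spec$stuck_run_spec$n_runs)) {
      # keep candidate windows clear of existing run members
      ok <- setdiff(starts_pool, unique(unlist(
        lapply(run_members, function(i) (i - len + 1):(i + len - 1))
      )))
      if (length(ok) == 0) break
      s <- sample(ok, 1)
      members <- s:(s + len - 1)
      run_val <- fs$substrate_temperature[members[1]]
      for (m in members) {
        note("stuck_run", fs_file, fs$fulcrum_id[m], "substrate_temperature",
             run_val, fs$substrate_temperature[m])
        fs$substrate_temperature[m] <- run_val
      }
      run_members <- c(run_members, members)
      # nudge untouched neighbours so the injected run stays maximal
      for (b in c(s - 1, s + len)) {
        if (b >= 1 && b <= n && !b %in% run_members &&
            fs$substrate_temperature[b] == run_val) {
          fs$substrate_temperature[b] <-
            sprintf("%.1f", as.numeric(run_val) + 0.2)
        }
      }
    }
  }

  # Fahrenheit injections, away from run members so runs stay intact
  f_pool <- setdiff(seq_len(n), run_members)
  f_idx <- f_pool[runif(length(f_pool)) < spec$fahrenheit_rate]
  for (i in f_idx) {
    field <- sample(c("ambient_temperature_c", "substrate_temperature"), 1)
    injected <- sprintf("%.1f", runif(1, 60, 110))
    note("fahrenheit", fs_file, fs$fulcrum_id[i], field, injected, fs[[field]][i])
    fs[[field]][i] <- injected
  }

  # label anomalies on disjoint collection sets
  pool <- seq_len(n)
  n_dup_pairs <- floor(spec$duplicate_c_label_rate * n)
  dup_idx <- if (n_dup_pairs > 0 && length(pool) >= 2 * n_dup_pairs) {
    sample(pool, 2 * n_dup_pairs)
  } else integer(0)
  if (length(dup_idx) > 0) {
    for (p in seq_len(n_dup_pairs)) {
      i <- dup_idx[2 * p - 1]; j <- dup_idx[2 * p]
      note("duplicate_c_label", fs_file, fs$fulcrum_id[i], "c_label",
           fs$c_label[i], fs$c_label[i])
      note("duplicate_c_label", fs_file, fs$fulcrum_id[j], "c_label",
           fs$c_label[i], fs$c_label[j])
      fs$c_label[j] <- fs$c_label[i]
    }
    pool <- setdiff(pool, dup_idx)
  }
  miss_idx <- pool[runif(length(pool)) < spec$missing_c_label_rate]
  for (i in miss_idx) {
    note("missing_c_label", fs_file, fs$fulcrum_id[i], "c_label", "",
         fs$c_label[i])
    fs$c_label[i] <- NA_character_
  }
  pool <- setdiff(pool, miss_idx)
  mis_idx <- pool[runif(length(pool)) < spec$misformat_c_label_rate]
  for (i in mis_idx) {
    bad <- sub("-", "", fs$c_label[i], fixed = TRUE)
    note("misformat_c_label", fs_file, fs$fulcrum_id[i], "c_label", bad,
         fs$c_label[i])
    fs$c_label[i] <- bad
  }

  # --- photos ---
  ph_file <- paste0(spec$prefix, "_field_sampling_sample_photo.csv")
  no_photo <- seq_len(n)[runif(n) < spec$missing_photo_rate]
  for (i in no_photo) {
    note("missing_photo", ph_file, fs$fulcrum_id[i], "sample_photo", "",
         "photo record")
  }
  with_photo <- setdiff(seq_len(n), no_photo)
  n_photos <- draw_counts(length(with_photo), spec$photos_per_collection)
  photo_parent <- rep(with_photo, n_photos)
  np <- length(photo_parent)
  photos <- tibble(
    fulcrum_id = make_record_ids(np),
    fulcrum_parent_id = fs$fulcrum_id[photo_parent],
    exif_gps_latitude = sprintf(
      "%.6f", as.numeric(fs$latitude[photo_parent]) + rnorm(np, 0, 1e-4)),
    exif_gps_longitude = sprintf(
      "%.6f", as.numeric(fs$longitude[photo_parent]) + rnorm(np, 0, 1e-4)),
    exif_gps_dop = sprintf("%.1f", rlnorm(np, spec$dop_meanlog, spec$dop_sdlog))
  )
  photos$sample_photo <- photos$fulcrum_id
  photos <- photos[, c("fulcrum_id", "fulcrum_parent_id", "sample_photo",
                       "exif_gps_latitude", "exif_gps_longitude",
                       "exif_gps_dop")]
  fs$sample_photo <- vapply(seq_len(n), function(i) {
    paste(photos$sample_photo[photos$fulcrum_parent_id == fs$fulcrum_id[i]],
          collapse = ",")
  }, character(1))

  readr::write_csv(fs, file.path(layout$raw_fulcrum, fs_file), na = "")
  readr::write_csv(photos, file.path(layout$raw_fulcrum, ph_file), na = "")

  if (spec$write_photo_files) {
    for (k in seq_len(nrow(photos))) {
      write_stub_jpeg(
        file.path(layout$raw_photos, paste0(photos$sample_photo[k], ".jpg")),
        k
      )
    }
  }

  # --- isolation trio ---
  s_counter <- 0L
  all_s_rows <- tibble(fulcrum_id = character(), fulcrum_parent_id = character(),
                       s_label = character())
  clean_s_labels <- character(0)
  if (spec$include_isolation) {
    iso_idx <- seq_len(n)[runif(n) < spec$isolation_rate]
    n_iso <- length(iso_idx)
    k_s <- if (n_iso > 0) draw_counts(n_iso, spec$s_labels_per_isolation) else integer(0)
    iso <- tibble(
      fulcrum_id = make_record_ids(n_iso),
      c_label = fs$fulcrum_id[iso_idx],
      date = fs$date[iso_idx],
      time = fs$time[iso_idx],
      worms_on_sample = ifelse(k_s > 0, "Yes",
                               sample(c("No", "Tracks"), max(n_iso, 1),
                                      replace = TRUE)[seq_len(max(n_iso, 0))]),
      created_by = sample(c("isolator_a@example.org", "isolator_b@example.org"),
                          max(n_iso, 1), replace = TRUE)[seq_len(max(n_iso, 0))]
    )
    sp_file <- paste0(spec$prefix, "_isolation_s_labeled_plates.csv")
    parent <- rep(iso$fulcrum_id, k_s)
    ns <- length(parent)
    s_labels <- sprintf("S-%04d", seq_len(ns) + 500L)
    plates <- tibble(
      fulcrum_id = make_record_ids(ns),
      fulcrum_parent_id = parent,
      s_label = s_labels
    )

    # S-label anomalies on disjoint plate rows
    spool <- seq_len(ns)
    n_sdup <- floor(spec$duplicate_s_label_rate * ns)
    sdup <- if (n_sdup > 0 && length(spool) >= 2 * n_sdup) {
      sample(spool, 2 * n_sdup)
    } else integer(0)
    if (length(sdup) > 0) {
      for (p in seq_len(n_sdup)) {
        i <- sdup[2 * p - 1]; j <- sdup[2 * p]
        note("duplicate_s_label", sp_file, plates$fulcrum_id[i], "s_label",
             plates$s_label[i], plates$s_label[i])
        note("duplicate_s_label", sp_file, plates$fulcrum_id[j], "s_label",
             plates$s_label[i], plates$s_label[j])
        plates$s_label[j] <- plates$s_label[i]
      }
      spool <- setdiff(spool, sdup)
    }
    smiss <- spool[runif(length(spool)) < spec$missing_s_label_rate]
    for (i in smiss) {
      note("missing_s_label", sp_file, plates$fulcrum_id[i], "s_label", "",
           plates$s_label[i])
      plates$s_label[i] <- NA_character_
    }
    spool <- setdiff(spool, smiss)
    smis <- spool[runif(length(spool)) < spec$misformat_s_label_rate]
    for (i in smis) {
      bad <- sub("-", "", plates$s_label[i], fixed = TRUE)
      note("misformat_s_label", sp_file, plates$fulcrum_id[i], "s_label", bad,
           plates$s_label[i])
      plates$s_label[i] <- bad
    }
    clean_s_labels <- plates$s_label[setdiff(seq_len(ns), c(sdup, smiss, smis))]
    all_s_rows <- plates

    iso_photos <- tibble(
      fulcrum_id = make_record_ids(n_iso),
      fulcrum_parent_id = iso$fulcrum_id,
      photos = make_record_ids(n_iso)
    )
    readr::write_csv(iso, file.path(
      layout$raw_fulcrum, paste0(spec$prefix, "_isolation.csv")), na = "")
    readr::write_csv(plates, file.path(layout$raw_fulcrum, sp_file), na = "")
    readr::write_csv(iso_photos, file.path(
      layout$raw_fulcrum, paste0(spec$prefix, "_isolation_photos.csv")), na = "")
  }

  # --- genotyping sheet ---
  sheet_path <- file.path(layout$root,
                          paste0(spec$prefix, "_genotyping_sheet.csv"))
  sheet <- build_genotype_sheet(spec, clean_s_labels, note)
  readr::write_csv(sheet, sheet_path, na = "")

  # --- annotation polygons: an island box and a nested trail box ---
  features_path <- file.path(layout$raw_annotate, "features.geojson")
  write_fixture_features(features_path, br)

  out <- if (length(manifest) > 0) bind_rows(manifest) else tibble(
    anomaly = character(), file = character(), record_id = character(),
    field = character(), injected_value = character(), true_value = character()
  )
  attr(out, "sheet_path") <- sheet_path
  attr(out, "features_path") <- features_path
  attr(out, "prefix") <- spec$prefix
  class(out) <- c("anomaly_manifest", class(tibble()))
  out
}

build_genotype_sheet <- function(spec, clean_s_labels, note) {
  species_pool <- c("Caenorhabditis elegans", "Caenorhabditis briggsae",
                    "Caenorhabditis tropicalis", "Oscheius tipulae")
  rates <- spec$sheet_anomaly_rates
  sheet_file <- paste0(spec$prefix, "_genotyping_sheet.csv")
  pick <- clean_s_labels[runif(length(clean_s_labels)) < spec$geno_rate]
  rows <- tibble(
    project_id = rep(spec$prefix, length(pick)),
    s_label = pick,
    species_id = sample(species_pool, length(pick), replace = TRUE),
    possible_new_sp = ifelse(runif(length(pick)) < 0.05, "1", NA_character_),
    strain_name = sprintf("ECA%04d", seq_along(pick) + 800L)
  )
  if (spec$schema == "nematode" && nrow(rows) > 0) {
    rows$proliferation <- ifelse(runif(nrow(rows)) < 0.8, "1", NA_character_)
    rows$its2_genotype <- rows$species_id
    rows$ssu_genotype <- "Rhabditid"
  }
  if (nrow(rows) > 0) {
    miss_sp <- which(runif(nrow(rows)) < (rates$missing_species %||% 0))
    for (i in miss_sp) {
      note("sheet_missing_species", sheet_file, rows$s_label[i], "species_id",
           "", rows$species_id[i])
      rows$species_id[i] <- NA_character_
    }
    miss_st <- setdiff(which(runif(nrow(rows)) < (rates$missing_strain %||% 0)),
                       miss_sp)
    for (i in miss_st) {
      note("sheet_missing_strain", sheet_file, rows$s_label[i], "strain_name",
           "", rows$strain_name[i])
      rows$strain_name[i] <- NA_character_
    }
    dup <- which(runif(nrow(rows)) < (rates$duplicate_s_label %||% 0))
    for (i in dup) {
      note("sheet_duplicate_s_label", sheet_file, rows$s_label[i], "s_label",
           rows$s_label[i], rows$s_label[i])
    }
    if (length(dup) > 0) rows <- bind_rows(rows, rows[dup, ])
  }
  n_unknown <- floor((rates$unknown_s_label %||% 0) *
                       max(length(clean_s_labels), 1))
  if (n_unknown > 0) {
    unknown <- tibble(
      project_id = rep(spec$prefix, n_unknown),
      s_label = sprintf("S-%04d", seq_len(n_unknown) + 9000L),
      species_id = sample(species_pool, n_unknown, replace = TRUE),
      possible_new_sp = rep(NA_character_, n_unknown),
      strain_name = sprintf("ECA%04d", seq_len(n_unknown) + 9000L)
    )
    if (spec$schema == "nematode") {
      unknown$proliferation <- "1"
      unknown$its2_genotype <- unknown$species_id
      unknown$ssu_genotype <- "Rhabditid"
    }
    for (i in seq_len(n_unknown)) {
      note("sheet_unknown_s_label", sheet_file, unknown$s_label[i], "s_label",
           unknown$s_label[i], "")
    }
    rows <- bind_rows(rows, unknown)
  }
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small solid-color JPEG keyed to an index; a valid JFIF stand-in for a
# real substrate photograph.
write_stub_jpeg <- function(path, index, width = 16, height = 12) {
  rgb <- c((index * 37) %% 256, (index * 59) %% 256, (index * 83) %% 256) / 255
  img <- array(rep(rgb, each = height * width), dim = c(height, width, 3))
  jpeg::writeJPEG(img, path, quality = 0.9)
  invisible(path)
}

# Two nested rectangles: the whole bounding region ("Kauai") and its
# south-west quadrant ("Waimea Canyon Trail").
write_fixture_features <- function(path, br) {
  box_ring <- function(lon0, lat0, lon1, lat1) {
    list(list(lon0, lat0), list(lon1, lat0), list(lon1, lat1),
         list(lon0, lat1), list(lon0, lat0))
  }
  lon_mid <- unname((br["lon_min"] + br["lon_max"]) / 2)
  lat_mid <- unname((br["lat_min"] + br["lat_max"]) / 2)
  fc <- list(
    type = "FeatureCollection",
    features = list(
      list(
        type = "Feature",
        properties = list(name = "Kauai"),
        geometry = list(
          type = "Polygon",
          coordinates = list(box_ring(
            unname(br["lon_min"]) - 0.01, unname(br["lat_min"]) - 0.01,
            unname(br["lon_max"]) + 0.01, unname(br["lat_max"]) + 0.01
          ))
        )
      ),
      list(
        type = "Feature",
        properties = list(name = "Waimea Canyon Trail"),
        geometry = list(
          type = "Polygon",
          coordinates = list(box_ring(
            unname(br["lon_min"]) - 0.005, unname(br["lat_min"]) - 0.005,
            lon_mid, lat_mid
          ))
        )
      )
    )
  )
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
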