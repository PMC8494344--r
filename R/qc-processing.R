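#' Processing configuration
#'
#' Bundles the tunable parameters used during processing, joining, and photo
#' handling.
#'
#' @param fahrenheit_threshold Raw temperature readings strictly above this
#'   value are treated as Fahrenheit and converted to Celsius (default 40).
#'   A reading equal to the threshold is left untouched.
#' @param run_length_min Minimum number of identical consecutive temperature
#'   readings (over collections ordered by date and time) that is flagged as
#'   a possible stuck probe (default 3).
#' @param ambient_temp_range,substrate_temp_range Plausible ranges in degrees
#'   Celsius; processed values outside them raise an extreme-value flag
#'   (defaults `c(-10, 50)`).
#' @param altitude_range Plausible altitude range in meters (default
#'   `c(-100, 5500)`).
#' @param c_label_pattern,s_label_pattern Regular expressions a normalized
#'   (trimmed, upper-cased) label must match; defaults `^C-[0-9]+$` and
#'   `^S-[0-9]+$` matching the printed label style (e.g. `C-3205`).
#' @param thumbnail_max_dim Longest side of generated photo thumbnails, in
#'   pixels (default 300).
#' @return A list of class `processing_config`.
#' @export
processing_config <- function(fahrenheit_threshold = 40,
                              run_length_min = 3,
                              ambient_temp_range = c(-10, 50),
                              substrate_temp_range = c(-10, 50),
                              altitude_range = c(-100, 5500),
                              c_label_pattern = "^C-[0-9]+$",
                              s_label_pattern = "^S-[0-9]+$",
                              thumbnail_max_dim = 300) {
  stopifnot(
    is.numeric(fahrenheit_threshold), length(fahrenheit_threshold) == 1,
    fahrenheit_threshold > 0,
    is.numeric(run_length_min), length(run_length_min) == 1, run_length_min >= 2,
    length(ambient_temp_range) == 2, diff(ambient_temp_range) > 0,
    length(substrate_temp_range) == 2, diff(substrate_temp_range) > 0,
    length(altitude_range) == 2, diff(altitude_range) > 0,
    is.numeric(thumbnail_max_dim), thumbnail_max_dim >= 1
  )
  structure(
    list(
      fahrenheit_threshold = fahrenheit_threshold,
      run_length_min = as.integer(run_length_min),
      ambient_temp_range = ambient_temp_range,
      substrate_temp_range = substrate_temp_range,
      altitude_range = altitude_range,
      c_label_pattern = c_label_pattern,
      s_label_pattern = s_label_pattern,
      thumbnail_max_dim = thumbnail_max_dim
    ),
    class = "processing_config"
  )
}

#' Convert suspected Fahrenheit readings to Celsius
#'
#' Field temperature probes are sometimes left in Fahrenheit mode. Any raw
#' reading strictly above `threshold` is assumed to be Fahrenheit and
#' converted to Celsius as `(value - 32) * 5/9`; readings at or below the
#' threshold, and missing values, pass through unchanged. The conversion is
#' always paired with a flag so that it can be reviewed and reverted with
#' [fix_temperatures()].
#'
#' @param value Numeric vector of raw readings (may contain `NA`).
#' @param threshold Conversion threshold in raw degrees (default 40).
#' @return A list with `value` (the possibly converted numeric vector) and
#'   `converted` (logical vector, `TRUE` where a conversion was applied).
#' @examples
#' convert_temperature(c(104, 40, -5, NA))
#' @export
convert_temperature <- function(value, threshold = 40) {
  if (is.character(value)) {
    num <- suppressWarnings(as.numeric(value))
    bad <- which(!is.na(value) & is.na(num))
    if (length(bad) > 0) {
      abort(
        paste0("Non-numeric temperature value(s) at position(s) ",
               paste(bad, collapse = ", "), ": ",
               paste(value[bad], collapse = ", ")),
        class = "sampleflow_coercion_error"
      )
    }
    value <- num
  }
  if (!is.numeric(value)) {
    abort("`value` must be numeric.", class = "sampleflow_coercion_error")
  }
  converted <- !is.na(value) & value > threshold
  out <- value
  out[converted] <- (value[converted] - 32) * 5 / 9
  list(value = out, converted = converted)
}

#' Standardize and flag the raw export tables
#'
#' Processes each table of a raw bundle independently: dates are parsed to
#' ISO 8601, times to 24-hour `HH:MM:SS`, temperatures are passed through
#' [convert_temperature()], altitude and GPS coordinates are coerced to
#' numbers with range checks on latitude/longitude, and collection and
#' isolation labels are normalized (trimmed and upper-cased) and validated
#' against the label grammar. Every original column is preserved verbatim;
#' processed values live in new `*_proc` columns and anomalies in `flag_*`
#' columns. Anomalies are flagged, never fatal, so that field data always
#' survive processing for review.
#'
#' @param bundle A `raw_bundle` from [read_fulcrum()].
#' @param config A [processing_config()].
#' @return A `processed_bundle`: the same tables with processed columns and
#'   flags, plus `config` and an (initially empty) `audit` table that
#'   [fix_temperatures()] appends to.
#' @export
proc_fulcrum <- function(bundle, config = processing_config()) {
  stopifnot(inherits(bundle, "raw_bundle"), inherits(config, "processing_config"))

  fs <- bundle$field_sampling
  fs$collection_date <- parse_iso_date(fs$date)
  fs$flag_date_unparseable <- !is.na(fs$date) & is.na(fs$collection_date)
  fs$collection_time <- parse_hms_time(fs$time)
  fs$flag_time_unparseable <- !is.na(fs$time) & is.na(fs$collection_time)

  amb <- convert_temperature(fs$ambient_temperature_c, config$fahrenheit_threshold)
  fs$ambient_temperature_proc <- amb$value
  fs$flag_ambient_temperature_converted <- amb$converted
  sub <- convert_temperature(fs$substrate_temperature, config$fahrenheit_threshold)
  fs$substrate_temperature_proc <- sub$value
  fs$flag_substrate_temperature_converted <- sub$converted

  fs$ambient_humidity_proc <- suppressWarnings(as.numeric(fs$ambient_humidity))
  fs$altitude_proc <-
    if ("gps_altitude" %in% names(fs)) {
      suppressWarnings(as.numeric(fs$gps_altitude))
    } else {
      NA_real_
    }

  fs$latitude_proc <- suppressWarnings(as.numeric(fs$latitude))
  fs$longitude_proc <- suppressWarnings(as.numeric(fs$longitude))
  fs$flag_latitude_invalid <-
    !is.na(fs$latitude) & (is.na(fs$latitude_proc) | abs(fs$latitude_proc) > 90)
  fs$flag_longitude_invalid <-
    !is.na(fs$longitude) & (is.na(fs$longitude_proc) | abs(fs$longitude_proc) > 180)
  fs$latitude_proc[fs$flag_latitude_invalid] <- NA_real_
  fs$longitude_proc[fs$flag_longitude_invalid] <- NA_real_

  fs <- normalize_label(fs, "c_label", config$c_label_pattern)

  ph <- bundle$field_sampling_sample_photo
  ph$exif_gps_latitude_proc <- suppressWarnings(as.numeric(ph$exif_gps_latitude))
  ph$exif_gps_longitude_proc <- suppressWarnings(as.numeric(ph$exif_gps_longitude))
  ph$exif_gps_dop_proc <- suppressWarnings(as.numeric(ph$exif_gps_dop))

  out <- list(field_sampling = fs, field_sampling_sample_photo = ph)

  if (bundle$isolation_present) {
    iso <- bundle$isolation
    iso$isolation_date <- parse_iso_date(iso$date)
    iso$isolation_time <- parse_hms_time(iso$time)
    iso$worms_on_sample_proc <- categorize_worms(
      if ("worms_on_sample" %in% names(iso)) iso$worms_on_sample else
        rep(NA_character_, nrow(iso))
    )
    out$isolation <- iso

    sp <- bundle$isolation_s_labeled_plates
    sp <- normalize_label(sp, "s_label", config$s_label_pattern)
    out$isolation_s_labeled_plates <- sp

    out$isolation_photos <- bundle$isolation_photos
  }

  structure(
    c(out, list(
      prefix = bundle$prefix,
      isolation_present = bundle$isolation_present,
      config = config,
      audit = tibble(
        action = character(), table = character(), fulcrum_id = character(),
        field = character(), old_value = numeric(), new_value = numeric(),
        note = character()
      )
    )),
    class = "processed_bundle"
  )
}

# Trim + uppercase a label column; add missing / misformatted flags.
normalize_label <- function(tab, col, pattern) {
  raw <- tab[[col]]
  norm <- toupper(stringr::str_squish(ifelse(is.na(raw), "", raw)))
  norm[norm == ""] <- NA_character_
  tab[[paste0(col, "_proc")]] <- norm
  tab[[paste0("flag_", col, "_missing")]] <- is.na(norm)
  tab[[paste0("flag_", col, "_misformatted")]] <-
    !is.na(norm) & !stringr::str_detect(norm, pattern)
  tab
}

parse_iso_date <- function(x) {
  out <- as.Date(rep(NA, length(x)))
  for (fmt in c("%Y-%m-%d", "%m/%d/%Y", "%d-%b-%Y")) {
    idx <- is.na(out) & !is.na(x)
    if (!any(idx)) break
    out[idx] <- as.Date(x[idx], format = fmt)
  }
  out
}

parse_hms_time <- function(x) {
  m <- stringr::str_match(
    ifelse(is.na(x), "", x),
    "^\\s*([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}))?\\s*(AM|PM|am|pm)?\\s*$"
  )
  h <- suppressWarnings(as.integer(m[, 2]))
  mi <- suppressWarnings(as.integer(m[, 3]))
  s <- suppressWarnings(as.integer(m[, 4]))
  s[is.na(s) & !is.na(h)] <- 0L
  ampm <- toupper(m[, 5])
  h <- ifelse(!is.na(ampm) & ampm == "PM" & h < 12, h + 12L, h)
  h <- ifelse(!is.na(ampm) & ampm == "AM" & h == 12, 0L, h)
  ok <- !is.na(h) & !is.na(mi) & h < 24 & mi < 60 & s < 60
  ifelse(ok, sprintf("%02d:%02d:%02d", h, mi, s), NA_character_)
}

categorize_worms <- function(x) {
  norm <- toupper(stringr::str_squish(ifelse(is.na(x), "", x)))
  dplyr::case_when(
    norm %in% c("YES", "Y", "PRESENT") ~ "present",
    norm %in% c("NO", "N", "ABSENT") ~ "absent",
    norm %in% c("TRACKS", "TRACKS ONLY", "TRACKS_ONLY") ~ "tracks_only",
    TRUE ~ "unknown"
  )
}

# Collections in chronological review order: date, then time, then record id.
ordered_field_sampling <- function(fs) {
  fs[order(fs$collection_date, fs$collection_time, fs$fulcrum_id,
           na.last = TRUE), , drop = FALSE]
}

# Maximal runs of >= run_length_min identical consecutive non-missing values.
# Returns an integer run id per position (NA where not part of a run).
detect_stuck_runs <- function(values, run_length_min) {
  n <- length(values)
  run_id <- rep(NA_integer_, n)
  if (n == 0) return(run_id)
  r <- rle(ifelse(is.na(values), "NA", format(values, digits = 15)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- 0L
  for (i in seq_along(r$lengths)) {
    if (r$lengths[i] >= run_length_min && !is.na(values[starts[i]])) {
      k <- k + 1L
      run_id[starts[i]:ends[i]] <- k
    }
  }
  run_id
}

#' Review flagged temperature values
#'
#' Lists (a) every temperature that was auto-converted from Fahrenheit, with
#' its original and converted value, and (b) every maximal run of
#' `run_length_min` or more identical consecutive readings in the ambient and
#' substrate series, with collections ordered by collection date and time
#' (ties broken by record id). Such runs suggest a stuck or mis-handled
#' temperature probe. Use [fix_temperatures()] to revert conversions judged
#' inappropriate or to blank out erroneous readings.
#'
#' @param processed A `processed_bundle` from [proc_fulcrum()].
#' @param config A [processing_config()]; defaults to the one stored in the
#'   bundle.
#' @return A `temperature_report`: a list of two tibbles, `conversions` and
#'   `runs`. Both are empty when nothing is flagged.
#' @export
check_temperatures <- function(processed, config = NULL) {
  stopifnot(inherits(processed, "processed_bundle"))
  if (is.null(config)) config <- processed$config
  fs <- processed$field_sampling

  conv <- purrr::map_dfr(
    c(ambient = "ambient_temperature_c", substrate = "substrate_temperature"),
    function(col) {
      series <- if (col == "ambient_temperature_c") "ambient" else "substrate"
      proc_col <- if (series == "ambient") "ambient_temperature_proc" else
        "substrate_temperature_proc"
      flag_col <- paste0("flag_", series, "_temperature_converted")
      idx <- which(fs[[flag_col]])
      tibble(
        fulcrum_id = fs$fulcrum_id[idx],
        c_label = fs$c_label_proc[idx],
        field = rep(paste0(series, "_temperature"), length(idx)),
        raw_value = suppressWarnings(as.numeric(fs[[col]][idx])),
        converted_value = fs[[proc_col]][idx]
      )
    }
  )

  ord <- ordered_field_sampling(fs)
  runs <- purrr::map_dfr(
    c(ambient = "ambient_temperature_proc", substrate = "substrate_temperature_proc"),
    function(col) {
      series <- if (col == "ambient_temperature_proc") "ambient" else "substrate"
      rid <- detect_stuck_runs(ord[[col]], config$run_length_min)
      idx <- which(!is.na(rid))
      tibble(
        field = rep(paste0(series, "_temperature"), length(idx)),
        run = rid[idx],
        fulcrum_id = ord$fulcrum_id[idx],
        c_label = ord$c_label_proc[idx],
        value = ord[[col]][idx]
      )
    }
  )

  structure(list(conversions = conv, runs = runs), class = "temperature_report")
}

#' @export
print.temperature_report <- function(x, ...) {
  cat("<temperature_report>\n")
  if (nrow(x$conversions) == 0 && nrow(x$runs) == 0) {
    cat("  No flagged temperature values.\n")
    return(invisible(x))
  }
  if (nrow(x$conversions) > 0) {
    cat("Fahrenheit-to-Celsius conversions (review and revert if wrong):\n")
    print(as.data.frame(x$conversions), row.names = FALSE)
  }
  if (nrow(x$runs) > 0) {
    cat("Identical consecutive readings (possible stuck probe):\n")
    print(as.data.frame(x$runs), row.names = FALSE)
  }
  invisible(x)
}

#' Revert or remove flagged temperature values
#'
#' Applies reviewed repairs to the processed temperature columns. A revert
#' restores the original raw value of a previously auto-converted reading and
#' clears its conversion flag; a removal blanks an erroneous reading. Raw
#' columns are never modified, and every repair (including refused ones) is
#' appended to the bundle's audit table, so no flag disappears without a
#' trace.
#'
#' @param processed A `processed_bundle`.
#' @param revert_ids,remove_ids Data frames with columns `fulcrum_id` and
#'   `field` (`"ambient_temperature"` or `"substrate_temperature"`), or
#'   `NULL`.
#' @return The updated `processed_bundle`.
#' @export
fix_temperatures <- function(processed, revert_ids = NULL, remove_ids = NULL) {
  stopifnot(inherits(processed, "processed_bundle"))
  fs <- processed$field_sampling
  audit <- processed$audit

  resolve <- function(ids) {
    ids <- as_tibble(ids)
    stopifnot(all(c("fulcrum_id", "field") %in% names(ids)))
    bad_field <- setdiff(unique(ids$field),
                         c("ambient_temperature", "substrate_temperature"))
    if (length(bad_field) > 0) {
      abort(paste0("Unknown temperature field(s): ",
                   paste(bad_field, collapse = ", ")),
            class = "sampleflow_lookup_error")
    }
    missing <- setdiff(ids$fulcrum_id, fs$fulcrum_id)
    if (length(missing) > 0) {
      abort(paste0("Unknown record id(s): ", paste(missing, collapse = ", ")),
            class = "sampleflow_lookup_error")
    }
    ids
  }

  if (!is.null(revert_ids) && nrow(as_tibble(revert_ids)) > 0) {
    ids <- resolve(revert_ids)
    for (i in seq_len(nrow(ids))) {
      series <- sub("_temperature$", "", ids$field[i])
      raw_col <- if (series == "ambient") "ambient_temperature_c" else
        "substrate_temperature"
      proc_col <- paste0(series, "_temperature_proc")
      flag_col <- paste0("flag_", series, "_temperature_converted")
      row <- which(fs$fulcrum_id == ids$fulcrum_id[i])
      if (!isTRUE(fs[[flag_col]][row])) {
        warn(paste0("Revert requested for non-converted field ", ids$field[i],
                    " of record ", ids$fulcrum_id[i], "; skipped."))
        audit <- bind_rows(audit, tibble(
          action = "revert_refused", table = "field_sampling",
          fulcrum_id = ids$fulcrum_id[i], field = ids$field[i],
          old_value = fs[[proc_col]][row], new_value = fs[[proc_col]][row],
          note = "field was not converted"
        ))
        next
      }
      raw_val <- suppressWarnings(as.numeric(fs[[raw_col]][row]))
      audit <- bind_rows(audit, tibble(
        action = "revert_conversion", table = "field_sampling",
        fulcrum_id = ids$fulcrum_id[i], field = ids$field[i],
        old_value = fs[[proc_col]][row], new_value = raw_val,
        note = "user reverted Fahrenheit-to-Celsius conversion"
      ))
      fs[[proc_col]][row] <- raw_val
      fs[[flag_col]][row] <- FALSE
    }
  }

  if (!is.null(remove_ids) && nrow(as_tibble(remove_ids)) > 0) {
    ids <- resolve(remove_ids)
    for (i in seq_len(nrow(ids))) {
      series <- sub("_temperature$", "", ids$field[i])
      proc_col <- paste0(series, "_temperature_proc")
      row <- which(fs$fulcrum_id == ids$fulcrum_id[i])
      audit <- bind_rows(audit, tibble(
        action = "remove_value", table = "field_sampling",
        fulcrum_id = ids$fulcrum_id[i], field = ids$field[i],
        old_value = fs[[proc_col]][row], new_value = NA_real_,
        note = "user removed erroneous temperature"
      ))
      fs[[proc_col]][row] <- NA_real_
    }
  }

  processed$field_sampling <- fs
  processed$audit <- audit
  processed
}
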