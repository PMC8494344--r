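#' Select the best photo for a collection
#'
#' Mobile devices store a GPS fix in photo metadata; the photo table exports
#' a per-photo precision estimate (`exif_gps_dop`, in meters, smaller is more
#' precise). When a collection has several photos, the one with the smallest
#' precision estimate is kept; a missing estimate counts as infinitely
#' imprecise, and exact ties are broken by lexicographic photo record id so
#' reruns are deterministic.
#'
#' @param photos A data frame of photo rows sharing one parent collection,
#'   with at least `fulcrum_id` and a numeric `exif_gps_dop_proc` (or raw
#'   `exif_gps_dop`) column.
#' @return The single best photo row, or `NULL` for an empty input.
#' @export
select_best_photo <- function(photos) {
  if (is.null(photos) || nrow(photos) == 0) return(NULL)
  dop <- if ("exif_gps_dop_proc" %in% names(photos)) {
    photos$exif_gps_dop_proc
  } else {
    suppressWarnings(as.numeric(photos$exif_gps_dop))
  }
  dop[is.na(dop)] <- Inf
  ord <- order(dop, photos$fulcrum_id)
  photos[ord[1], , drop = FALSE]
}

#' Join the processed tables into one long collection table
#'
#' Builds the unified long table: one row per S-label for collections with
#' isolated specimens, and exactly one row for collections without any. The
#' join proceeds in order: field-sampling records are joined to isolation
#' records on the platform's record identifiers; the best photo per
#' collection is selected with [select_best_photo()] and its GPS fix
#' attached; the final location prefers the photo GPS fix over the
#' record-time fix (photo fixes are typically closer to the true sampling
#' site) with `location_source` recording which was used; S-labels are
#' expanded from the plates table; finally project-wide flags are computed
#' (extreme temperatures and altitude, duplicated/missing/misformatted
#' C- and S-labels, missing photos, orphaned isolations).
#'
#' Isolations that reference a collection record id absent from the
#' field-sampling table are retained and flagged as orphans rather than
#' dropped. Duplicate collection record ids violate the export's uniqueness
#' contract and abort the join.
#'
#' @param processed A `processed_bundle` from [proc_fulcrum()], with any
#'   temperature repairs already applied.
#' @param config A [processing_config()]; defaults to the bundle's.
#' @return A tibble of class `joined_collection`.
#' @export
join_fulcrum <- function(processed, config = NULL) {
  stopifnot(inherits(processed, "processed_bundle"))
  if (is.null(config)) config <- processed$config
  fs <- processed$field_sampling

  if (anyDuplicated(fs$fulcrum_id) > 0) {
    abort(
      paste0("Duplicate collection record id(s) in field_sampling: ",
             paste(unique(fs$fulcrum_id[duplicated(fs$fulcrum_id)]),
                   collapse = ", ")),
      class = "sampleflow_integrity_error"
    )
  }

  # stuck-probe run flags over the chronologically ordered series
  ord <- ordered_field_sampling(fs)
  run_flags <- tibble(
    fulcrum_id = ord$fulcrum_id,
    flag_ambient_temperature_run =
      !is.na(detect_stuck_runs(ord$ambient_temperature_proc, config$run_length_min)),
    flag_substrate_temperature_run =
      !is.na(detect_stuck_runs(ord$substrate_temperature_proc, config$run_length_min))
  )

  # best photo per collection
  ph <- processed$field_sampling_sample_photo
  best <- ph %>%
    dplyr::group_by(.data$fulcrum_parent_id) %>%
    dplyr::group_modify(function(rows, key) {
      b <- select_best_photo(rows)
      if (is.null(b)) rows[0, ] else b
    }) %>%
    dplyr::ungroup() %>%
    dplyr::transmute(
      collection_id = .data$fulcrum_parent_id,
      best_photo_id = .data$fulcrum_id,
      best_photo_filename = paste0(.data$sample_photo, ".jpg"),
      photo_latitude = .data$exif_gps_latitude_proc,
      photo_longitude = .data$exif_gps_longitude_proc,
      exif_gps_dop = .data$exif_gps_dop_proc
    )

  base <- fs %>%
    dplyr::transmute(
      collection_id = .data$fulcrum_id,
      c_label = .data$c_label_proc,
      collection_date = .data$collection_date,
      collection_time = .data$collection_time,
      collection_by = if ("created_by" %in% names(fs)) .data$created_by else NA_character_,
      gridsect = .data$gridsect,
      ambient_temperature = .data$ambient_temperature_proc,
      substrate_temperature = .data$substrate_temperature_proc,
      ambient_humidity = .data$ambient_humidity_proc,
      altitude = .data$altitude_proc,
      record_latitude = .data$latitude_proc,
      record_longitude = .data$longitude_proc,
      flag_c_label_missing = .data$flag_c_label_missing,
      flag_c_label_misformatted = .data$flag_c_label_misformatted,
      flag_ambient_temperature_converted = .data$flag_ambient_temperature_converted,
      flag_substrate_temperature_converted = .data$flag_substrate_temperature_converted
    ) %>%
    left_join(run_flags, by = c(collection_id = "fulcrum_id")) %>%
    left_join(best, by = "collection_id")

  # isolation + S-label expansion
  if (processed$isolation_present && nrow(processed$isolation) > 0) {
    iso <- processed$isolation %>%
      dplyr::transmute(
        isolation_id = .data$fulcrum_id,
        collection_id = .data$c_label,
        isolation_date = .data$isolation_date,
        isolation_time = .data$isolation_time,
        worms_on_sample = .data$worms_on_sample_proc
      )
    sp <- processed$isolation_s_labeled_plates %>%
      dplyr::transmute(
        isolation_id = .data$fulcrum_parent_id,
        s_label = .data$s_label_proc,
        flag_s_label_missing = .data$flag_s_label_missing,
        flag_s_label_misformatted = .data$flag_s_label_misformatted
      )
    iso_full <- left_join(iso, sp, by = "isolation_id",
                          relationship = "one-to-many")

    orphans <- iso_full %>%
      filter(!.data$collection_id %in% base$collection_id) %>%
      mutate(flag_orphan_isolation = TRUE)

    joined <- base %>%
      left_join(
        iso_full %>% filter(.data$collection_id %in% base$collection_id),
        by = "collection_id", relationship = "one-to-many"
      ) %>%
      mutate(flag_orphan_isolation = FALSE) %>%
      bind_rows(orphans)
  } else {
    joined <- base %>%
      mutate(
        isolation_id = NA_character_,
        isolation_date = as.Date(NA),
        isolation_time = NA_character_,
        worms_on_sample = NA_character_,
        s_label = NA_character_,
        flag_s_label_missing = FALSE,
        flag_s_label_misformatted = FALSE,
        flag_orphan_isolation = FALSE
      )
  }

  joined <- joined %>%
    mutate(
      worms_on_sample = dplyr::coalesce(.data$worms_on_sample, "unknown"),
      flag_s_label_missing = dplyr::coalesce(.data$flag_s_label_missing, FALSE),
      flag_s_label_misformatted = dplyr::coalesce(.data$flag_s_label_misformatted, FALSE),
      location_source = dplyr::case_when(
        !is.na(.data$photo_latitude) & !is.na(.data$photo_longitude) ~ "photo",
        !is.na(.data$record_latitude) & !is.na(.data$record_longitude) ~ "record",
        TRUE ~ "none"
      ),
      latitude = dplyr::case_when(
        .data$location_source == "photo" ~ .data$photo_latitude,
        .data$location_source == "record" ~ .data$record_latitude,
        TRUE ~ NA_real_
      ),
      longitude = dplyr::case_when(
        .data$location_source == "photo" ~ .data$photo_longitude,
        .data$location_source == "record" ~ .data$record_longitude,
        TRUE ~ NA_real_
      ),
      flag_ambient_temperature_extreme =
        !is.na(.data$ambient_temperature) &
        (.data$ambient_temperature < config$ambient_temp_range[1] |
           .data$ambient_temperature > config$ambient_temp_range[2]),
      flag_substrate_temperature_extreme =
        !is.na(.data$substrate_temperature) &
        (.data$substrate_temperature < config$substrate_temp_range[1] |
           .data$substrate_temperature > config$substrate_temp_range[2]),
      flag_altitude_extreme =
        !is.na(.data$altitude) &
        (.data$altitude < config$altitude_range[1] |
           .data$altitude > config$altitude_range[2]),
      flag_photo_missing = is.na(.data$best_photo_id)
    )

  # project-wide duplicate flags over distinct entities, after normalization
  dup_c <- base %>%
    filter(!is.na(.data$c_label)) %>%
    dplyr::count(.data$c_label) %>%
    filter(.data$n > 1) %>%
    pull(.data$c_label)
  dup_s <- joined %>%
    filter(!is.na(.data$s_label)) %>%
    dplyr::count(.data$s_label) %>%
    filter(.data$n > 1) %>%
    pull(.data$s_label)
  joined <- joined %>%
    mutate(
      flag_c_label_duplicated = !is.na(.data$c_label) & .data$c_label %in% dup_c,
      flag_s_label_duplicated = !is.na(.data$s_label) & .data$s_label %in% dup_s,
      flag_c_label_missing = dplyr::coalesce(.data$flag_c_label_missing, FALSE),
      flag_c_label_misformatted = dplyr::coalesce(.data$flag_c_label_misformatted, FALSE)
    )

  class(joined) <- c("joined_collection", class(joined))
  joined
}

# flag column -> export file responsible for it
sampleflow_flag_sources <- c(
  flag_c_label_missing = "field_sampling",
  flag_c_label_misformatted = "field_sampling",
  flag_c_label_duplicated = "field_sampling",
  flag_ambient_temperature_converted = "field_sampling",
  flag_substrate_temperature_converted = "field_sampling",
  flag_ambient_temperature_run = "field_sampling",
  flag_substrate_temperature_run = "field_sampling",
  flag_ambient_temperature_extreme = "field_sampling",
  flag_substrate_temperature_extreme = "field_sampling",
  flag_altitude_extreme = "field_sampling",
  flag_photo_missing = "field_sampling_sample_photo",
  flag_s_label_missing = "isolation_s_labeled_plates",
  flag_s_label_misformatted = "isolation_s_labeled_plates",
  flag_s_label_duplicated = "isolation_s_labeled_plates",
  flag_orphan_isolation = "isolation"
)

#' Summarize flags raised during the join
#'
#' Groups every raised flag by type, lists the affected C- and S-labels, and
#' names the export file whose data is responsible for that flag type, so
#' errors can be traced to their source.
#'
#' @param joined A `joined_collection` from [join_fulcrum()].
#' @return A tibble of class `join_report` with columns `flag`, `source_file`,
#'   `n`, and `labels`; zero rows when the data are clean.
#' @export
check_join <- function(joined) {
  stopifnot(inherits(joined, "joined_collection"))
  flag_cols <- intersect(names(sampleflow_flag_sources), names(joined))
  rows <- purrr::map_dfr(flag_cols, function(col) {
    hit <- which(dplyr::coalesce(joined[[col]], FALSE))
    if (length(hit) == 0) return(tibble())
    labels <- if (startsWith(sub("^flag_", "", col), "s_label")) {
      joined$s_label[hit]
    } else {
      joined$c_label[hit]
    }
    labels[is.na(labels)] <- "<missing>"
    tibble(
      flag = sub("^flag_", "", col),
      source_file = unname(sampleflow_flag_sources[col]),
      n = length(hit),
      labels = paste(sort(unique(labels)), collapse = "; ")
    )
  })
  if (nrow(rows) == 0) {
    rows <- tibble(flag = character(), source_file = character(),
                   n = integer(), labels = character())
  }
  structure(rows, class = c("join_report", class(tibble())))
}

#' @export
print.join_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<join_report> No flags raised; data are clean.\n")
    return(invisible(x))
  }
  cat("<join_report>", sum(x$n), "flag(s) in", nrow(x), "categories:\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
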