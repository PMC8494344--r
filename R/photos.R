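#' Copy, rename, and thumbnail collection photos
#'
#' Raw photos are exported as JPEG files named by their photo record id,
#' which makes them hard to browse. For each collection's best photo this
#' copies the raw file byte-for-byte to `data/processed/fulcrum/photos`
#' renamed to the collection's C-label (`C-3205.jpg`), and writes an
#' aspect-preserving thumbnail (longest side at most
#' `config$thumbnail_max_dim` pixels) under `.../photos/thumbnails`. When
#' two collections share a C-label the later files get `_2`, `_3` suffixes
#' so nothing is silently overwritten. A missing or unreadable raw file is
#' reported per row (`photo_status = "missing_raw"`) without aborting the
#' run. Re-running overwrites deterministically.
#'
#' @param final A `final_table` (or `joined_collection`) with
#'   `best_photo_filename` and `c_label` columns.
#' @param layout The [project_layout()] holding the raw and processed photo
#'   directories.
#' @param config A [processing_config()].
#' @param all_photos Reserved; only the best photo per collection is
#'   currently processed.
#' @return `final` with columns `raw_photo_path`, `processed_photo_path`,
#'   `thumbnail_path`, and `photo_status` (`"ok"` or `"missing_raw"`).
#' @export
proc_photos <- function(final, layout, config = processing_config(),
                        all_photos = FALSE) {
  stopifnot(inherits(layout, "project_layout"))
  for (d in c(layout$processed_photos, layout$thumbnails)) {
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }

  # one physical photo per collection; suffix duplicate C-labels by
  # collection id order so reruns name files identically
  coll <- final %>%
    distinct(.data$collection_id, .keep_all = TRUE) %>%
    filter(!is.na(.data$best_photo_filename)) %>%
    arrange(.data$collection_id) %>%
    group_by(.data$c_label) %>%
    mutate(.dup_rank = row_number()) %>%
    ungroup()

  res <- purrr::pmap_dfr(
    list(coll$collection_id, coll$c_label, coll$best_photo_filename, coll$.dup_rank),
    function(cid, c_label, fname, rank) {
      stem <- if (is.na(c_label)) paste0("collection-", cid) else c_label
      if (rank > 1) stem <- paste0(stem, "_", rank)
      raw <- file.path(layout$raw_photos, fname)
      dest <- file.path(layout$processed_photos, paste0(stem, ".jpg"))
      thumb <- file.path(layout$thumbnails, paste0(stem, ".jpg"))
      status <- "ok"
      if (!file.exists(raw)) {
        status <- "missing_raw"
      } else {
        ok <- tryCatch({
          file.copy(raw, dest, overwrite = TRUE)
          write_thumbnail(raw, thumb, config$thumbnail_max_dim)
          TRUE
        }, error = function(e) {
          warn(paste0("Could not process photo ", fname, ": ",
                      conditionMessage(e)))
          FALSE
        })
        if (!ok) status <- "missing_raw"
      }
      tibble(
        collection_id = cid,
        raw_photo_path = if (status == "ok") raw else NA_character_,
        processed_photo_path = if (status == "ok") dest else NA_character_,
        thumbnail_path = if (status == "ok") thumb else NA_character_,
        photo_status = status
      )
    }
  )

  out <- final %>%
    left_join(res, by = "collection_id") %>%
    mutate(photo_status = dplyr::coalesce(.data$photo_status, "missing_raw"))
  class(out) <- class(final)
  out
}

# Aspect-preserving downscale by nearest-neighbour sampling; no upscaling.
write_thumbnail <- function(raw_path, thumb_path, max_dim) {
  img <- jpeg::readJPEG(raw_path)
  h <- dim(img)[1]
  w <- dim(img)[2]
  scale <- min(1, max_dim / max(h, w))
  th <- max(1L, round(h * scale))
  tw <- max(1L, round(w * scale))
  rows <- pmin(h, pmax(1L, round(seq(1, h, length.out = th))))
  cols <- pmin(w, pmax(1L, round(seq(1, w, length.out = tw))))
  small <- if (length(dim(img)) == 3) img[rows, cols, , drop = FALSE] else
    img[rows, cols, drop = FALSE]
  jpeg::writeJPEG(small, thumb_path, quality = 0.9)
  invisible(thumb_path)
}
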