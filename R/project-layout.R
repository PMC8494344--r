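#' Describe the fixed project directory layout
#'
#' A sampling project lives in a single root directory with a fixed tree:
#' raw exports under `data/raw/fulcrum` (photos in `data/raw/fulcrum/photos`),
#' spatial annotation files under `data/raw/annotate`, processed outputs under
#' `data/processed/fulcrum` (photos and thumbnails below it) and
#' `data/processed/genotypes`, rendered reports under `reports`, and editable
#' report scripts under `scripts`.
#'
#' `project_layout()` only computes the paths; [make_directory_structure()]
#' creates them on disk.
#'
#' @param root Path to the project root directory.
#' @return An object of class `project_layout`: a named list of the root and
#'   its nine derived directories.
#' @seealso [make_directory_structure()]
#' @export
project_layout <- function(root) {
  if (length(root) != 1 || !is.character(root) || is.na(root)) {
    abort("`root` must be a single path.", class = "sampleflow_invalid_path")
  }
  structure(
    list(
      root                = root,
      raw_fulcrum         = file.path(root, "data", "raw", "fulcrum"),
      raw_photos          = file.path(root, "data", "raw", "fulcrum", "photos"),
      raw_annotate        = file.path(root, "data", "raw", "annotate"),
      processed_fulcrum   = file.path(root, "data", "processed", "fulcrum"),
      processed_photos    = file.path(root, "data", "processed", "fulcrum", "photos"),
      thumbnails          = file.path(root, "data", "processed", "fulcrum", "photos", "thumbnails"),
      processed_genotypes = file.path(root, "data", "processed", "genotypes"),
      reports             = file.path(root, "reports"),
      scripts             = file.path(root, "scripts")
    ),
    class = "project_layout"
  )
}

#' @export
print.project_layout <- function(x, ...) {
  cat("<project_layout>\n")
  cat("  root:", x$root, "\n")
  for (nm in setdiff(names(x), "root")) {
    cat(sprintf("  %-19s %s\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Create the project directory structure
#'
#' Creates every directory of the fixed project layout under `root`. The call
#' is idempotent: directories that already exist are left alone and existing
#' files are never touched, so it is safe to run on a partially populated
#' project.
#'
#' @inheritParams project_layout
#' @return The [project_layout()] for `root`, invisibly usable downstream.
#' @examples
#' root <- file.path(tempdir(), "my_project")
#' layout <- make_directory_structure(root)
#' dir.exists(layout$raw_fulcrum)
#' @export
make_directory_structure <- function(root) {
  layout <- project_layout(root)
  if (file.exists(root) && !dir.exists(root)) {
    abort(
      paste0("`root` exists but is not a directory: ", root),
      class = "sampleflow_invalid_path"
    )
  }
  for (path in unlist(layout)) {
    if (!dir.exists(path)) {
      ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
      if (!ok && !dir.exists(path)) {
        abort(
          paste0("Could not create directory (permission denied?): ", path),
          class = "sampleflow_permission_error"
        )
      }
    }
  }
  layout
}

#' Detect the export-file prefix of a project
#'
#' Export files follow the naming convention `<prefix>_field_sampling.csv`,
#' `<prefix>_isolation.csv`, and so on, where the prefix identifies the
#' data-collection application (for example `nematode`). The prefix is
#' discovered from the file names in the raw export directory.
#'
#' @param raw_fulcrum_dir Directory holding the raw CSV exports
#'   (`<root>/data/raw/fulcrum` in the standard layout).
#' @return The prefix string.
#' @export
detect_prefix <- function(raw_fulcrum_dir) {
  files <- list.files(raw_fulcrum_dir, pattern = "_field_sampling\\.csv$")
  prefixes <- unique(sub("_field_sampling\\.csv$", "", files))
  prefixes <- prefixes[nzchar(prefixes)]
  if (length(prefixes) == 0) {
    abort(
      paste0(
        "No `<prefix>_field_sampling.csv` export found in ", raw_fulcrum_dir
      ),
      class = "sampleflow_missing_export"
    )
  }
  if (length(prefixes) > 1) {
    abort(
      paste0(
        "Multiple export prefixes found in ", raw_fulcrum_dir, ": ",
        paste(sort(prefixes), collapse = ", ")
      ),
      class = "sampleflow_ambiguous_prefix"
    )
  }
  prefixes
}
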