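#' Read the raw export files into a bundle
#'
#' Reads the five CSV files exported by the data-collection platform from
#' `data/raw/fulcrum` into a named bundle of tibbles. The two field-sampling
#' tables (`field_sampling` and `field_sampling_sample_photo`) are required.
#' The three isolation tables (`isolation`, `isolation_s_labeled_plates`,
#' `isolation_photos`) are optional as a trio, covering the special case of a
#' project where specimens were never isolated; a partial trio is an error
#' rather than a silent drop of laboratory data.
#'
#' Files are parsed as UTF-8, comma-separated, RFC 4180-quoted CSV with a
#' header row. All columns are read as character so that raw cell values are
#' preserved verbatim; empty strings become missing values. Typed copies are
#' added later by [proc_fulcrum()].
#'
#' @param layout A [project_layout()], or a path to the project root.
#' @param prefix Export-file prefix; autodetected with [detect_prefix()] when
#'   `NULL`.
#' @return A `raw_bundle`: a list with one tibble per export table plus
#'   `prefix` and `isolation_present`.
#' @export
read_fulcrum <- function(layout, prefix = NULL) {
  if (is.character(layout)) layout <- project_layout(layout)
  stopifnot(inherits(layout, "project_layout"))
  dir <- layout$raw_fulcrum
  if (!dir.exists(dir)) {
    abort(paste0("Raw export directory does not exist: ", dir),
          class = "sampleflow_missing_export")
  }
  if (is.null(prefix)) prefix <- detect_prefix(dir)

  paths <- setNames(
    file.path(dir, paste0(prefix, "_", sampleflow_table_roles, ".csv")),
    sampleflow_table_roles
  )
  present <- setNames(file.exists(paths), names(paths))
  required <- c("field_sampling", "field_sampling_sample_photo")
  if (!all(present[required])) {
    abort(
      paste0("Missing required export file(s): ",
             paste(basename(paths[required][!present[required]]), collapse = ", ")),
      class = "sampleflow_missing_export"
    )
  }
  iso_present <- present[sampleflow_isolation_roles]
  if (any(iso_present) && !all(iso_present)) {
    abort(
      paste0(
        "Isolation export is incomplete; expected all three of ",
        paste(basename(paths[sampleflow_isolation_roles]), collapse = ", "),
        " or none."
      ),
      class = "sampleflow_missing_export"
    )
  }

  roles <- c(required, if (all(iso_present)) sampleflow_isolation_roles)
  tables <- lapply(setNames(roles, roles), function(role) {
    read_export_csv(paths[[role]], role)
  })

  structure(
    c(tables, list(prefix = prefix, isolation_present = all(iso_present))),
    class = "raw_bundle"
  )
}

# Parse one export CSV: all-character columns, "" -> NA, header required.
read_export_csv <- function(path, role) {
  tab <- tryCatch(
    readr::read_csv(
      path,
      col_types = readr::cols(.default = readr::col_character()),
      na = c(""),
      trim_ws = FALSE,
      locale = readr::locale(encoding = "UTF-8"),
      progress = FALSE,
      show_col_types = FALSE
    ),
    error = function(e) {
      abort(paste0("Failed to parse ", basename(path), ": ", conditionMessage(e)),
            class = "sampleflow_parse_error")
    }
  )
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(
      paste0("Malformed CSV in ", basename(path), " at line(s) ",
             paste(unique(probs$row), collapse = ", ")),
      class = "sampleflow_parse_error"
    )
  }
  missing_cols <- setdiff(sampleflow_required_columns[[role]], names(tab))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Column(s) ", paste(missing_cols, collapse = ", "),
             " missing from ", basename(path)),
      class = "sampleflow_schema_error"
    )
  }
  tab
}

#' @export
print.raw_bundle <- function(x, ...) {
  cat("<raw_bundle> prefix:", x$prefix,
      "| isolation data:", if (x$isolation_present) "present" else "absent", "\n")
  for (role in intersect(sampleflow_table_roles, names(x))) {
    cat(sprintf("  %-28s %d rows x %d cols\n", role, nrow(x[[role]]), ncol(x[[role]])))
  }
  invisible(x)
}
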