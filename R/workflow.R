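#' The main workflow operations
#'
#' The public workflow API consists of thirteen operations, run in this
#' order: directory creation, reading the exports, processing, reviewing and
#' repairing temperatures, joining, reviewing the join, geographic
#' annotation, reading / checking / joining the genotyping sheet, photo
#' processing, and report generation.
#'
#' @return Character vector of the thirteen exported function names in
#'   workflow order.
#' @export
workflow_functions <- function() {
  c(
    "make_directory_structure",
    "read_fulcrum",
    "proc_fulcrum",
    "check_temperatures",
    "fix_temperatures",
    "join_fulcrum",
    "check_join",
    "annotate_fulcrum",
    "read_genotypes",
    "check_genotypes",
    "join_geno_fulc",
    "proc_photos",
    "generate_report"
  )
}

sampleflow_stages <- c("read", "process", "join", "annotate", "genotype",
                       "photos", "report")

sampleflow_stage_requires <- list(
  read = character(0), process = "read", join = "process",
  annotate = "join", genotype = "join", photos = "join", report = "join"
)

#' Run the full workflow over a project directory
#'
#' Chains the workflow stages over an existing project: read the exports,
#' process and flag, join, optionally annotate with GeoJSON features,
#' optionally join the genotyping sheet, process photos, and generate the
#' HTML report. Every stage's flag counts are logged via `message()`.
#' Anomalies are logged and carried as flags, never fatal — field data must
#' reach review — so only referential-integrity violations (for example
#' duplicated collection record ids) abort the run.
#'
#' Requesting a stage without the stage it depends on raises an ordering
#' error naming the missing prerequisite.
#'
#' @param root Project root directory (see [make_directory_structure()]).
#' @param config A [processing_config()].
#' @param features_file GeoJSON feature file for the annotate stage; when
#'   `NULL`, the first `.geojson` file in `data/raw/annotate` is used if one
#'   exists.
#' @param sheet Path to a genotyping-sheet CSV/TSV; `NULL` skips the
#'   genotype stage.
#' @param schema Genotyping-sheet schema.
#' @param revert_ids,remove_ids Temperature repairs forwarded to
#'   [fix_temperatures()] between processing and joining.
#' @param deterministic_report Passed to [generate_report()].
#' @param stages Stages to run, a subset of
#'   `c("read", "process", "join", "annotate", "genotype", "photos",
#'   "report")` in workflow order.
#' @return Invisibly, a list with the layout, the final table, the
#'   [check_join()] report, and the report path (when generated).
#' @export
run_workflow <- function(root,
                         config = processing_config(),
                         features_file = NULL,
                         sheet = NULL,
                         schema = c("general", "nematode"),
                         revert_ids = NULL,
                         remove_ids = NULL,
                         deterministic_report = FALSE,
                         stages = sampleflow_stages) {
  schema <- match.arg(schema)
  stages <- match.arg(stages, sampleflow_stages, several.ok = TRUE)
  for (stage in stages) {
    missing <- setdiff(sampleflow_stage_requires[[stage]], stages)
    if (length(missing) > 0) {
      abort(
        paste0("Stage `", stage, "` requires stage `", missing[1],
               "` to run first."),
        class = "sampleflow_ordering_error"
      )
    }
  }
  layout <- make_directory_structure(root)
  result <- list(layout = layout)
  final <- NULL

  if ("read" %in% stages) {
    bundle <- read_fulcrum(layout)
    message("read: ", length(intersect(sampleflow_table_roles, names(bundle))),
            " export tables (prefix `", bundle$prefix, "`)")
    result$bundle <- bundle
  }
  if ("process" %in% stages) {
    processed <- proc_fulcrum(result$bundle, config)
    temp_report <- check_temperatures(processed)
    message("process: ", nrow(temp_report$conversions),
            " temperature conversion(s), ",
            dplyr::n_distinct(temp_report$runs$run), " stuck-probe run(s)")
    if (!is.null(revert_ids) || !is.null(remove_ids)) {
      processed <- fix_temperatures(processed, revert_ids, remove_ids)
    }
    result$processed <- processed
    result$temperature_report <- temp_report
  }
  if ("join" %in% stages) {
    joined <- join_fulcrum(result$processed, config)
    report <- check_join(joined)
    message("join: ", nrow(joined), " rows; ", sum(report$n), " flag(s) in ",
            nrow(report), " categories")
    result$join_report <- report
    final <- joined
  }
  if ("annotate" %in% stages) {
    if (is.null(features_file)) {
      candidates <- list.files(layout$raw_annotate, pattern = "\\.geojson$",
                               full.names = TRUE)
      features_file <- if (length(candidates) > 0) candidates[1] else NULL
    }
    if (!is.null(features_file)) {
      features <- read_features(features_file)
      final <- annotate_fulcrum(final, features)
      message("annotate: ", sum(!is.na(final$location)), " of ", nrow(final),
              " rows inside a named feature")
    } else {
      final <- annotate_fulcrum(final, NULL)
      message("annotate: no feature file found; columns added empty")
    }
  }
  if ("genotype" %in% stages && !is.null(sheet)) {
    genos <- read_genotypes(sheet, schema)
    geno_report <- check_genotypes(genos, final, config)
    message("genotype: ", nrow(genos), " sheet rows; ",
            length(geno_report$only_in_sheet), " only in sheet, ",
            length(geno_report$only_in_fulcrum), " only in field data")
    final <- join_geno_fulc(genos, final, layout)
    result$genotype_report <- geno_report
  }
  if ("photos" %in% stages) {
    final <- proc_photos(final, layout, config)
    message("photos: ",
            sum(final$photo_status == "ok" &
                  !duplicated(final$collection_id)), " processed")
  }
  if ("join" %in% stages) {
    if (!dir.exists(layout$processed_fulcrum)) {
      dir.create(layout$processed_fulcrum, recursive = TRUE)
    }
    readr::write_csv(final, file.path(layout$processed_fulcrum,
                                      "joined_collections.csv"), na = "")
  }
  if ("report" %in% stages) {
    result$report_path <- generate_report(final, layout,
                                          deterministic = deterministic_report)
    message("report: ", result$report_path)
  }
  result$final <- final
  invisible(result)
}
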