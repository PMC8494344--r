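# Genotyping-sheet column contracts. The general schema is the minimal
# species-identification sheet; the nematode schema adds the lysis/genotype
# bookkeeping columns used for molecular-barcode identification.
sampleflow_genotype_columns <- list(
  general = c("project_id", "s_label", "species_id", "possible_new_sp",
              "strain_name"),
  nematode = c("project_id", "s_label", "species_id", "possible_new_sp",
               "strain_name", "proliferation", "its2_genotype", "ssu_genotype")
)

#' Read a genotyping sheet
#'
#' Reads the local CSV/TSV export of the genotyping sheet that maps S-labels
#' to species identifications obtained from molecular-barcode alignments
#' performed outside this package. Two schemas are supported: `"general"`
#' (project id, S-label, species id, possible-new-species mark, strain name)
#' and `"nematode"`, which adds proliferation, ITS2-genotype, and
#' SSU-genotype columns. The possible-new-species column holds `1` when the
#' alignment suggests a new species and is blank otherwise; blanks parse as
#' `FALSE`. S-labels are normalized (trimmed, upper-cased).
#'
#' @param source Path to a CSV (or TSV, by extension) file with a header row
#'   containing at least the schema's column names.
#' @param schema `"general"` or `"nematode"`.
#' @return A tibble of class `genotype_sheet` with one row per sheet row,
#'   `possible_new_sp` as logical and `s_label` normalized.
#' @export
read_genotypes <- function(source, schema = c("general", "nematode")) {
  schema <- match.arg(schema)
  delim <- if (grepl("\\.tsv$|\\.txt$", source, ignore.case = TRUE)) "\t" else ","
  header <- strsplit(readLines(source, n = 1), delim, fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (anyDuplicated(header) > 0) {
    abort(
      paste0("Duplicate column name(s) in genotyping sheet: ",
             paste(unique(header[duplicated(header)]), collapse = ", ")),
      class = "sampleflow_format_error"
    )
  }
  tab <- readr::read_delim(
    source, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = c(""), progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(sampleflow_genotype_columns[[schema]], names(tab))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Genotyping sheet is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "sampleflow_schema_error"
    )
  }
  s_norm <- toupper(stringr::str_squish(dplyr::coalesce(tab$s_label, "")))
  s_norm[s_norm == ""] <- NA_character_
  tab$s_label <- s_norm
  tab$possible_new_sp <-
    dplyr::coalesce(trimws(tab$possible_new_sp), "") == "1"
  attr(tab, "schema") <- schema
  class(tab) <- c("genotype_sheet", class(tab))
  tab
}

#' Check the genotyping sheet against the joined collection data
#'
#' Report-only validation of the genotyping sheet: S-labels that are missing,
#' misformatted, or duplicated within the sheet; missing species
#' identifications; missing strain names where a species was identified; and
#' (nematode schema) missing proliferation and ITS2-genotype entries. The
#' sheet is also reconciled against the joined field data: `only_in_sheet`
#' lists sheet S-labels absent from the field data and `only_in_fulcrum` the
#' reverse, so transcription disparities between the two sources surface
#' before joining.
#'
#' @param genos A `genotype_sheet` from [read_genotypes()].
#' @param joined A `joined_collection` (or the final table) carrying an
#'   `s_label` column.
#' @param config A [processing_config()] supplying the S-label grammar.
#' @return A `genotype_report`: list with a `sheet_flags` tibble (columns
#'   `flag`, `n`, `s_labels`) and character vectors `only_in_sheet` and
#'   `only_in_fulcrum`.
#' @export
check_genotypes <- function(genos, joined, config = processing_config()) {
  stopifnot(inherits(genos, "genotype_sheet"))
  schema <- attr(genos, "schema")

  flag_rows <- list()
  add_flag <- function(flag, labels) {
    labels <- labels[!is.na(labels)]
    if (length(labels) == 0 && flag != "s_label_missing") return()
    flag_rows[[length(flag_rows) + 1]] <<- tibble(
      flag = flag, n = max(length(labels), 0L),
      s_labels = paste(sort(unique(labels)), collapse = "; ")
    )
  }

  n_missing <- sum(is.na(genos$s_label))
  if (n_missing > 0) {
    flag_rows[[length(flag_rows) + 1]] <- tibble(
      flag = "s_label_missing", n = n_missing, s_labels = ""
    )
  }
  misformatted <- genos$s_label[
    !is.na(genos$s_label) &
      !stringr::str_detect(genos$s_label, config$s_label_pattern)
  ]
  add_flag("s_label_misformatted", misformatted)
  dup <- genos$s_label[!is.na(genos$s_label) & duplicated(genos$s_label)]
  add_flag("s_label_duplicated", unique(dup))
  add_flag("species_id_missing", genos$s_label[is.na(genos$species_id)])
  add_flag("strain_name_missing",
           genos$s_label[!is.na(genos$species_id) & is.na(genos$strain_name)])
  if (schema == "nematode") {
    add_flag("proliferation_missing", genos$s_label[is.na(genos$proliferation)])
    add_flag("its2_genotype_missing", genos$s_label[is.na(genos$its2_genotype)])
  }
  sheet_flags <- if (length(flag_rows) > 0) bind_rows(flag_rows) else
    tibble(flag = character(), n = integer(), s_labels = character())

  sheet_set <- unique(genos$s_label[!is.na(genos$s_label)])
  fulc_set <- unique(joined$s_label[!is.na(joined$s_label)])
  structure(
    list(
      sheet_flags = sheet_flags,
      only_in_sheet = sort(setdiff(sheet_set, fulc_set)),
      only_in_fulcrum = sort(setdiff(fulc_set, sheet_set))
    ),
    class = "genotype_report"
  )
}

#' @export
print.genotype_report <- function(x, ...) {
  cat("<genotype_report>\n")
  if (nrow(x$sheet_flags) == 0) cat("  Sheet flags: none\n")
  else {
    cat("  Sheet flags:\n")
    print(as.data.frame(x$sheet_flags), row.names = FALSE)
  }
  cat("  S-labels only in sheet:",
      if (length(x$only_in_sheet)) paste(x$only_in_sheet, collapse = ", ") else "none", "\n")
  cat("  S-labels only in field data:",
      if (length(x$only_in_fulcrum)) paste(x$only_in_fulcrum, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Join genotyping data onto the collection table
#'
#' Left join of the joined collection table onto the genotyping sheet by
#' normalized S-label: every collection row is retained, and rows whose
#' S-label is absent from the sheet keep missing genotype fields. If the
#' sheet contains a duplicated S-label, the first occurrence wins
#' (deterministically) and the affected rows are flagged with
#' `flag_genotype_duplicated`. When a project layout is supplied the result
#' is persisted to `data/processed/genotypes` as a CSV with a JSON sidecar
#' recording column types, a portable equivalent of a binary serialization.
#'
#' @param genos A `genotype_sheet`.
#' @param joined A `joined_collection` (possibly annotated).
#' @param layout Optional [project_layout()]; when given, the table is
#'   written to its `processed_genotypes` directory.
#' @return A tibble of class `final_table` with one row per input row.
#' @export
join_geno_fulc <- function(genos, joined, layout = NULL) {
  stopifnot(inherits(genos, "genotype_sheet"), inherits(joined, "joined_collection"))
  schema <- attr(genos, "schema")
  dup_labels <- unique(genos$s_label[!is.na(genos$s_label) & duplicated(genos$s_label)])
  if (length(dup_labels) > 0) {
    warn(paste0("Duplicate S-label(s) in genotyping sheet; keeping first ",
                "occurrence: ", paste(dup_labels, collapse = ", ")))
  }
  geno_cols <- setdiff(sampleflow_genotype_columns[[schema]], "s_label")
  first <- genos %>%
    filter(!is.na(.data$s_label)) %>%
    distinct(.data$s_label, .keep_all = TRUE) %>%
    select(dplyr::all_of(c("s_label", geno_cols)))

  out <- joined %>%
    left_join(first, by = "s_label") %>%
    mutate(
      possible_new_sp = dplyr::coalesce(.data$possible_new_sp, FALSE),
      flag_genotype_duplicated =
        !is.na(.data$s_label) & .data$s_label %in% dup_labels
    )
  class(out) <- c("final_table", "joined_collection", class(tibble()))

  if (!is.null(layout)) {
    stopifnot(inherits(layout, "project_layout"))
    if (!dir.exists(layout$processed_genotypes)) {
      dir.create(layout$processed_genotypes, recursive = TRUE)
    }
    csv_path <- file.path(layout$processed_genotypes, "processed_genotypes.csv")
    readr::write_csv(out, csv_path, na = "")
    types <- vapply(out, function(col) class(col)[1], character(1))
    jsonlite::write_json(
      as.list(types),
      file.path(layout$processed_genotypes, "processed_genotypes.types.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  out
}
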