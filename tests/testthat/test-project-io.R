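test_that("directory creation builds the full layout and is idempotent", {
  root <- withr::local_tempdir()
  layout <- make_directory_structure(file.path(root, "proj"))
  dirs <- setdiff(names(layout), "root")
  expect_length(dirs, 9)
  expect_true(all(dir.exists(unlist(layout[dirs]))))
  expect_true(all(startsWith(
    normalizePath(unlist(layout[dirs])),
    normalizePath(layout$root)
  )))

  before <- list.files(layout$root, recursive = TRUE, include.dirs = TRUE)
  layout2 <- make_directory_structure(file.path(root, "proj"))
  after <- list.files(layout$root, recursive = TRUE, include.dirs = TRUE)
  expect_identical(layout2, layout)
  expect_identical(before, after)
})

test_that("existing files survive directory creation", {
  root <- withr::local_tempdir()
  raw <- file.path(root, "data", "raw", "fulcrum")
  dir.create(raw, recursive = TRUE)
  keep <- file.path(raw, "keep.csv")
  writeLines("a,b\n1,2", keep)
  tree_before <- sort(list.files(root, recursive = TRUE))
  make_directory_structure(root)
  expect_true(file.exists(keep))
  expect_identical(readLines(keep), c("a,b", "1,2"))
  # nothing removed, only missing siblings added
  expect_true(all(tree_before %in% sort(list.files(root, recursive = TRUE))))
})

test_that("a root that is a regular file is rejected", {
  root <- withr::local_tempdir()
  f <- file.path(root, "not_a_dir")
  writeLines("x", f)
  expect_error(make_directory_structure(f), class = "sampleflow_invalid_path")
})

test_that("prefix detection follows the file-name convention", {
  root <- withr::local_tempdir()
  file.create(file.path(root, "nematode_field_sampling.csv"))
  expect_identical(detect_prefix(root), "nematode")

  root2 <- withr::local_tempdir()
  file.create(file.path(root2, "isopod_field_sampling.csv"))
  expect_identical(detect_prefix(root2), "isopod")

  file.create(file.path(root2, "tardigrade_field_sampling.csv"))
  err <- expect_error(detect_prefix(root2), class = "sampleflow_ambiguous_prefix")
  expect_match(conditionMessage(err), "isopod")
  expect_match(conditionMessage(err), "tardigrade")

  expect_error(detect_prefix(withr::local_tempdir()),
               class = "sampleflow_missing_export")
})

test_that("prefix detection recovers arbitrary generated prefixes", {
  for (prefix in c("nematode", "isopod", "abc123", "x")) {
    root <- withr::local_tempdir()
    layout <- make_directory_structure(root)
    generate_project(
      fixture_spec(prefix = prefix, n_collections = 3, seed = 5,
                   write_photo_files = FALSE),
      layout
    )
    expect_identical(detect_prefix(layout$raw_fulcrum), prefix)
  }
})

test_that("read_fulcrum returns a typed bundle with the isolation trio intact", {
  prj <- local_project(n_collections = 8, seed = 3, write_photo_files = FALSE)
  bundle <- read_fulcrum(prj$layout)
  expect_s3_class(bundle, "raw_bundle")
  expect_true(bundle$isolation_present)
  expect_setequal(
    intersect(names(bundle),
              c("field_sampling", "field_sampling_sample_photo", "isolation",
                "isolation_s_labeled_plates", "isolation_photos")),
    c("field_sampling", "field_sampling_sample_photo", "isolation",
      "isolation_s_labeled_plates", "isolation_photos")
  )
  expect_identical(bundle$prefix, "nematode")
  expect_equal(nrow(bundle$field_sampling), 8)
})

test_that("a field-sampling-only project reads as the isolation-absent case", {
  root <- withr::local_tempdir()
  layout <- make_directory_structure(root)
  generate_project(
    fixture_spec(n_collections = 5, seed = 4, include_isolation = FALSE,
                 write_photo_files = FALSE),
    layout
  )
  bundle <- read_fulcrum(layout)
  expect_false(bundle$isolation_present)
  expect_null(bundle[["isolation"]])
})

test_that("a partial isolation trio and missing schema columns are errors", {
  prj <- local_project(n_collections = 4, seed = 9, write_photo_files = FALSE)
  file.remove(file.path(prj$layout$raw_fulcrum, "nematode_isolation_photos.csv"))
  expect_error(read_fulcrum(prj$layout), class = "sampleflow_missing_export")

  prj2 <- local_project(n_collections = 4, seed = 9, write_photo_files = FALSE)
  fs_path <- file.path(prj2$layout$raw_fulcrum, "nematode_field_sampling.csv")
  fs <- readr::read_csv(fs_path, col_types = readr::cols(.default = "c"))
  readr::write_csv(fs[setdiff(names(fs), "c_label")], fs_path, na = "")
  err <- expect_error(read_fulcrum(prj2$layout), class = "sampleflow_schema_error")
  expect_match(conditionMessage(err), "c_label")
  expect_match(conditionMessage(err), "field_sampling")
})

test_that("every written cell is recovered on read (base-parser cross-check)", {
  prj <- local_project(n_collections = 12, seed = 21, fahrenheit_rate = 0.2,
                       missing_c_label_rate = 0.1, write_photo_files = FALSE)
  bundle <- read_fulcrum(prj$layout)
  for (role in c("field_sampling", "field_sampling_sample_photo",
                 "isolation", "isolation_s_labeled_plates")) {
    path <- file.path(prj$layout$raw_fulcrum, paste0("nematode_", role, ".csv"))
    ref <- utils::read.csv(path, colClasses = "character",
                           na.strings = "", check.names = FALSE)
    got <- as.data.frame(bundle[[role]])
    expect_identical(dim(got), dim(ref))
    expect_identical(names(got), names(ref))
    for (col in names(ref)) {
      expect_identical(got[[col]], ref[[col]],
                       label = paste(role, col, "via readr"),
                       expected.label = paste(role, col, "via base parser"))
    }
  }
})
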