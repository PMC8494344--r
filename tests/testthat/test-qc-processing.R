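test_that("temperature conversion applies strictly above the threshold", {
  expect_equal(convert_temperature(104, 40), list(value = 40, converted = TRUE))
  expect_equal(convert_temperature(40, 40), list(value = 40, converted = FALSE))
  expect_equal(convert_temperature(-5, 40), list(value = -5, converted = FALSE))
  res <- convert_temperature(c(95, NA, 20))
  expect_equal(res$value, c((95 - 32) * 5 / 9, NA, 20))
  expect_equal(res$converted, c(TRUE, FALSE, FALSE))
  expect_error(convert_temperature(c("21.5", "warm")),
               class = "sampleflow_coercion_error")
})

make_processed <- function(fs, photos = manual_photos(fs), ...) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  layout <- make_directory_structure(root)
  write_manual_project(layout, fs, photos, ...)
  proc_fulcrum(read_fulcrum(layout))
}

test_that("proc_fulcrum standardizes values, normalizes labels, keeps raw columns", {
  fs <- manual_fs(3,
                  c_label = c("c-3205 ", "C3205", NA),
                  ambient = c("75", "23.0", "21.5"))
  processed <- make_processed(fs)
  out <- processed$field_sampling

  expect_equal(out$ambient_temperature_proc[1], (75 - 32) * 5 / 9,
               tolerance = 1e-12)
  expect_true(out$flag_ambient_temperature_converted[1])
  expect_false(any(out$flag_ambient_temperature_converted[2:3]))

  expect_identical(out$c_label_proc[1], "C-3205")
  expect_false(out$flag_c_label_misformatted[1])
  expect_true(out$flag_c_label_misformatted[2])
  expect_true(out$flag_c_label_missing[3])

  # raw columns untouched
  expect_identical(out$ambient_temperature_c, fs$ambient_temperature_c)
  expect_identical(out$c_label, fs$c_label)
  expect_identical(out$date, fs$date)
  # dates/times standardized
  expect_identical(out$collection_date, as.Date(rep("2019-07-03", 3)))
  expect_identical(out$collection_time, fs$time)
})

test_that("proc_fulcrum flags invalid coordinates and bad dates without dropping rows", {
  fs <- manual_fs(2, lat = c("95.0", "21.9"), date = c("notadate", "2019-07-03"))
  processed <- make_processed(fs)
  out <- processed$field_sampling
  expect_equal(nrow(out), 2)
  expect_true(out$flag_latitude_invalid[1])
  expect_true(is.na(out$latitude_proc[1]))
  expect_true(out$flag_date_unparseable[1])
  expect_identical(out$date[1], "notadate")
})

test_that("row counts are preserved across processing for every table", {
  prj <- local_project(n_collections = 15, seed = 11, fahrenheit_rate = 0.3,
                       write_photo_files = FALSE)
  bundle <- read_fulcrum(prj$layout)
  processed <- proc_fulcrum(bundle)
  for (role in c("field_sampling", "field_sampling_sample_photo", "isolation",
                 "isolation_s_labeled_plates", "isolation_photos")) {
    expect_equal(nrow(processed[[role]]), nrow(bundle[[role]]), label = role)
  }
})

test_that("check_temperatures reports conversions with original values", {
  fs <- manual_fs(2, ambient = c("95", "22.0"))
  report <- check_temperatures(make_processed(fs))
  expect_equal(nrow(report$conversions), 1)
  expect_equal(report$conversions$raw_value, 95)
  expect_equal(report$conversions$converted_value, 35)
  expect_identical(report$conversions$field, "ambient_temperature")
})

test_that("stuck-probe runs match a brute-force scan", {
  fs <- manual_fs(4, substrate = c("20.1", "20.1", "20.1", "22"))
  report <- check_temperatures(make_processed(fs))
  sub_runs <- report$runs[report$runs$field == "substrate_temperature", ]
  expect_equal(nrow(sub_runs), 3)
  expect_setequal(sub_runs$fulcrum_id, fs$fulcrum_id[1:3])

  fs2 <- manual_fs(4, substrate = c("20", "21", "20", "21"))
  report2 <- check_temperatures(make_processed(fs2))
  expect_equal(nrow(report2$runs), 0)

  # property: random series with heavy ties vs the oracle
  withr::with_seed(99, {
    for (i in 1:20) {
      n <- sample(5:25, 1)
      vals <- sample(c(18, 19, 20, NA), n, replace = TRUE)
      fs3 <- manual_fs(n, substrate = ifelse(is.na(vals), NA, sprintf("%.1f", vals)))
      rep3 <- check_temperatures(make_processed(fs3))
      got <- fs3$fulcrum_id %in%
        rep3$runs$fulcrum_id[rep3$runs$field == "substrate_temperature"]
      # manual_fs rows are already in chronological order
      expect_identical(got, brute_force_runs(vals, 3))
    }
  })
})

test_that("fix_temperatures reverts and removes with an audit trail", {
  fs <- manual_fs(3, ambient = c("75", "22.0", "23.0"))
  processed <- make_processed(fs)

  # identity when nothing requested
  same <- fix_temperatures(processed, NULL, NULL)
  expect_identical(same$field_sampling, processed$field_sampling)

  fixed <- fix_temperatures(
    processed,
    revert_ids = data.frame(fulcrum_id = fs$fulcrum_id[1],
                            field = "ambient_temperature")
  )
  out <- fixed$field_sampling
  expect_equal(out$ambient_temperature_proc[1], 75)
  expect_false(out$flag_ambient_temperature_converted[1])
  expect_equal(fixed$audit$action, "revert_conversion")
  # the conversion no longer appears on re-check
  expect_equal(nrow(check_temperatures(fixed)$conversions), 0)

  removed <- fix_temperatures(
    fixed,
    remove_ids = data.frame(fulcrum_id = fs$fulcrum_id[2],
                            field = "ambient_temperature")
  )
  expect_true(is.na(removed$field_sampling$ambient_temperature_proc[2]))
  expect_identical(removed$audit$action, c("revert_conversion", "remove_value"))

  # revert of a non-converted field is a no-op recorded in the audit
  expect_warning(
    noop <- fix_temperatures(
      removed,
      revert_ids = data.frame(fulcrum_id = fs$fulcrum_id[3],
                              field = "ambient_temperature")
    ),
    "non-converted"
  )
  expect_equal(noop$field_sampling$ambient_temperature_proc[3], 23)
  expect_identical(utils::tail(noop$audit$action, 1), "revert_refused")

  expect_error(
    fix_temperatures(processed,
                     revert_ids = data.frame(fulcrum_id = "nope", field = "ambient_temperature")),
    class = "sampleflow_lookup_error"
  )
})

test_that("conversion then revert restores every raw value", {
  prj <- local_project(n_collections = 25, seed = 31, fahrenheit_rate = 0.4,
                       write_photo_files = FALSE)
  processed <- proc_fulcrum(read_fulcrum(prj$layout))
  conv <- check_temperatures(processed)$conversions
  expect_gt(nrow(conv), 0)
  reverted <- fix_temperatures(
    processed,
    revert_ids = data.frame(fulcrum_id = conv$fulcrum_id, field = conv$field)
  )
  fs <- reverted$field_sampling
  expect_equal(fs$ambient_temperature_proc,
               as.numeric(fs$ambient_temperature_c), tolerance = 1e-9)
  expect_equal(fs$substrate_temperature_proc,
               as.numeric(fs$substrate_temperature), tolerance = 1e-9)
})

test_that("injected Fahrenheit values are recovered with full precision and recall", {
  prj <- local_project(n_collections = 40, seed = 13, fahrenheit_rate = 0.25,
                       write_photo_files = FALSE)
  processed <- proc_fulcrum(read_fulcrum(prj$layout))
  conv <- check_temperatures(processed)$conversions
  man <- prj$manifest[prj$manifest$anomaly == "fahrenheit", ]
  got <- paste(conv$fulcrum_id, conv$field)
  want <- paste(man$record_id, sub("_c$", "", man$field))
  expect_setequal(got, want)
})
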