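test_that("best-photo selection minimizes the GPS precision estimate", {
  photos <- tibble::tibble(
    fulcrum_id = c("p1", "p2"),
    exif_gps_dop_proc = c(5, 3)
  )
  expect_identical(select_best_photo(photos)$fulcrum_id, "p2")

  single <- tibble::tibble(fulcrum_id = "p9", exif_gps_dop_proc = NA_real_)
  expect_identical(select_best_photo(single)$fulcrum_id, "p9")

  expect_null(select_best_photo(photos[0, ]))

  # tie-break and missing-as-infinity, checked by an exhaustive pair oracle
  withr::with_seed(7, {
    for (i in 1:50) {
      dops <- sample(c(1, 2, 2, NA), 3)
      ids <- sample(c("a", "b", "c"))
      ph <- tibble::tibble(fulcrum_id = ids, exif_gps_dop_proc = dops)
      got <- select_best_photo(ph)$fulcrum_id
      key <- ifelse(is.na(dops), Inf, dops)
      best <- ids[key == min(key)]
      expect_identical(got, sort(best)[1])
    }
  })
})

joined_4row_project <- function(env = parent.frame()) {
  # 3 collections: one with 2 S-labels, one with no isolation, one with 1
  root <- withr::local_tempdir(.local_envir = env)
  layout <- make_directory_structure(root)
  fs <- manual_fs(3)
  photos <- manual_photos(fs)
  iso <- tibble::tibble(
    fulcrum_id = c("iso1", "iso2"),
    c_label = fs$fulcrum_id[c(1, 3)],
    date = fs$date[c(1, 3)], time = fs$time[c(1, 3)],
    worms_on_sample = c("Yes", "Yes")
  )
  plates <- tibble::tibble(
    fulcrum_id = c("pl1", "pl2", "pl3"),
    fulcrum_parent_id = c("iso1", "iso1", "iso2"),
    s_label = c("S-0001", "S-0002", "S-0003")
  )
  iso_photos <- tibble::tibble(
    fulcrum_id = c("ip1", "ip2"), fulcrum_parent_id = c("iso1", "iso2"),
    photos = c("f1", "f2")
  )
  write_manual_project(layout, fs, photos, iso, plates, iso_photos)
  list(layout = layout, fs = fs)
}

test_that("the join emits one row per S-label and one per isolation-free collection", {
  prj <- joined_4row_project()
  joined <- join_fulcrum(proc_fulcrum(read_fulcrum(prj$layout)))
  expect_equal(nrow(joined), 4)
  expect_setequal(joined$s_label[!is.na(joined$s_label)],
                  c("S-0001", "S-0002", "S-0003"))
  no_iso <- joined[joined$collection_id == prj$fs$fulcrum_id[2], ]
  expect_equal(nrow(no_iso), 1)
  expect_true(is.na(no_iso$isolation_id))
  expect_identical(no_iso$worms_on_sample, "unknown")
  expect_setequal(unique(joined$c_label), c("C-0001", "C-0002", "C-0003"))
})

test_that("photo GPS wins location resolution, record GPS is the fallback", {
  root <- withr::local_tempdir()
  layout <- make_directory_structure(root)
  fs <- manual_fs(2)
  photos <- manual_photos(fs[1, ])
  photos$exif_gps_latitude <- "22.100000"
  photos$exif_gps_longitude <- "-159.400000"
  write_manual_project(layout, fs, photos)
  joined <- join_fulcrum(proc_fulcrum(read_fulcrum(layout)))

  with_photo <- joined[joined$collection_id == fs$fulcrum_id[1], ]
  expect_identical(with_photo$location_source, "photo")
  expect_equal(with_photo$latitude, 22.1)
  expect_equal(with_photo$longitude, -159.4)

  without <- joined[joined$collection_id == fs$fulcrum_id[2], ]
  expect_identical(without$location_source, "record")
  expect_equal(without$latitude, as.numeric(fs$latitude[2]))
  expect_true(without$flag_photo_missing)
})

test_that("location_source is none exactly when both GPS sources are missing", {
  root <- withr::local_tempdir()
  layout <- make_directory_structure(root)
  fs <- manual_fs(2, lat = c(NA, "22.0"), lon = c(NA, "-159.5"))
  write_manual_project(layout, fs, manual_photos(fs[0, ]))
  joined <- join_fulcrum(proc_fulcrum(read_fulcrum(layout)))
  expect_identical(
    joined$location_source,
    ifelse(joined$collection_id == fs$fulcrum_id[1], "none", "record")
  )
  expect_true(is.na(joined$latitude[joined$location_source == "none"]))
})

test_that("shared C-labels are flagged on every member of the duplicate group", {
  root <- withr::local_tempdir()
  layout <- make_directory_structure(root)
  fs <- manual_fs(3, c_label = c("C-0001", "C-0001", "C-0002"))
  write_manual_project(layout, fs, manual_photos(fs))
  joined <- join_fulcrum(proc_fulcrum(read_fulcrum(layout)))
  expect_identical(
    joined$flag_c_label_duplicated[match(fs$fulcrum_id, joined$collection_id)],
    c(TRUE, TRUE, FALSE)
  )
})

test_that("orphan isolations are flagged and retained, duplicate record ids abort", {
  root <- withr::local_tempdir()
  layout <- make_directory_structure(root)
  fs <- manual_fs(1)
  iso <- tibble::tibble(
    fulcrum_id = c("iso1", "iso2"),
    c_label = c(fs$fulcrum_id[1], "no-such-collection"),
    date = "2019-07-03", time = "09:00:00", worms_on_sample = "Yes"
  )
  plates <- tibble::tibble(
    fulcrum_id = c("pl1", "pl2"), fulcrum_parent_id = c("iso1", "iso2"),
    s_label = c("S-0001", "S-0002")
  )
  iso_photos <- tibble::tibble(fulcrum_id = "ip1", fulcrum_parent_id = "iso1",
                               photos = "f1")
  write_manual_project(layout, fs, manual_photos(fs), iso, plates, iso_photos)
  joined <- join_fulcrum(proc_fulcrum(read_fulcrum(layout)))
  orphan <- joined[joined$isolation_id == "iso2" & !is.na(joined$isolation_id), ]
  expect_equal(nrow(orphan), 1)
  expect_true(orphan$flag_orphan_isolation)
  expect_identical(orphan$s_label, "S-0002")

  # duplicate collection record ids violate the export contract
  fs_dup <- dplyr::bind_rows(fs, fs)
  root2 <- withr::local_tempdir()
  layout2 <- make_directory_structure(root2)
  write_manual_project(layout2, fs_dup, manual_photos(fs))
  expect_error(join_fulcrum(proc_fulcrum(read_fulcrum(layout2))),
               class = "sampleflow_integrity_error")
})

test_that("check_join is empty on clean data and names the offending file", {
  prj <- local_project(n_collections = 10, seed = 17, write_photo_files = FALSE)
  joined <- join_fulcrum(proc_fulcrum(read_fulcrum(prj$layout)))
  expect_equal(nrow(check_join(joined)), 0)

  prj2 <- local_project(n_collections = 10, seed = 17,
                        missing_s_label_rate = 0.2, write_photo_files = FALSE)
  joined2 <- join_fulcrum(proc_fulcrum(read_fulcrum(prj2$layout)))
  report <- check_join(joined2)
  expect_gt(nrow(report), 0)
  expect_identical(report$source_file[report$flag == "s_label_missing"],
                   "isolation_s_labeled_plates")
})

test_that("no C-label is lost and every S-label appears exactly once", {
  withr::with_seed(23, {
    for (i in 1:8) {
      prj <- local_project(
        n_collections = sample(4:15, 1),
        isolation_rate = runif(1, 0.3, 1),
        missing_photo_rate = runif(1, 0, 0.3),
        seed = sample.int(1e6, 1),
        write_photo_files = FALSE
      )
      bundle <- read_fulcrum(prj$layout)
      joined <- join_fulcrum(proc_fulcrum(bundle))
      expect_setequal(unique(joined$c_label),
                      unique(toupper(bundle$field_sampling$c_label)))
      plates <- bundle$isolation_s_labeled_plates$s_label
      expect_identical(sort(joined$s_label[!is.na(joined$s_label)]),
                       sort(plates))
      # cardinality: sum over collections of max(1, S-labels)
      iso_by_coll <- table(bundle$isolation$c_label)
      s_by_iso <- table(bundle$isolation_s_labeled_plates$fulcrum_parent_id)
      expected <- sum(vapply(bundle$field_sampling$fulcrum_id, function(cid) {
        iso_ids <- bundle$isolation$fulcrum_id[bundle$isolation$c_label == cid]
        n_s <- sum(vapply(iso_ids, function(i)
          max(1L, sum(bundle$isolation_s_labeled_plates$fulcrum_parent_id == i)),
          integer(1)))
        max(1L, n_s)
      }, integer(1)))
      expect_equal(nrow(joined), expected)
    }
  })
})
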