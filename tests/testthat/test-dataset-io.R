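# On-disk dataset writing, indexing, loading, participants table.

test_that("write_converted emits 2-4 files per volume as options demand", {
  d <- tempfile()
  make_megre_classic(d, parts = "mag", seed = 60L)
  g <- read_dicom_tree(d)[[1L]]
  v <- stack_volume(split_parts(g)$mag, "mag")
  spec <- detect_acquisition(g)
  main <- extract_metadata(g, spec, v)
  sp <- split_patient_fields(g$datasets[[1L]])
  extra <- list(encoding = "dicom-tags-v1", source_kind = "classic",
                headers = lapply(g$datasets, serialize_extra))
  key <- entity_key("01", "megre", part = "mag")
  root <- tempfile()
  paths <- write_converted(v, list(main = main, patient = sp$patient,
                                   extra = extra), key, root)
  expect_length(paths, 4L)
  expect_true(all(startsWith(basename(paths), "sub-01_part-mag_megre")))
  expect_true(all(file.exists(paths)))
  root2 <- tempfile()
  paths2 <- write_converted(v, list(main = main), key, root2,
                            write_patient = FALSE, write_extra = FALSE)
  expect_length(paths2, 2L)
  # collision protection, then idempotent overwrite
  expect_error(write_converted(v, list(main = main), key, root2), "overwrite")
  expect_length(write_converted(v, list(main = main), key, root2,
                                write_patient = FALSE, write_extra = FALSE,
                                overwrite = TRUE), 2L)
})

test_that("sidecar/echo-axis consistency is enforced before writing", {
  d <- tempfile()
  make_megre_classic(d, parts = "mag", seed = 61L)
  g <- read_dicom_tree(d)[[1L]]
  v <- stack_volume(split_parts(g)$mag, "mag")
  key <- entity_key("01", "megre", part = "mag")
  expect_error(
    write_converted(v, list(main = list(EchoTime = c(1, 2))), key,
                    tempfile()),
    "echo axis")
})

test_that("write then load is the identity on voxels, affine and sidecar", {
  root <- converted_root()
  idx <- load_dataset(root)
  fx <- fixture_suite()
  cases <- list(
    list(key = entity_key("01", "megre", part = "mag"), dir = "megre",
         part = "mag"),
    list(key = entity_key("01", "megre", part = "phase"), dir = "megre",
         part = "phase"),
    list(key = entity_key("01", "mese", part = "mag"), dir = "mese",
         part = "mag"),
    list(key = entity_key("01", "ct"), dir = "ct", part = "none"),
    list(key = entity_key("01", "hrpqct"), dir = "hrpqct", part = "none"),
    list(key = entity_key("01", "cr"), dir = "cr", part = "none"))
  for (case in cases) {
    groups <- read_dicom_tree(file.path(fx, case$dir))
    g <- NULL
    for (cand in groups) {
      if (mskmids:::.part_from_image_type(
            cand$frames[[1L]]$tags$image_type) == case$part ||
          case$part == "none") { g <- cand; break }
    }
    ref <- stack_volume(split_parts(g)[[case$part]], case$part)
    lv <- load_volume(idx, case$key)
    expect_identical(dim(lv$volume$voxels), dim(ref$voxels))
    expect_equal(lv$volume$voxels, ref$voxels, tolerance = 1e-5,
                 ignore_attr = TRUE)
    expect_equal(unclass(lv$volume$affine), unclass(ref$affine),
                 tolerance = 1e-5, ignore_attr = TRUE)
    expect_identical(lv$volume$part, case$part)
    expect_identical(lv$volume$dim_labels, ref$dim_labels)
    if (!is.null(ref$echo_times))
      expect_equal(lv$volume$echo_times, ref$echo_times)
    spec <- detect_acquisition(g)
    main_again <- extract_metadata(g, spec, ref)
    expect_equal(lv$sidecars$main[names(main_again)],
                 lapply(main_again, function(x)
                   if (inherits(x, "AsIs")) as.numeric(x) else x),
                 ignore_attr = TRUE)
  }
})

test_that("participants table round-trips through TSV with n/a cells", {
  root <- tempfile(); dir.create(root)
  rows <- data.frame(participant_id = c("sub-01", "sub-02"),
                     age = c(54, NA), dominant_side = c("R", "L"))
  path <- write_participants(rows, root)
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_identical(lines[1L], "participant_id\tage\tdominant_side")
  expect_true(grepl("\tn/a\t", lines[3L]))
  back <- read_participants(path)
  expect_identical(back$participant_id, rows$participant_id)
  expect_equal(back$age, rows$age)
  expect_identical(back$dominant_side, rows$dominant_side)
  expect_error(write_participants(
    data.frame(participant_id = c("sub-01", "sub-01")), root),
    "duplicate")
})

test_that("load_dataset indexes volumes and tolerates strangers", {
  root <- copy_tree(converted_root())
  writeLines("hello", file.path(root, "README"))
  idx <- load_dataset(root)
  expect_length(idx$entries, 7L)
  expect_true("README" %in% idx$unknown)
  expect_length(idx$warnings, 0L)
  # image without main sidecar is a warning, not an error
  victim <- names(idx$entries)[1L]
  file.remove(file.path(root, sub("\\.nii\\.gz$", ".json", victim)))
  idx2 <- load_dataset(root)
  expect_true(any(grepl("without main sidecar", idx2$warnings)))
  empty <- tempfile(); dir.create(empty)
  idx3 <- load_dataset(empty)
  expect_length(idx3$entries, 0L)
})

test_that("derivatives trees mirror the source layout and are not indexed", {
  d <- tempfile()
  make_ct_series(d, "ct", seed = 62L)
  g <- read_dicom_tree(d)[[1L]]
  v <- stack_volume(split_parts(g)$none, "none")
  spec <- detect_acquisition(g)
  main <- extract_metadata(g, spec, v)
  root <- tempfile()
  paths <- write_converted(v, list(main = main), entity_key("02", "ct"),
                           root, write_patient = FALSE, write_extra = FALSE,
                           derivatives = TRUE)
  expect_true(all(grepl("derivatives/sub-02/ct/", paths)))
  idx <- load_dataset(root)
  expect_length(idx$entries, 0L)
})
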