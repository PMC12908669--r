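# Acquisition detection and metadata extraction over the converter
# registry.

test_that("every fixture variant is detected by exactly one converter", {
  fx <- fixture_suite()
  expected <- c(megre = "megre", mese = "mese", ct = "ct", pcct = "pcct",
                hrpqct = "hrpqct", cr = "cr")
  registry <- converter_registry()
  for (variant in names(expected)) {
    groups <- read_dicom_tree(file.path(fx, variant))
    for (g in groups) {
      matches <- Filter(function(s) isTRUE(s$detect(g)), registry)
      # most-specific-first ordering resolves predicate subset overlap
      # (every pcct/hrpqct is also a plain ct)
      spec <- detect_acquisition(g, registry)
      expect_identical(spec$suffix, unname(expected[variant]))
      expect_identical(matches[[1L]]$suffix, spec$suffix)
    }
  }
})

test_that("single-echo or token-free MR series are skipped, not converted", {
  d <- tempfile()
  make_megre_classic(d, echo_times = 5, parts = "mag", seed = 40L)
  g <- read_dicom_tree(d)[[1L]]
  expect_null(detect_acquisition(g))
  # no sequence information at all
  for (i in seq_along(g$frames)) {
    g$frames[[i]]$tags$scanning_sequence <- NULL
    g$frames[[i]]$tags$sequence_name <- NULL
    g$frames[[i]]$tags$series_description <- NULL
  }
  expect_null(detect_acquisition(g))
})

test_that("inversion-recovery gradient-echo series are not MEGRE", {
  d <- tempfile()
  make_megre_classic(d, parts = "mag", seed = 41L)
  g <- read_dicom_tree(d)[[1L]]
  for (i in seq_along(g$frames))
    g$frames[[i]]$tags$scanning_sequence <- c("GR", "IR")
  expect_null(detect_acquisition(g))
})

test_that("DESS sequence-name tokens route to the dess converter", {
  d <- tempfile()
  make_megre_classic(d, echo_times = 5, parts = "mag", seed = 42L)
  g <- read_dicom_tree(d)[[1L]]
  for (i in seq_along(g$frames))
    g$frames[[i]]$tags$sequence_name <- "DESS3d"
  spec <- detect_acquisition(g)
  expect_identical(spec$suffix, "dess")
  v <- stack_volume(split_parts(g)$mag, "mag")
  main <- extract_metadata(g, spec, v)
  expect_identical(main$PulseSequenceType, "DESS")
})

test_that("mese metadata carries the echo array and refocusing flip angle", {
  f <- tempfile(fileext = ".dcm")
  make_mese_enhanced(f, refocusing_flip_deg = 180, seed = 43L)
  g <- explode_enhanced(read_dicom_file(f))
  spec <- detect_acquisition(g)
  expect_identical(spec$suffix, "mese")
  v <- stack_volume(split_parts(g)$mag, "mag")
  main <- extract_metadata(g, spec, v)
  expect_equal(as.numeric(main$EchoTime), c(10, 20, 30, 40, 50))
  expect_equal(main$RefocusingFlipAngle, 180)
})

test_that("ct metadata passes acquisition values through literally", {
  d <- tempfile()
  make_ct_series(d, "ct", kvp = 120, exposure_mas = 100, kernel = "B30",
                 seed = 44L)
  g <- read_dicom_tree(d)[[1L]]
  spec <- detect_acquisition(g)
  v <- stack_volume(split_parts(g)$none, "none")
  main <- extract_metadata(g, spec, v)
  expect_equal(main$XRayEnergy, 120)
  expect_equal(main$XRayExposure, 100)
  expect_identical(main$ConvolutionKernel, "B30")
  expect_equal(main$RescaleSlope, 1)
  expect_equal(main$RescaleIntercept, -1024)
})

test_that("hrpqct metadata includes the four Scanco calibration fields", {
  d <- tempfile()
  make_ct_series(d, "hrpqct", seed = 45L)
  g <- read_dicom_tree(d)[[1L]]
  spec <- detect_acquisition(g)
  v <- stack_volume(split_parts(g)$none, "none")
  main <- extract_metadata(g, spec, v)
  expect_equal(main$ScancoMuScaling, 8192)
  expect_equal(main$ScancoDensitySlope, 1603.5)
  expect_equal(main$ScancoDensityIntercept, -391.2)
  expect_equal(main$ScancoMuWater, 0.2409)
})

test_that("WaterFatShift falls back to the closed-form chemical-shift formula", {
  d <- tempfile()
  make_megre_classic(d, parts = "mag", field_T = 3, pixel_bandwidth = 434,
                     seed = 46L)
  g <- read_dicom_tree(d)[[1L]]
  spec <- detect_acquisition(g)
  v <- stack_volume(split_parts(g)$mag, "mag")
  main <- extract_metadata(g, spec, v)
  # independent hand computation: shift[Hz] = B0 * gamma * delta_ppm
  expect_equal(main$WaterFatShift, (3 * 42.577 * 3.4) / 434)
  expect_true(isTRUE(main$WaterFatShiftComputed))
  expect_equal(main$MagneticFieldStrength, 3)
  expect_equal(main$PixelBandwidth, 434)
  # vendor-provided value wins over the computation
  for (i in seq_along(g$frames)) g$frames[[i]]$tags$water_fat_shift <- 1.25
  main2 <- extract_metadata(g, spec, v)
  expect_equal(main2$WaterFatShift, 1.25)
  expect_null(main2$WaterFatShiftComputed)
})

test_that("missing required tags reject the series naming the field", {
  d <- tempfile()
  make_ct_series(d, "ct", seed = 47L)
  g <- read_dicom_tree(d)[[1L]]
  spec <- detect_acquisition(g)
  v <- stack_volume(split_parts(g)$none, "none")
  for (i in seq_along(g$frames)) g$frames[[i]]$tags$convolution_kernel <- NULL
  expect_error(extract_metadata(g, spec, v), "ConvolutionKernel")
})

test_that("registry rows reproduce the standard's modality table", {
  reg <- converter_registry()
  by_suffix <- stats::setNames(reg, vapply(reg, `[[`, character(1), "suffix"))
  expect_identical(by_suffix$ct$folder, "ct")
  expect_setequal(by_suffix$ct$required_fields,
                  c("XRayEnergy", "XRayExposure", "ConvolutionKernel",
                    "RescaleIntercept", "RescaleSlope"))
  expect_setequal(by_suffix$hrpqct$required_fields,
                  c("XRayEnergy", "XRayExposure", "ConvolutionKernel",
                    "RescaleIntercept", "RescaleSlope", "ScancoMuScaling",
                    "ScancoDensitySlope", "ScancoDensityIntercept",
                    "ScancoMuWater"))
  expect_setequal(by_suffix$cr$required_fields,
                  c("ExposureTime", "XRayTubeCurrent"))
  expect_setequal(by_suffix$megre$required_fields,
                  c("EchoTime", "WaterFatShift", "MagneticFieldStrength"))
  expect_setequal(by_suffix$mese$required_fields,
                  c("EchoTime", "RefocusingFlipAngle"))
  expect_identical(by_suffix$dess$required_fields, "PulseSequenceType")
  expect_identical(by_suffix$megre$folder, "mr-anat")
  expect_identical(by_suffix$mese$folder, "mr-anat")
  expect_identical(by_suffix$megre$dims, 4L)
  expect_identical(by_suffix$cr$dims, 2L)
  # registry suffix/folder pairs agree with the filename registry
  sreg <- suffix_registry()
  for (spec in reg) {
    row <- sreg[sreg$suffix == spec$suffix, ]
    expect_identical(spec$folder, row$folder)
  }
})

test_that("registering a plugin spec leaves built-in detection unchanged", {
  dummy <- mskmids:::.new_spec("dummy", "mr-quant", "t1",
                               function(g) {
                                 sd <- mskmids:::series_tag(g, "series_description")
                                 !is.null(sd) && grepl("DUMMYTOKEN", sd)
                               },
                               character(0), dims = 3L)
  registry <- register_converter(converter_registry(), dummy,
                                 before = "hrpqct")
  fx <- fixture_suite()
  for (variant in c("megre", "ct", "hrpqct", "cr")) {
    for (g in read_dicom_tree(file.path(fx, variant))) {
      expect_identical(detect_acquisition(g, registry)$suffix,
                       detect_acquisition(g)$suffix)
    }
  }
})
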