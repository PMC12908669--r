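# Deterministic synthetic DICOM generator: vendor-style (never forged —
# manufacturer strings say "-style-fixture") inputs for every supported
# converter, so the full pipeline is testable with no downloads. Every
# fixture embeds sentinel PHI strings so anonymization can be tested by
# grepping output bytes. Phantoms are simple two-compartment geometries
# with known relaxation constants so quantitative sanity checks (e.g. a
# T2* fit across MEGRE echoes) have a ground truth.

.SENTINEL_NAME <- "SENTINEL^PHI"
.SENTINEL_INSTITUTION <- "SENTINEL INSTITUTE OF LEAKS"
.SENTINEL_ID <- "SENTINELID9999"

.phi_block <- function(ds) {
  ds <- ds_set(ds, "PatientName", .SENTINEL_NAME)
  ds <- ds_set(ds, "PatientID", .SENTINEL_ID)
  ds <- ds_set(ds, "PatientBirthDate", "19700101")
  ds <- ds_set(ds, "PatientSex", "O")
  ds <- ds_set(ds, "PatientAge", "054Y")
  ds <- ds_set(ds, "PatientWeight", 72.5)
  ds <- ds_set(ds, "InstitutionName", .SENTINEL_INSTITUTION)
  ds <- ds_set(ds, "ReferringPhysicianName", "SENTINEL^REFERRER")
  ds <- ds_set(ds, "OperatorsName", "SENTINEL^OPERATOR")
  ds <- ds_set(ds, "StationName", "SENTINELSTN")
  ds <- ds_set(ds, "DeviceSerialNumber", "SENTINEL-SN-1234")
  ds <- ds_set(ds, "StudyDate", "20240102")
  ds <- ds_set(ds, "StudyTime", "101500")
  ds <- ds_set(ds, "AccessionNumber", "SENTACC001")
  ds <- ds_set(ds, "PatientComments", "sentinel comment field")
  ds
}

#' Sentinel PHI strings embedded in every fixture
#'
#' @return Character vector of strings that must not appear anywhere in
#'   an anonymized dataset.
#' @export
phi_sentinels <- function() {
  c(.SENTINEL_NAME, .SENTINEL_ID, .SENTINEL_INSTITUTION, "SENTINEL^REFERRER",
    "SENTINEL^OPERATOR", "SENTINELSTN", "SENTINEL-SN-1234", "SENTACC001")
}

# disk phantom: background 0, centered disk of amplitude `s0`
.disk_phantom <- function(rows, cols, s0 = 1000) {
  r0 <- rows / 2 + 0.5; c0 <- cols / 2 + 0.5
  rad <- 0.35 * min(rows, cols)
  d <- outer(seq_len(rows), seq_len(cols),
             function(r, c) sqrt((r - r0)^2 + (c - c0)^2))
  s0 * (d <= rad)
}

.disk_mask <- function(rows, cols) .disk_phantom(rows, cols, 1) > 0

.noise <- function(rows, cols, sd) {
  matrix(stats::rnorm(rows * cols, sd = sd), nrow = rows)
}

.common_image_tags <- function(ds, rows, cols, spacing, study_uid, series_uid) {
  ds <- ds_set(ds, "Rows", rows); ds <- ds_set(ds, "Columns", cols)
  ds <- ds_set(ds, "BitsAllocated", 16L)
  ds <- ds_set(ds, "BitsStored", 16L)
  ds <- ds_set(ds, "HighBit", 15L)
  ds <- ds_set(ds, "PixelRepresentation", 1L)
  ds <- ds_set(ds, "SamplesPerPixel", 1L)
  ds <- ds_set(ds, "PhotometricInterpretation", "MONOCHROME2")
  ds <- ds_set(ds, "PixelSpacing", spacing[1:2])
  ds <- ds_set(ds, "SliceThickness", spacing[3L])
  ds <- ds_set(ds, "StudyInstanceUID", study_uid)
  ds <- ds_set(ds, "SeriesInstanceUID", series_uid)
  ds <- ds_set(ds, "StudyID", "1")
  ds
}

.slice_position <- function(orientation, spacing, slice_idx, origin = c(0, 0, 0)) {
  nrm <- .slice_normal(orientation)
  origin + nrm * spacing[3L] * (slice_idx - 1L)
}

#' Generate a classic multi-echo gradient-echo (MEGRE) series
#'
#' One file per (echo, slice, part) with GE-style tags (modality MR,
#' ScanningSequence GR). The magnitude signal follows a mono-exponential
#' decay `S0 * exp(-TE / T2*)` on a disk phantom (background 0, disk
#' S0 = 1000, T2* = 20 ms) plus seeded Gaussian noise (sigma = 2% of S0),
#' quantized to int16; phase, when requested, is a linear ramp stored
#' with a rescale mapping onto `[-pi, pi]`.
#'
#' @param dir Output directory (created).
#' @param n_slices Number of slices.
#' @param echo_times Echo times in ms.
#' @param matrix_size `c(rows, cols)`.
#' @param spacing `c(row, col, slice)` spacing in mm.
#' @param orientation Six direction cosines; default axial identity.
#' @param parts Subset of `c("mag", "phase")`.
#' @param field_T Main field strength (T).
#' @param pixel_bandwidth Readout bandwidth (Hz/pixel).
#' @param t2star_ms Phantom T2* (ms).
#' @param seed RNG seed (fixtures are byte-deterministic given the seed).
#' @return `dir`, invisibly.
#' @export
make_megre_classic <- function(dir, n_slices = 4L, echo_times = c(2.4, 4.8, 7.2),
                               matrix_size = c(32L, 32L),
                               spacing = c(1.5, 1.5, 3),
                               orientation = c(1, 0, 0, 0, 1, 0),
                               parts = "mag", field_T = 3,
                               pixel_bandwidth = 434, t2star_ms = 20,
                               seed = 1L) {
  stopifnot(all(parts %in% c("mag", "phase")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  rows <- matrix_size[1L]; cols <- matrix_size[2L]
  study_uid <- dcm_uid()
  base <- .disk_phantom(rows, cols)
  k <- 0L
  for (part in parts) {
    series_uid <- dcm_uid()
    for (e in seq_along(echo_times)) {
      te <- echo_times[e]
      for (s in seq_len(n_slices)) {
        ds <- list()
        ds <- .phi_block(ds)
        ds <- ds_set(ds, "SOPClassUID", .uid_mr_storage)
        ds <- ds_set(ds, "SOPInstanceUID", dcm_uid())
        ds <- ds_set(ds, "Modality", "MR")
        ds <- ds_set(ds, "Manufacturer", "GE-style-fixture")
        ds <- ds_set(ds, "ScanningSequence", "GR")
        ds <- ds_set(ds, "SequenceVariant", "SS")
        ds <- ds_set(ds, "SeriesDescription", "AX MEGRE FIXTURE")
        ds <- ds_set(ds, "ImageType",
                     c("ORIGINAL", "PRIMARY",
                       if (part == "mag") "MAGNITUDE" else "PHASE"))
        ds <- ds_set(ds, "EchoTime", te)
        ds <- ds_set(ds, "RepetitionTime", 30)
        ds <- ds_set(ds, "FlipAngle", 12)
        ds <- ds_set(ds, "PixelBandwidth", pixel_bandwidth)
        ds <- ds_set(ds, "MagneticFieldStrength", field_T)
        ds <- .common_image_tags(ds, rows, cols, spacing, study_uid, series_uid)
        ds <- ds_set(ds, "ImageOrientationPatient", orientation)
        ds <- ds_set(ds, "ImagePositionPatient",
                     .slice_position(orientation, spacing, s))
        ds <- ds_set(ds, "InstanceNumber",
                     (e - 1L) * n_slices + s)
        if (part == "mag") {
          img <- base * exp(-te / t2star_ms) + .noise(rows, cols, 20)
          stored <- pmax(pmin(round(img), 32767), 0)
        } else {
          ramp <- outer(seq_len(rows), seq_len(cols),
                        function(r, c) (c - 1) / (cols - 1) * 8190 - 4096)
          stored <- round(ramp)
          ds <- ds_set(ds, "RescaleSlope", pi / 4096)
          ds <- ds_set(ds, "RescaleIntercept", 0)
        }
        ds <- ds_set(ds, "PixelData", .pixels_raw(stored), vr = "OW")
        k <- k + 1L
        write_dicom_file(file.path(dir,
          sprintf("megre-%s-e%02d-s%02d.dcm", part, e, s)), ds)
      }
    }
  }
  invisible(dir)
}

.fg_item <- function(...) {
  # build a single-item functional-group sequence element
  list(vr = "SQ", value = list(list(...)))
}

.el <- function(keyword, value, vr = NULL) {
  tag <- dcm_tag(keyword)
  if (is.null(vr)) vr <- dcm_vr_for_tag(tag)
  stats::setNames(list(list(vr = vr, value = value)), tag)
}

#' Generate an enhanced multi-frame MESE file
#'
#' A single Philips-style enhanced MR file: `n_echoes * n_slices` frames
#' with per-frame functional groups (effective echo time, plane position)
#' and shared groups carrying orientation, pixel measures, and the
#' echo-train (refocusing) flip angle. The phantom decays
#' mono-exponentially with T2 = 50 ms.
#'
#' @param path Output file path.
#' @param n_slices,echo_times,matrix_size,spacing,seed As in
#'   [make_megre_classic()].
#' @param refocusing_flip_deg Refocusing flip angle (degrees).
#' @param t2_ms Phantom T2 (ms).
#' @param encoding `"enhanced"` (one multi-frame file) or `"classic"`
#'   (one file per frame, same tags) — the latter exists so tests can
#'   check that both encodings of one acquisition read identically.
#' @return The written path(s), invisibly.
#' @export
make_mese_enhanced <- function(path, n_slices = 3L,
                               echo_times = c(10, 20, 30, 40, 50),
                               refocusing_flip_deg = 180,
                               matrix_size = c(32L, 32L),
                               spacing = c(1.2, 1.2, 4),
                               t2_ms = 50, seed = 2L,
                               encoding = c("enhanced", "classic")) {
  encoding <- match.arg(encoding)
  set.seed(seed)
  rows <- matrix_size[1L]; cols <- matrix_size[2L]
  orientation <- c(1, 0, 0, 0, 1, 0)
  study_uid <- dcm_uid(); series_uid <- dcm_uid()
  base <- .disk_phantom(rows, cols)
  n_echo <- length(echo_times)
  planes <- list()
  meta <- list()
  i <- 0L
  for (s in seq_len(n_slices)) {
    for (e in seq_len(n_echo)) {
      i <- i + 1L
      img <- base * exp(-echo_times[e] / t2_ms) + .noise(rows, cols, 20)
      planes[[i]] <- pmax(pmin(round(img), 32767), 0)
      meta[[i]] <- list(te = echo_times[e],
                        pos = .slice_position(orientation, spacing, s))
    }
  }
  if (encoding == "classic") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    out <- character(0)
    for (j in seq_len(i)) {
      ds <- list()
      ds <- .phi_block(ds)
      ds <- ds_set(ds, "SOPClassUID", .uid_mr_storage)
      ds <- ds_set(ds, "SOPInstanceUID", dcm_uid())
      ds <- ds_set(ds, "Modality", "MR")
      ds <- ds_set(ds, "Manufacturer", "Philips-style-fixture")
      ds <- ds_set(ds, "ScanningSequence", "SE")
      ds <- ds_set(ds, "SeriesDescription", "MESE FIXTURE")
      ds <- ds_set(ds, "ImageType", c("ORIGINAL", "PRIMARY", "MAGNITUDE"))
      ds <- ds_set(ds, "EchoTime", meta[[j]]$te)
      ds <- ds_set(ds, "RepetitionTime", 3000)
      ds <- ds_set(ds, "FlipAngle", refocusing_flip_deg)
      ds <- .common_image_tags(ds, rows, cols, spacing, study_uid, series_uid)
      ds <- ds_set(ds, "ImageOrientationPatient", orientation)
      ds <- ds_set(ds, "ImagePositionPatient", meta[[j]]$pos)
      ds <- ds_set(ds, "InstanceNumber", j)
      ds <- ds_set(ds, "PixelData", .pixels_raw(planes[[j]]), vr = "OW")
      p <- file.path(path, sprintf("mese-%03d.dcm", j))
      write_dicom_file(p, ds)
      out <- c(out, p)
    }
    return(invisible(out))
  }
  shared_item <- c(
    .el("MRTimingAndRelatedParametersSequence", list(c(
      .el("RepetitionTime", 3000),
      .el("FlipAngle", refocusing_flip_deg)))),
    .el("PlaneOrientationSequence", list(c(
      .el("ImageOrientationPatient", orientation)))),
    .el("PixelMeasuresSequence", list(c(
      .el("PixelSpacing", spacing[1:2]),
      .el("SliceThickness", spacing[3L]))))
  )
  perframe <- lapply(seq_len(i), function(j) {
    c(.el("MREchoSequence", list(c(
        .el("EffectiveEchoTime", meta[[j]]$te)))),
      .el("PlanePositionSequence", list(c(
        .el("ImagePositionPatient", meta[[j]]$pos)))),
      .el("MRImageFrameTypeSequence", list(c(
        .el("FrameType", c("ORIGINAL", "PRIMARY", "MAGNITUDE"))))))
  })
  ds <- list()
  ds <- .phi_block(ds)
  ds <- ds_set(ds, "SOPClassUID", .uid_enhanced_mr_storage)
  ds <- ds_set(ds, "SOPInstanceUID", dcm_uid())
  ds <- ds_set(ds, "Modality", "MR")
  ds <- ds_set(ds, "Manufacturer", "Philips-style-fixture")
  ds <- ds_set(ds, "EchoPulseSequence", "SPIN")
  ds <- ds_set(ds, "SeriesDescription", "MESE FIXTURE")
  ds <- ds_set(ds, "NumberOfFrames", i)
  ds <- .common_image_tags(ds, rows, cols, spacing, study_uid, series_uid)
  ds[[dcm_tag("SharedFunctionalGroupsSequence")]] <-
    list(vr = "SQ", value = list(shared_item))
  ds[[dcm_tag("PerFrameFunctionalGroupsSequence")]] <-
    list(vr = "SQ", value = perframe)
  ds <- ds_set(ds, "PixelData",
               do.call(c, lapply(planes, function(p) .pixels_raw(p))),
               vr = "OW")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_dicom_file(path, ds)
  invisible(path)
}

#' Generate a classic CT series (conventional, photon-counting or HR-pQCT)
#'
#' Water-cylinder phantom (about 0 HU) with a bone-like insert (about
#' +700 HU), stored with the given rescale so Hounsfield units come out
#' of [apply_rescale()]. The `hrpqct` variant sets a Scanco-style
#' manufacturer string and the four density-calibration private tags; the
#' `pcct` variant sets a photon-counting detector type.
#'
#' @param dir Output directory.
#' @param variant `"ct"`, `"pcct"` or `"hrpqct"`.
#' @param kvp Tube voltage (kVp).
#' @param exposure_mas Exposure (mAs).
#' @param kernel Reconstruction kernel name.
#' @param slope,intercept Rescale slope/intercept.
#' @param scanco Named list of the four Scanco calibration values (used
#'   for `variant = "hrpqct"`).
#' @param matrix_size,n_slices,spacing,seed As in [make_megre_classic()].
#' @return `dir`, invisibly.
#' @export
make_ct_series <- function(dir, variant = c("ct", "pcct", "hrpqct"),
                           kvp = 120, exposure_mas = 100, kernel = "B30",
                           slope = 1, intercept = -1024,
                           scanco = list(mu_scaling = 8192,
                                         density_slope = 1603.5,
                                         density_intercept = -391.2,
                                         mu_water = 0.2409),
                           matrix_size = c(32L, 32L), n_slices = 6L,
                           spacing = c(0.8, 0.8, 1), seed = 3L) {
  variant <- match.arg(variant)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  rows <- matrix_size[1L]; cols <- matrix_size[2L]
  orientation <- c(1, 0, 0, 0, 1, 0)
  study_uid <- dcm_uid(); series_uid <- dcm_uid()
  d <- outer(seq_len(rows), seq_len(cols),
             function(r, c) sqrt((r - rows / 2 - 0.5)^2 +
                                 (c - cols / 2 - 0.5)^2))
  water <- d <= 0.35 * min(rows, cols)   # water cylinder, ~0 HU
  insert <- d <= 0.12 * min(rows, cols)  # bone-like core, ~+700 HU
  for (s in seq_len(n_slices)) {
    hu <- matrix(-1000, rows, cols)
    hu[water] <- 0
    hu[insert] <- 700
    hu <- hu + .noise(rows, cols, 5)
    stored <- round((hu - intercept) / slope)
    ds <- list()
    ds <- .phi_block(ds)
    ds <- ds_set(ds, "SOPClassUID", .uid_ct_storage)
    ds <- ds_set(ds, "SOPInstanceUID", dcm_uid())
    ds <- ds_set(ds, "Modality", "CT")
    ds <- ds_set(ds, "Manufacturer",
                 switch(variant, hrpqct = "SCANCO-style-fixture",
                        "CT-style-fixture"))
    if (variant == "pcct")
      ds <- ds_set(ds, "DetectorType", "PHOTON_COUNTING")
    ds <- ds_set(ds, "KVP", kvp)
    ds <- ds_set(ds, "Exposure", exposure_mas)
    ds <- ds_set(ds, "ConvolutionKernel", kernel)
    ds <- ds_set(ds, "RescaleSlope", slope)
    ds <- ds_set(ds, "RescaleIntercept", intercept)
    if (variant == "hrpqct") {
      ds <- ds_set(ds, "PrivateCreator0029", "SCANCO-style-fixture")
      ds <- ds_set(ds, "ScancoMuScaling", scanco$mu_scaling)
      ds <- ds_set(ds, "ScancoDensitySlope", scanco$density_slope)
      ds <- ds_set(ds, "ScancoDensityIntercept", scanco$density_intercept)
      ds <- ds_set(ds, "ScancoMuWater", scanco$mu_water)
    }
    ds <- .common_image_tags(ds, rows, cols, spacing, study_uid, series_uid)
    ds <- ds_set(ds, "ImageOrientationPatient", orientation)
    ds <- ds_set(ds, "ImagePositionPatient",
                 .slice_position(orientation, spacing, s))
    ds <- ds_set(ds, "InstanceNumber", s)
    ds <- ds_set(ds, "PixelData", .pixels_raw(stored), vr = "OW")
    write_dicom_file(file.path(dir, sprintf("%s-s%02d.dcm", variant, s)), ds)
  }
  invisible(dir)
}

#' Generate a single computed-radiography image
#'
#' One 2D CR-modality file (projectional: no patient-space position or
#' orientation), which must convert to a 2D volume.
#'
#' @param path Output file path.
#' @param exposure_time_ms Exposure time (ms).
#' @param tube_current_mA Tube current (mA).
#' @param matrix_size,seed As in [make_megre_classic()].
#' @return `path`, invisibly.
#' @export
make_cr_image <- function(path, exposure_time_ms = 10, tube_current_mA = 200,
                          matrix_size = c(48L, 40L), seed = 4L) {
  set.seed(seed)
  rows <- matrix_size[1L]; cols <- matrix_size[2L]
  img <- .disk_phantom(rows, cols, 800) + .noise(rows, cols, 15)
  stored <- pmax(pmin(round(img), 32767), 0)
  ds <- list()
  ds <- .phi_block(ds)
  ds <- ds_set(ds, "SOPClassUID", .uid_cr_storage)
  ds <- ds_set(ds, "SOPInstanceUID", dcm_uid())
  ds <- ds_set(ds, "Modality", "CR")
  ds <- ds_set(ds, "Manufacturer", "CR-style-fixture")
  ds <- ds_set(ds, "ExposureTime", exposure_time_ms)
  ds <- ds_set(ds, "XRayTubeCurrent", tube_current_mA)
  ds <- ds_set(ds, "Rows", rows); ds <- ds_set(ds, "Columns", cols)
  ds <- ds_set(ds, "BitsAllocated", 16L)
  ds <- ds_set(ds, "BitsStored", 16L)
  ds <- ds_set(ds, "HighBit", 15L)
  ds <- ds_set(ds, "PixelRepresentation", 1L)
  ds <- ds_set(ds, "SamplesPerPixel", 1L)
  ds <- ds_set(ds, "PhotometricInterpretation", "MONOCHROME2")
  ds <- ds_set(ds, "PixelSpacing", c(0.2, 0.2))
  ds <- ds_set(ds, "StudyInstanceUID", dcm_uid())
  ds <- ds_set(ds, "SeriesInstanceUID", dcm_uid())
  ds <- ds_set(ds, "InstanceNumber", 1L)
  ds <- ds_set(ds, "PixelData", .pixels_raw(stored), vr = "OW")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_dicom_file(path, ds)
  invisible(path)
}

#' Generate the full fixture suite
#'
#' One sub-directory per supported acquisition, each convertible by the
#' built-in registry.
#'
#' @param root Output root directory.
#' @param seed Base RNG seed; per-variant seeds are derived from it.
#' @return Named character vector of fixture directories/files.
#' @export
make_fixture_suite <- function(root, seed = 1L) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  out <- c(
    megre = make_megre_classic(file.path(root, "megre"),
                               parts = c("mag", "phase"), seed = seed),
    mese = make_mese_enhanced(file.path(root, "mese", "mese.dcm"),
                              seed = seed + 1L),
    ct = make_ct_series(file.path(root, "ct"), "ct", seed = seed + 2L),
    pcct = make_ct_series(file.path(root, "pcct"), "pcct", seed = seed + 3L),
    hrpqct = make_ct_series(file.path(root, "hrpqct"), "hrpqct",
                            seed = seed + 4L),
    cr = make_cr_image(file.path(root, "cr", "cr.dcm"), seed = seed + 5L)
  )
  out
}
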