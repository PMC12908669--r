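# Normalizes classic (one frame per file) and enhanced (multi-frame)
# DICOM into a flat list of per-frame records so downstream assembly is
# encoding-agnostic.

# ---- pixel decoding ---------------------------------------------------------

.decode_pixels <- function(raw_bytes, rows, cols, signed, offset_frames = 0L) {
  nper <- rows * cols
  start <- offset_frames * nper * 2L
  seg <- raw_bytes[seq.int(start + 1L, length.out = nper * 2L)]
  v <- readBin(seg, "integer", n = nper, size = 2L, signed = signed,
               endian = "little")
  # DICOM stores row-major (row by row of the image)
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
}

# ---- frame records ----------------------------------------------------------

.simple_frame_tags <- function(ds) {
  first_or_null <- function(x) if (is.null(x) || !length(x)) NULL else x
  list(
    modality = first_or_null(ds_get(ds, "Modality")),
    manufacturer = first_or_null(ds_get(ds, "Manufacturer")),
    scanning_sequence = ds_get(ds, "ScanningSequence"),
    echo_pulse_sequence = ds_get(ds, "EchoPulseSequence"),
    sequence_name = first_or_null(ds_get(ds, "SequenceName")),
    series_description = first_or_null(ds_get(ds, "SeriesDescription")),
    image_type = ds_get(ds, "ImageType"),
    echo_time = first_or_null(ds_get(ds, "EchoTime")),
    repetition_time = first_or_null(ds_get(ds, "RepetitionTime")),
    flip_angle = first_or_null(ds_get(ds, "FlipAngle")),
    refocusing_flip_angle = NULL,
    pixel_bandwidth = first_or_null(ds_get(ds, "PixelBandwidth")),
    field_strength = first_or_null(ds_get(ds, "MagneticFieldStrength")),
    water_fat_shift = first_or_null(ds_get(ds, "WaterFatShift")),
    kvp = first_or_null(ds_get(ds, "KVP")),
    exposure_mas = first_or_null(ds_get(ds, "Exposure")),
    tube_current = first_or_null(ds_get(ds, "XRayTubeCurrent")),
    exposure_time = first_or_null(ds_get(ds, "ExposureTime")),
    convolution_kernel = first_or_null(ds_get(ds, "ConvolutionKernel")),
    detector_type = first_or_null(ds_get(ds, "DetectorType")),
    rescale_slope = first_or_null(ds_get(ds, "RescaleSlope")),
    rescale_intercept = first_or_null(ds_get(ds, "RescaleIntercept")),
    position = ds_get(ds, "ImagePositionPatient"),
    orientation = ds_get(ds, "ImageOrientationPatient"),
    pixel_spacing = ds_get(ds, "PixelSpacing"),
    slice_thickness = first_or_null(ds_get(ds, "SliceThickness")),
    instance_number = first_or_null(ds_get(ds, "InstanceNumber")),
    series_uid = first_or_null(ds_get(ds, "SeriesInstanceUID")),
    acquisition_time = first_or_null(ds_get(ds, "AcquisitionTime")),
    scanco_mu_scaling = first_or_null(ds_get(ds, "ScancoMuScaling")),
    scanco_density_slope = first_or_null(ds_get(ds, "ScancoDensitySlope")),
    scanco_density_intercept = first_or_null(ds_get(ds, "ScancoDensityIntercept")),
    scanco_mu_water = first_or_null(ds_get(ds, "ScancoMuWater"))
  )
}

.validate_frame_tags <- function(tags, where) {
  ori <- tags$orientation
  if (!is.null(ori) && length(ori)) {
    if (length(ori) != 6L)
      stop("image orientation must have 6 cosines (", where, ")")
    for (i in c(1L, 4L)) {
      nrm <- sqrt(sum(ori[i:(i + 2L)]^2))
      if (abs(nrm - 1) > 1e-3)
        stop("orientation cosines not unit-norm (", where, ")")
    }
  }
  ps <- tags$pixel_spacing
  if (!is.null(ps) && length(ps) && any(ps <= 0))
    stop("pixel spacing must be strictly positive (", where, ")")
  invisible(tags)
}

.new_frame <- function(tags, pixels, where = "frame") {
  .validate_frame_tags(tags, where)
  structure(list(tags = tags, pixels = pixels), class = "mids_frame")
}

.is_enhanced <- function(ds) {
  nf <- ds_get(ds, "NumberOfFrames")
  !is.null(ds[[dcm_tag("PerFrameFunctionalGroupsSequence")]]) &&
    !is.null(nf) && nf >= 1
}

# ---- enhanced multi-frame ---------------------------------------------------

.fg_get <- function(item, seq_kw, kw) {
  sq <- item[[dcm_tag(seq_kw)]]
  if (is.null(sq) || !length(sq$value)) return(NULL)
  v <- ds_get(sq$value[[1L]], kw)
  if (is.null(v) || !length(v)) NULL else v
}

#' Explode an enhanced multi-frame DICOM dataset into per-frame records
#'
#' Shared functional-group values apply to every frame; per-frame values
#' override them. Frame pixel planes are sliced from the single pixel
#' buffer in declared frame order.
#'
#' @param dcm A parsed file as returned by [read_dicom_file()].
#' @return A series-group list (`uid`, `frames`, `source_kind = "enhanced"`,
#'   `datasets`).
#' @export
explode_enhanced <- function(dcm) {
  ds <- dcm$dataset
  nf <- ds_get(ds, "NumberOfFrames")
  if (is.null(nf) || nf < 1) stop("enhanced dataset declares no frames")
  nf <- as.integer(nf)
  rows <- ds_get(ds, "Rows"); cols <- ds_get(ds, "Columns")
  signed <- identical(ds_get(ds, "PixelRepresentation", 0L), 1L)
  px <- ds[[dcm_tag("PixelData")]]$value
  shared_items <- ds[[dcm_tag("SharedFunctionalGroupsSequence")]]
  shared <- if (!is.null(shared_items) && length(shared_items$value))
    shared_items$value[[1L]] else list()
  perframe <- ds[[dcm_tag("PerFrameFunctionalGroupsSequence")]]$value
  if (length(perframe) != nf)
    stop("per-frame functional groups (", length(perframe),
         ") do not match declared frame count (", nf, ")")
  base <- .simple_frame_tags(ds)
  # spin-echo vendors record the echo-train (refocusing) angle in the
  # timing functional group; see vignette
  shared_overlay <- function(item, tags) {
    et <- .fg_get(item, "MREchoSequence", "EffectiveEchoTime")
    if (!is.null(et)) tags$echo_time <- et
    pos <- .fg_get(item, "PlanePositionSequence", "ImagePositionPatient")
    if (!is.null(pos)) tags$position <- pos
    ori <- .fg_get(item, "PlaneOrientationSequence", "ImageOrientationPatient")
    if (!is.null(ori)) tags$orientation <- ori
    ps <- .fg_get(item, "PixelMeasuresSequence", "PixelSpacing")
    if (!is.null(ps)) tags$pixel_spacing <- ps
    st <- .fg_get(item, "PixelMeasuresSequence", "SliceThickness")
    if (!is.null(st)) tags$slice_thickness <- st
    sl <- .fg_get(item, "PixelValueTransformationSequence", "RescaleSlope")
    if (!is.null(sl)) tags$rescale_slope <- sl
    ic <- .fg_get(item, "PixelValueTransformationSequence", "RescaleIntercept")
    if (!is.null(ic)) tags$rescale_intercept <- ic
    ft <- .fg_get(item, "MRImageFrameTypeSequence", "FrameType")
    if (!is.null(ft)) tags$image_type <- ft
    tr <- .fg_get(item, "MRTimingAndRelatedParametersSequence", "RepetitionTime")
    if (!is.null(tr)) tags$repetition_time <- tr
    fa <- .fg_get(item, "MRTimingAndRelatedParametersSequence", "FlipAngle")
    if (!is.null(fa)) tags$refocusing_flip_angle <- fa
    tags
  }
  base <- shared_overlay(shared, base)
  multi_slice <- nf > 1L
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    tags <- shared_overlay(perframe[[i]], base)
    if (multi_slice && is.null(tags$position))
      stop("missing per-frame image position for frame ", i)
    tags$instance_number <- i
    frames[[i]] <- .new_frame(tags,
                              .decode_pixels(px, rows, cols, signed, i - 1L),
                              where = paste0("frame ", i))
  }
  structure(list(uid = ds_get(ds, "SeriesInstanceUID", "unknown"),
                 frames = frames, source_kind = "enhanced",
                 datasets = list(ds), paths = dcm$path),
            class = "mids_series")
}

.classic_frame <- function(dcm) {
  ds <- dcm$dataset
  rows <- ds_get(ds, "Rows"); cols <- ds_get(ds, "Columns")
  signed <- identical(ds_get(ds, "PixelRepresentation", 0L), 1L)
  px <- ds[[dcm_tag("PixelData")]]$value
  tags <- .simple_frame_tags(ds)
  ss <- tags$scanning_sequence
  if (!is.null(ss) && any(ss == "SE"))
    tags$refocusing_flip_angle <- tags$flip_angle
  .new_frame(tags, .decode_pixels(px, rows, cols, signed), where = dcm$path)
}

#' Read a directory tree of DICOM files into series groups
#'
#' Classic files are grouped by SeriesInstanceUID and ordered by instance
#' number; each enhanced multi-frame file becomes its own series group via
#' [explode_enhanced()]. Non-DICOM files are skipped silently; files with
#' a DICOM preamble that fail to parse produce a warning and are skipped.
#'
#' @param root Directory to scan recursively.
#' @return List of series groups, ordered by series UID.
#' @export
read_dicom_tree <- function(root) {
  if (!dir.exists(root)) stop("input directory does not exist: ", root)
  files <- sort(list.files(root, recursive = TRUE, full.names = TRUE))
  files <- files[vapply(files, is_dicom_file, logical(1))]
  if (!length(files)) stop("no readable DICOM files under ", root)
  classic <- list()
  groups <- list()
  for (f in files) {
    dcm <- tryCatch(read_dicom_file(f), error = function(e) {
      warning("skipping unreadable DICOM file ", f, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(dcm)) next
    if (.is_enhanced(dcm$dataset)) {
      groups[[length(groups) + 1L]] <- explode_enhanced(dcm)
    } else {
      uid <- ds_get(dcm$dataset, "SeriesInstanceUID", "unknown")
      classic[[uid]] <- c(classic[[uid]], list(dcm))
    }
  }
  for (uid in sort(names(classic))) {
    dcms <- classic[[uid]]
    frames <- lapply(dcms, .classic_frame)
    inst <- vapply(frames, function(fr) {
      v <- fr$tags$instance_number
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    ord <- order(inst, na.last = TRUE)
    grp <- structure(list(uid = uid, frames = frames[ord],
                          source_kind = "classic",
                          datasets = lapply(dcms[ord], `[[`, "dataset"),
                          paths = vapply(dcms[ord], `[[`, character(1), "path")),
                     class = "mids_series")
    mods <- unique(vapply(grp$frames, function(fr)
      fr$tags$modality %||% "", character(1)))
    if (length(mods) > 1L)
      stop("series ", uid, " mixes modalities: ", paste(mods, collapse = ", "))
    groups[[length(groups) + 1L]] <- grp
  }
  uids <- vapply(groups, `[[`, character(1), "uid")
  if (!length(groups)) stop("no readable DICOM files under ", root)
  groups[order(uids)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

series_tag <- function(group, name) {
  for (fr in group$frames) {
    v <- fr$tags[[name]]
    if (!is.null(v)) return(v)
  }
  NULL
}

#' @export
format.mids_series <- function(x, ...) {
  paste0("<series ", x$uid, ": ", length(x$frames), " ", x$source_kind,
         " frame(s), modality ", series_tag(x, "modality") %||% "?", ">")
}

#' @export
print.mids_series <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
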