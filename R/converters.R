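# Plugin registry of acquisition converters. Each converter spec pairs a
# detection predicate over a DICOM series with the target modality
# folder, file-name suffix, required sidecar fields, and dimensionality
# contract. Detection is strict: a series matching no spec is skipped,
# never force-converted — compliance over coverage.

.GYROMAGNETIC_MHZ_PER_T <- 42.577 # proton gyromagnetic ratio
.WATER_FAT_PPM <- 3.4             # default water-fat chemical shift

.distinct_echo_times <- function(group) {
  tes <- unlist(lapply(group$frames, function(fr) fr$tags$echo_time))
  if (is.null(tes)) return(numeric(0))
  u <- sort(unique(as.numeric(tes)))
  u[c(TRUE, diff(u) > .ECHO_TOL)]
}

.mr_sequence_kind <- function(group) {
  # ScanningSequence first, then EchoPulseSequence, then sequence-name
  # tokens: vendors disagree on which field carries this
  ss <- series_tag(group, "scanning_sequence")
  if (!is.null(ss)) {
    if (any(toupper(ss) == "GR")) return("GR")
    if (any(toupper(ss) == "SE")) return("SE")
    if (any(toupper(ss) == "IR")) return("IR")
  }
  eps <- series_tag(group, "echo_pulse_sequence")
  if (!is.null(eps)) {
    if (any(toupper(eps) == "GRADIENT")) return("GR")
    if (any(toupper(eps) == "SPIN")) return("SE")
  }
  sn <- toupper(series_tag(group, "sequence_name") %||% "")
  if (grepl("GRE|FFE|GR", sn)) return("GR")
  if (grepl("SE|TSE|FSE", sn)) return("SE")
  NULL
}

.has_ir <- function(group) {
  ss <- series_tag(group, "scanning_sequence")
  !is.null(ss) && any(toupper(ss) == "IR")
}

.dess_token <- function(group) {
  toks <- toupper(paste(c(series_tag(group, "sequence_name") %||% "",
                          series_tag(group, "series_description") %||% "",
                          series_tag(group, "scanning_sequence") %||% ""),
                        collapse = " "))
  grepl("DESS|MENSA|FADE", toks)
}

.map_token <- function(group, token) {
  sd <- toupper(series_tag(group, "series_description") %||% "")
  it <- toupper(paste(series_tag(group, "image_type") %||% "", collapse = " "))
  grepl(token, sd) || grepl(token, it)
}

.new_spec <- function(name, folder, suffix, detect, required_fields,
                      optional_fields = character(0), dims) {
  structure(list(name = name, folder = folder, suffix = suffix,
                 detect = detect, required_fields = required_fields,
                 optional_fields = optional_fields, dims = dims),
            class = "mids_converter_spec")
}

.ct_fields <- c("XRayEnergy", "XRayExposure", "ConvolutionKernel",
                "RescaleIntercept", "RescaleSlope")
.scanco_fields <- c("ScancoMuScaling", "ScancoDensitySlope",
                    "ScancoDensityIntercept", "ScancoMuWater")

#' The built-in converter registry
#'
#' Ordered most-specific first (HR-pQCT and photon-counting CT before
#' plain CT; quantitative-map and DESS detection before the generic
#' multi-echo MR predicates). Each spec reproduces one "included" row of
#' the standard's modality table: folder, suffix, required JSON fields,
#' dimensionality.
#'
#' @param wt2_token Regular expression on SeriesDescription identifying
#'   water-T2 maps (no DICOM tag encodes "water T2"; site-configurable).
#' @param t1_token,t2_token Analogous tokens for T1/T2 maps.
#' @return List of converter specs.
#' @export
converter_registry <- function(wt2_token = "WT2[ _-]?MAP",
                               t1_token = "T1[ _-]?MAP",
                               t2_token = "(?<!W)T2[ _-]?MAP") {
  list(
    .new_spec("hrpqct", "ct", "hrpqct",
      function(g) identical(series_tag(g, "modality"), "CT") &&
        grepl("SCANCO", toupper(series_tag(g, "manufacturer") %||% "")),
      c(.ct_fields, .scanco_fields), dims = 3L),
    .new_spec("pcct", "ct", "pcct",
      function(g) identical(series_tag(g, "modality"), "CT") &&
        grepl("PHOTON", toupper(series_tag(g, "detector_type") %||% "")),
      .ct_fields, dims = 3L),
    .new_spec("ct", "ct", "ct",
      function(g) identical(series_tag(g, "modality"), "CT"),
      .ct_fields, dims = 3L),
    .new_spec("cr", "cr", "cr",
      function(g) (series_tag(g, "modality") %||% "") %in% c("CR", "DX"),
      c("ExposureTime", "XRayTubeCurrent"), dims = 2L),
    .new_spec("t1", "mr-quant", "t1",
      function(g) identical(series_tag(g, "modality"), "MR") &&
        .map_token(g, t1_token), character(0), dims = 3L),
    .new_spec("wt2", "mr-quant", "wt2",
      function(g) identical(series_tag(g, "modality"), "MR") &&
        .map_token(g, wt2_token), character(0), dims = 3L),
    .new_spec("t2", "mr-quant", "t2",
      function(g) identical(series_tag(g, "modality"), "MR") &&
        grepl(t2_token, toupper(series_tag(g, "series_description") %||% ""),
              perl = TRUE), character(0), dims = 3L),
    .new_spec("dess", "mr-anat", "dess",
      function(g) identical(series_tag(g, "modality"), "MR") && .dess_token(g),
      "PulseSequenceType", dims = 3L),
    .new_spec("megre", "mr-anat", "megre",
      function(g) identical(series_tag(g, "modality"), "MR") &&
        identical(.mr_sequence_kind(g), "GR") && !.has_ir(g) &&
        length(.distinct_echo_times(g)) >= 2L,
      c("EchoTime", "WaterFatShift", "MagneticFieldStrength"),
      optional_fields = c("PixelBandwidth", "WaterFatShiftComputed"),
      dims = 4L),
    .new_spec("mese", "mr-anat", "mese",
      function(g) identical(series_tag(g, "modality"), "MR") &&
        identical(.mr_sequence_kind(g), "SE") &&
        length(.distinct_echo_times(g)) >= 2L,
      c("EchoTime", "RefocusingFlipAngle"), dims = 4L)
  )
}

#' Detect the acquisition type of a series
#'
#' Runs the registry's predicates in order and returns the first match, or
#' `NULL` when nothing matches (the series is then skipped by the
#' conversion pipeline — unrecognized data are never force-converted).
#'
#' @param group Series group.
#' @param registry Converter registry; defaults to [converter_registry()].
#' @return A converter spec or `NULL`.
#' @export
detect_acquisition <- function(group, registry = converter_registry()) {
  if (!length(registry)) stop("empty converter registry")
  for (spec in registry) {
    if (isTRUE(spec$detect(group))) return(spec)
  }
  NULL
}

#' Register an additional converter spec
#'
#' Returns a new registry with `spec` inserted ahead of the built-ins it
#' should shadow (default: appended, i.e. least specific). Existing specs
#' are untouched — extension never changes built-in behavior for data the
#' new spec does not match.
#'
#' @param registry Existing registry.
#' @param spec A spec built like the registry entries
#'   (`name`, `folder`, `suffix`, `detect`, `required_fields`, `dims`).
#' @param before Optional name of the spec to insert before.
#' @return The extended registry.
#' @export
register_converter <- function(registry, spec, before = NULL) {
  if (is.null(before)) return(c(registry, list(spec)))
  at <- which(vapply(registry, `[[`, character(1), "name") == before)
  if (!length(at)) stop("no spec named '", before, "' in registry")
  append(registry, list(spec), after = at[1L] - 1L)
}

.require_tag <- function(value, field, suffix) {
  if (is.null(value) || !length(value) || all(is.na(value)))
    stop("incomplete metadata for suffix '", suffix,
         "': required field ", field, " is unobtainable")
  value
}

#' Extract the minimal interpretive sidecar for a detected series
#'
#' Populates exactly the required JSON fields of the matched converter
#' spec (plus documented optional keys), taking vendor conventions into
#' account: WaterFatShift is read from the vendor tag when present and
#' otherwise computed as the water-fat frequency shift (3.4 ppm at the
#' stated field strength, gamma = 42.577 MHz/T) divided by the pixel
#' bandwidth, flagged with `WaterFatShiftComputed = true`.
#'
#' @param group Series group.
#' @param spec Matched converter spec.
#' @param volume Assembled volume (supplies the echo-time axis).
#' @return Named list: the main sidecar payload.
#' @export
extract_metadata <- function(group, spec, volume) {
  sfx <- spec$suffix
  main <- list()
  if (sfx %in% c("ct", "pcct", "hrpqct")) {
    main$XRayEnergy <- .require_tag(series_tag(group, "kvp"), "XRayEnergy", sfx)
    main$XRayExposure <- .require_tag(series_tag(group, "exposure_mas"),
                                      "XRayExposure", sfx)
    main$ConvolutionKernel <- .require_tag(
      series_tag(group, "convolution_kernel"), "ConvolutionKernel", sfx)
    main$RescaleIntercept <- .require_tag(
      series_tag(group, "rescale_intercept") %||% 0, "RescaleIntercept", sfx)
    main$RescaleSlope <- .require_tag(
      series_tag(group, "rescale_slope") %||% 1, "RescaleSlope", sfx)
    if (sfx == "hrpqct") {
      main$ScancoMuScaling <- .require_tag(
        series_tag(group, "scanco_mu_scaling"), "ScancoMuScaling", sfx)
      main$ScancoDensitySlope <- .require_tag(
        series_tag(group, "scanco_density_slope"), "ScancoDensitySlope", sfx)
      main$ScancoDensityIntercept <- .require_tag(
        series_tag(group, "scanco_density_intercept"),
        "ScancoDensityIntercept", sfx)
      main$ScancoMuWater <- .require_tag(
        series_tag(group, "scanco_mu_water"), "ScancoMuWater", sfx)
    }
  } else if (sfx == "cr") {
    main$ExposureTime <- .require_tag(series_tag(group, "exposure_time"),
                                      "ExposureTime", sfx)
    main$XRayTubeCurrent <- .require_tag(series_tag(group, "tube_current"),
                                         "XRayTubeCurrent", sfx)
  } else if (sfx == "megre") {
    tes <- volume$echo_times %||% series_tag(group, "echo_time")
    main$EchoTime <- I(as.numeric(.require_tag(tes, "EchoTime", sfx)))
    bw <- series_tag(group, "pixel_bandwidth")
    field <- .require_tag(series_tag(group, "field_strength"),
                          "MagneticFieldStrength", sfx)
    wfs <- series_tag(group, "water_fat_shift")
    if (is.null(wfs)) {
      bw <- .require_tag(bw, "WaterFatShift (needs PixelBandwidth)", sfx)
      wfs <- field * .GYROMAGNETIC_MHZ_PER_T * .WATER_FAT_PPM / bw
      main$WaterFatShiftComputed <- TRUE
    }
    main$WaterFatShift <- wfs
    main$MagneticFieldStrength <- field
    if (!is.null(bw)) main$PixelBandwidth <- bw
  } else if (sfx == "mese") {
    tes <- volume$echo_times %||% series_tag(group, "echo_time")
    main$EchoTime <- I(as.numeric(.require_tag(tes, "EchoTime", sfx)))
    main$RefocusingFlipAngle <- .require_tag(
      series_tag(group, "refocusing_flip_angle"), "RefocusingFlipAngle", sfx)
  } else if (sfx %in% c("dess", "dess-fid", "dess_echo")) {
    main$PulseSequenceType <- "DESS"
  }
  # unit normalization: DS tags arrive as numerics already (ms, deg, kVp...)
  missing <- setdiff(spec$required_fields, names(main))
  if (length(missing))
    stop("incomplete metadata for suffix '", sfx, "': ",
         paste(missing, collapse = ", "))
  main
}

#' Required sidecar fields for a suffix
#'
#' @param suffix Acquisition suffix.
#' @param registry Converter registry.
#' @return Character vector of required JSON keys (empty for suffixes with
#'   no required fields).
#' @export
required_fields_for <- function(suffix, registry = converter_registry()) {
  for (spec in registry) if (spec$suffix == suffix) return(spec$required_fields)
  character(0)
}

.optional_fields_for <- function(suffix, registry = converter_registry()) {
  for (spec in registry) if (spec$suffix == suffix) return(spec$optional_fields)
  character(0)
}
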