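# Reconstruction of the original DICOM series from a converted volume
# plus its serialized "extra" sidecar — the bidirectionality half of the
# standard. All non-pixel tags are restored verbatim; pixel planes are
# re-derived from the voxels by inverting the stored rescale and rounding
# to the nearest stored integer (exact for unmodified integer data).
# Fresh SOP instance UIDs are generated so a PACS re-upload of processed
# data cannot collide with the originals; series/study UIDs are restored.

.invert_rescale <- function(values, slope, intercept) {
  if (is.null(slope)) slope <- 1
  if (is.null(intercept)) intercept <- 0
  as.integer(round((values - intercept) / slope))
}

.frame_plane <- function(volume, ds, tol = 1e-3) {
  # locate the (slice, echo) plane of `ds` within the volume via its
  # stored position/echo-time; returns a rows x cols stored-integer matrix
  vox <- volume$voxels
  nd <- length(dim(vox))
  e_idx <- 1L
  if (nd == 4L) {
    te <- ds_get(ds, "EchoTime")
    if (is.null(te)) stop("cannot place frame: no echo time in restored tags")
    e_idx <- which(abs(volume$echo_times - as.numeric(te)) < tol)
    if (length(e_idx) != 1L)
      stop("cannot place frame: echo time ", te, " not on the echo axis")
  }
  s_idx <- 1L
  if (nd >= 3L) {
    pos <- ds_get(ds, "ImagePositionPatient")
    if (is.null(pos)) stop("cannot place frame: no stored position")
    ras <- c(-pos[1L], -pos[2L], pos[3L])
    n_slice <- dim(vox)[3L]
    origins <- vapply(seq_len(n_slice) - 1L, function(k)
      sqrt(sum((volume$affine[1:3, ] %*% c(0, 0, k, 1) - ras)^2)), numeric(1))
    s_idx <- which.min(origins)
    if (origins[s_idx] > 0.1)
      stop("cannot place frame: stored position ", paste(pos, collapse = ","),
           " does not match any slice origin")
  }
  plane <- if (nd == 4L) vox[, , s_idx, e_idx]
           else if (nd == 3L) vox[, , s_idx]
           else vox
  sl <- ds_get(ds, "RescaleSlope", 1)
  ic <- ds_get(ds, "RescaleIntercept", 0)
  t(.matrix_of(plane)) |> .as_stored(sl, ic)
}

.matrix_of <- function(plane) matrix(plane, nrow = dim(plane)[1L])

.as_stored <- function(m, slope, intercept) {
  matrix(.invert_rescale(m, slope, intercept), nrow = nrow(m))
}

.encode_pixels <- function(m) {
  # row-major int16 little endian, as stored originally
  v <- as.integer(t(m))
  v[v < 0] <- v[v < 0] + 65536L
  writeBin(as.integer(v %% 256L + (v %/% 256L) * 256L), raw(),
           size = 2L, endian = "little")
}

.pixels_raw <- function(m) {
  v <- as.integer(t(m)) # row-major
  neg <- v < 0L
  v[neg] <- v[neg] + 65536L
  as.raw(rbind(v %% 256L, v %/% 256L))
}

#' Reconstruct a DICOM series from a converted volume
#'
#' @param volume The loaded `mids_volume` (voxels in rescaled units;
#'   phase parts are only exactly invertible when the stored rescale
#'   mapped directly into radians).
#' @param extra The extra sidecar as read from disk (serialized form,
#'   i.e. the `load_volume()` `sidecars$extra` element).
#' @param out_dir Output directory for the Part-10 files.
#' @return Character vector of written file paths (one per original
#'   classic file; a single file for enhanced sources).
#' @export
reconstruct_dicom <- function(volume, extra, out_dir) {
  if (is.null(extra)) stop("cannot round-trip: extra sidecar is missing")
  if (is.null(extra$source_kind) || is.null(extra$headers))
    stop("extra sidecar does not carry serialized DICOM headers")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kind <- extra$source_kind
  headers <- lapply(extra$headers, deserialize_extra)
  written <- character(0)
  if (kind == "classic") {
    for (idx in seq_along(headers)) {
      ds <- headers[[idx]]
      rows <- ds_get(ds, "Rows"); cols <- ds_get(ds, "Columns")
      nd <- dim(volume$voxels)
      if (cols != nd[1L] || rows != nd[2L])
        stop("shape mismatch: restored header says ", rows, "x", cols,
             " but volume plane is ", nd[2L], "x", nd[1L])
      if (length(headers) != .expected_planes(volume))
        stop("shape mismatch: ", length(headers), " stored headers vs ",
             .expected_planes(volume), " volume planes")
      plane <- .frame_plane(volume, ds)
      ds <- ds_set(ds, "PixelData", .pixels_raw(plane), vr = "OW")
      ds <- ds_set(ds, "SOPInstanceUID", dcm_uid())
      path <- file.path(out_dir, sprintf("restored-%03d.dcm", idx))
      write_dicom_file(path, ds)
      written <- c(written, path)
    }
  } else if (kind == "enhanced") {
    ds <- headers[[1L]]
    nf <- as.integer(ds_get(ds, "NumberOfFrames"))
    rows <- ds_get(ds, "Rows"); cols <- ds_get(ds, "Columns")
    nd <- dim(volume$voxels)
    if (cols != nd[1L] || rows != nd[2L] || nf != .expected_planes(volume))
      stop("shape mismatch: enhanced header declares ", nf, " frames of ",
           rows, "x", cols, ", volume has ", .expected_planes(volume),
           " planes of ", nd[2L], "x", nd[1L])
    perframe <- ds[[dcm_tag("PerFrameFunctionalGroupsSequence")]]$value
    buf <- raw(0)
    bufs <- vector("list", nf)
    for (i in seq_len(nf)) {
      item <- perframe[[i]]
      fake <- list()
      pos <- .fg_get(item, "PlanePositionSequence", "ImagePositionPatient")
      te <- .fg_get(item, "MREchoSequence", "EffectiveEchoTime")
      sl <- .fg_get(item, "PixelValueTransformationSequence", "RescaleSlope")
      ic <- .fg_get(item, "PixelValueTransformationSequence",
                    "RescaleIntercept")
      shared <- ds[[dcm_tag("SharedFunctionalGroupsSequence")]]$value
      if (length(shared)) {
        sh <- shared[[1L]]
        if (is.null(sl)) sl <- .fg_get(sh, "PixelValueTransformationSequence",
                                       "RescaleSlope")
        if (is.null(ic)) ic <- .fg_get(sh, "PixelValueTransformationSequence",
                                       "RescaleIntercept")
        if (is.null(te)) te <- .fg_get(sh, "MREchoSequence",
                                       "EffectiveEchoTime")
      }
      if (!is.null(pos)) fake <- ds_set(fake, "ImagePositionPatient", pos)
      if (!is.null(te)) fake <- ds_set(fake, "EchoTime", te)
      fake <- ds_set(fake, "RescaleSlope", sl %||% 1)
      fake <- ds_set(fake, "RescaleIntercept", ic %||% 0)
      bufs[[i]] <- .pixels_raw(.frame_plane(volume, fake))
    }
    ds <- ds_set(ds, "PixelData", do.call(c, bufs), vr = "OW")
    ds <- ds_set(ds, "SOPInstanceUID", dcm_uid())
    path <- file.path(out_dir, "restored-enhanced.dcm")
    write_dicom_file(path, ds)
    written <- path
  } else {
    stop("unknown source kind in extra sidecar: ", kind)
  }
  written
}

.expected_planes <- function(volume) {
  d <- dim(volume$voxels)
  if (length(d) <= 2L) 1L else prod(d[-(1:2)])
}
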