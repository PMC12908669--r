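# Assembles series groups into part-separated image volumes with echoes
# stacked on the 4th axis (the MSK convention: the 4th NIfTI dimension
# holds echoes, not time).

.ECHO_TOL <- 1e-3 # ms; vendor headers jitter below this

.part_from_image_type <- function(image_type) {
  if (is.null(image_type)) return("none")
  it <- toupper(image_type)
  if (any(it %in% c("MAGNITUDE", "M", "M_SE", "M_GR"))) return("mag")
  if (any(it %in% c("PHASE", "P", "P_SE", "P_GR"))) return("phase")
  if (any(it %in% c("REAL", "R"))) return("real")
  if (any(it %in% c("IMAGINARY", "I", "IMAG"))) return("imag")
  "none"
}

#' Partition a series' frames by complex part
#'
#' MR frames are split on the complex-component token of their ImageType
#' (or enhanced FrameType): MAGNITUDE, PHASE, REAL, IMAGINARY. Frames with
#' no token fall under part `"none"`; non-MR series are always
#' `list(none = frames)`. The partition is exhaustive and disjoint.
#'
#' @param group A series group from [read_dicom_tree()].
#' @return Named list mapping part label to a list of frame records.
#' @export
split_parts <- function(group) {
  modality <- series_tag(group, "modality") %||% ""
  if (modality != "MR")
    return(list(none = group$frames))
  parts <- vapply(group$frames, function(fr)
    .part_from_image_type(fr$tags$image_type), character(1))
  if ("none" %in% parts && length(unique(parts)) > 1L)
    stop("ambiguous complex parts: some frames carry no part token while ",
         "others do")
  out <- split(group$frames, parts)
  out[unique(parts)] # stable, first-appearance order
}

.group_echoes <- function(tes) {
  # cluster echo times within tolerance; returns integer group ids in
  # ascending echo-time order
  if (all(is.na(tes))) return(list(ids = rep(1L, length(tes)), times = NA_real_))
  u <- sort(unique(tes))
  reps <- u[c(TRUE, diff(u) > .ECHO_TOL)]
  ids <- vapply(tes, function(t) which.min(abs(reps - t)), integer(1))
  list(ids = ids, times = reps)
}

#' Stack a list of same-part frames into an image volume
#'
#' Frames are grouped by distinct echo time (ascending, with a tolerance
#' for header jitter) and, within each echo, sorted along the slice
#' normal. The result is 3D for a single echo and 4D `(x, y, z, echo)` for
#' multi-echo series; plain projectional images (no patient geometry,
#' single frame) yield a 2D volume. The DICOM rescale is applied; phase
#' parts are converted to radians via [scale_phase()].
#'
#' @param frames List of frame records, all of one part.
#' @param part Part label (`mag`, `phase`, `real`, `imag`, `none`).
#' @return An object of class `mids_volume` with fields `voxels`, `affine`,
#'   `dim_labels`, `part`, `dtype_hint`, `echo_times` (ms, matching the 4th
#'   axis) and `n_source_frames`.
#' @export
stack_volume <- function(frames, part = "none") {
  if (!length(frames)) stop("no frames to stack")
  tes <- vapply(frames, function(fr)
    as.numeric(fr$tags$echo_time %||% NA_real_), numeric(1))
  modality <- frames[[1L]]$tags$modality %||% ""
  if (modality == "MR" && sum(!is.na(unique(tes))) > 1L && anyNA(tes))
    stop("multi-echo series with frames lacking an echo time")
  eg <- .group_echoes(tes)
  n_echo <- max(eg$ids)
  planar <- is.null(frames[[1L]]$tags$position) ||
    is.null(frames[[1L]]$tags$orientation)
  if (planar && length(frames) > 1L)
    stop("multiple frames but no patient-space geometry")

  by_echo <- split(frames, factor(eg$ids, levels = seq_len(n_echo)))
  counts <- lengths(by_echo)
  if (length(unique(counts)) > 1L)
    stop("ragged acquisition: echoes have unequal slice counts (",
         paste(counts, collapse = ", "), ")")
  n_slice <- counts[[1L]]

  sorted <- lapply(by_echo, function(fs) {
    if (planar) return(fs)
    fs <- .sort_slices(fs)
    if (n_slice > 1L) {
      nrm <- .slice_normal(fs[[1L]]$tags$orientation)
      proj <- vapply(fs, function(fr) sum(fr$tags$position * nrm), numeric(1))
      if (any(diff(proj) < 1e-6))
        stop("duplicate (echo, position) frames in series")
    }
    fs
  })

  first <- sorted[[1L]][[1L]]
  rows <- nrow(first$pixels); cols <- ncol(first$pixels)
  vox <- array(0, dim = c(cols, rows, n_slice, n_echo))
  identity_rescale <- TRUE
  for (e in seq_len(n_echo)) {
    for (s in seq_len(n_slice)) {
      fr <- sorted[[e]][[s]]
      sl <- fr$tags$rescale_slope %||% 1
      ic <- fr$tags$rescale_intercept %||% 0
      vals <- if (part == "phase") scale_phase(fr$pixels, sl, ic)
              else apply_rescale(fr$pixels, sl, ic)
      if (!(sl == 1 && ic == 0) || part == "phase") identity_rescale <- FALSE
      vox[, , s, e] <- t(matrix(vals, nrow = rows))
    }
  }
  affine <- if (planar) .planar_affine(first$tags$pixel_spacing)
            else compute_affine(sorted[[1L]])
  echo_times <- if (n_echo > 1L) eg$times else NULL
  if (planar) {
    vox <- array(vox, dim = c(cols, rows))
    labels <- c("x", "y")
  } else if (n_echo == 1L) {
    vox <- array(vox, dim = c(cols, rows, n_slice))
    labels <- c("x", "y", "z")
  } else {
    labels <- c("x", "y", "z", "echo")
  }
  new_volume(voxels = vox, affine = affine, dim_labels = labels, part = part,
             dtype_hint = if (identity_rescale) "int16" else "float32",
             echo_times = echo_times, n_source_frames = length(frames))
}

#' Construct an image volume
#'
#' Low-level constructor enforcing the volume invariants: one axis label
#' per voxel axis, a nonsingular affine, phase values within `[-pi, pi]`,
#' and a 4th axis drawn from the allowed label set.
#'
#' @param voxels Numeric array with 2-4 axes.
#' @param affine 4x4 RAS affine.
#' @param dim_labels Axis names from `x, y, z, echo, time, direction, label`.
#' @param part Complex-part label or `"none"`.
#' @param dtype_hint Storage kind (`"int16"` or `"float32"`).
#' @param echo_times Optional numeric vector of echo times (ms) matching
#'   the 4th axis.
#' @param n_source_frames Number of source DICOM frames.
#' @return A `mids_volume`.
#' @export
new_volume <- function(voxels, affine, dim_labels, part = "none",
                       dtype_hint = "float32", echo_times = NULL,
                       n_source_frames = NA_integer_) {
  nd <- length(dim(voxels))
  if (!nd %in% 2:4) stop("volume must have 2-4 axes, got ", nd)
  if (length(dim_labels) != nd)
    stop("dim_labels length (", length(dim_labels),
         ") must equal number of voxel axes (", nd, ")")
  ok <- c("x", "y", "z", "echo", "time", "direction", "label")
  if (!all(dim_labels %in% ok)) stop("invalid axis label")
  if (nd == 4L && !dim_labels[4L] %in% c("echo", "time", "direction", "label"))
    stop("4th axis must be echo, time, direction or label")
  if (!part %in% c("mag", "phase", "real", "imag", "none"))
    stop("invalid part label: ", part)
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine upper-left 3x3 block is singular")
  if (part == "phase" &&
      (min(voxels) < -pi - 1e-6 || max(voxels) > pi + 1e-6))
    stop("phase voxels outside [-pi, pi]")
  if (!is.null(echo_times)) {
    if (nd == 4L && length(echo_times) != dim(voxels)[4L])
      stop("echo_times length must match 4th axis")
    if (is.unsorted(echo_times, strictly = TRUE))
      stop("echo_times must be strictly increasing")
  }
  structure(list(voxels = voxels, affine = affine, dim_labels = dim_labels,
                 part = part, dtype_hint = dtype_hint,
                 echo_times = echo_times,
                 n_source_frames = n_source_frames),
            class = "mids_volume")
}

#' @export
format.mids_volume <- function(x, ...) {
  paste0("<volume ", paste(dim(x$voxels), collapse = "x"),
         " [", paste(x$dim_labels, collapse = ","), "] part-", x$part,
         if (!is.null(x$echo_times))
           paste0(" TE=", paste(x$echo_times, collapse = ",")), ">")
}

#' @export
print.mids_volume <- function(x, ...) { cat(format(x), "\n"); invisible(x) }
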