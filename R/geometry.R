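# Patient-space geometry. DICOM stores LPS coordinates with the image
# orientation as six direction cosines (row direction, then column
# direction); NIfTI wants an RAS affine. Voxel index convention here is
# (i, j, k) = (column, row, slice), zero-based, matching NIfTI's
# x-fastest storage, and the LPS->RAS flip is applied once, to the affine
# only — voxel data are never reordered.

.ORIENT_TOL <- 1e-3   # per-cosine consistency across frames
.SPACING_TOL <- 0.01  # max/min inter-slice gap ratio - 1

.slice_normal <- function(ori) {
  r <- ori[1:3]; c_ <- ori[4:6]
  c(r[2] * c_[3] - r[3] * c_[2],
    r[3] * c_[1] - r[1] * c_[3],
    r[1] * c_[2] - r[2] * c_[1])
}

.sort_slices <- function(frames) {
  ori <- frames[[1L]]$tags$orientation
  nrm <- .slice_normal(ori)
  proj <- vapply(frames, function(fr) sum(fr$tags$position * nrm), numeric(1))
  inst <- vapply(frames, function(fr)
    as.numeric(fr$tags$instance_number %||% NA_real_), numeric(1))
  frames[order(proj, inst, na.last = TRUE)]
}

#' Compute the RAS affine of an ordered slice stack
#'
#' Builds the standard DICOM LPS voxel-to-patient mapping (origin at the
#' first slice's ImagePositionPatient; in-plane axes from the orientation
#' cosines scaled by pixel spacing; through-plane axis from the
#' displacement between consecutive slice origins, or normal x slice
#' thickness for a single slice) and converts it to RAS by negating the
#' first two coordinate rows.
#'
#' @param frames List of frame records covering distinct slice positions;
#'   sorted internally along the slice normal.
#' @return A 4x4 RAS affine matrix (class `mids_affine`).
#' @export
compute_affine <- function(frames) {
  if (!length(frames)) stop("no frames to compute geometry from")
  ori <- frames[[1L]]$tags$orientation
  if (is.null(ori)) stop("frames carry no image orientation")
  for (fr in frames) {
    if (max(abs(fr$tags$orientation - ori)) > .ORIENT_TOL)
      stop("inconsistent image orientation across frames")
  }
  frames <- .sort_slices(frames)
  ps <- frames[[1L]]$tags$pixel_spacing # (row spacing, column spacing)
  if (is.null(ps) || length(ps) != 2L) stop("frames carry no pixel spacing")
  p0 <- frames[[1L]]$tags$position
  rowdir <- ori[1:3]   # direction of increasing column index i
  coldir <- ori[4:6]   # direction of increasing row index j
  n <- length(frames)
  if (n > 1L) {
    pos <- t(vapply(frames, function(fr) fr$tags$position, numeric(3)))
    gaps <- sqrt(rowSums((pos[-1L, , drop = FALSE] -
                            pos[-n, , drop = FALSE])^2))
    if (min(gaps) <= 0) stop("duplicate slice positions in stack")
    if (max(gaps) / min(gaps) > 1 + .SPACING_TOL)
      stop("non-uniform slice spacing (gap ratio ",
           format(max(gaps) / min(gaps), digits = 4), ")")
    kdir <- (pos[n, ] - pos[1L, ]) / (n - 1L)
  } else {
    st <- frames[[1L]]$tags$slice_thickness
    if (is.null(st) || !length(st) || st <= 0)
      stop("single slice with no slice thickness: geometry is degenerate")
    kdir <- .slice_normal(ori) * st
  }
  m <- cbind(rowdir * ps[2L], coldir * ps[1L], kdir, p0)
  m <- rbind(m, c(0, 0, 0, 1))
  m[1:2, ] <- -m[1:2, ] # LPS -> RAS
  if (abs(det(m[1:3, 1:3])) < 1e-12) stop("degenerate affine (singular 3x3 block)")
  structure(m, class = c("mids_affine", "matrix", "array"))
}

# affine for projectional (2D) images with no patient-space geometry:
# index scaling by pixel spacing only.
.planar_affine <- function(pixel_spacing) {
  ps <- pixel_spacing %||% c(1, 1)
  m <- diag(c(-ps[2L], -ps[1L], 1, 1))
  structure(m, class = c("mids_affine", "matrix", "array"))
}

#' Apply the DICOM linear rescale to stored pixel values
#'
#' @param stored Numeric array of stored values.
#' @param slope,intercept Rescale slope/intercept; defaults `(1, 0)` stand
#'   in for absent tags.
#' @return Floating-point array `slope * stored + intercept`.
#' @export
apply_rescale <- function(stored, slope = 1, intercept = 0) {
  if (is.null(slope)) slope <- 1
  if (is.null(intercept)) intercept <- 0
  if (slope == 0) stop("invalid rescale: slope must be nonzero")
  slope * as.numeric(stored) + intercept
}

#' Map stored phase values onto radians in [-pi, pi]
#'
#' Applies the linear rescale, then — when the rescaled range is not
#' already inside `[-pi, pi]` — linearly maps the stored range so that its
#' minimum lands on `-pi` and its maximum on `pi`. Vendors store phase in
#' arbitrary integer ranges; this default heuristic is overridable per
#' converter.
#'
#' @param stored Stored pixel array.
#' @param slope,intercept Rescale parameters.
#' @param vendor Unused by the default heuristic; kept so converter
#'   plugins can dispatch vendor-specific scalings.
#' @return Array of phase values in radians.
#' @export
scale_phase <- function(stored, slope = 1, intercept = 0, vendor = "") {
  x <- apply_rescale(stored, slope, intercept)
  lo <- min(x); hi <- max(x)
  tol <- 1e-6
  if (lo >= -pi - tol && hi <= pi + tol) {
    x[x > pi] <- pi
    x[x < -pi] <- -pi
    return(x)
  }
  if (hi - lo <= 0)
    stop("constant phase plane outside [-pi, pi] cannot be scaled")
  (x - lo) / (hi - lo) * (2 * pi) - pi
}
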