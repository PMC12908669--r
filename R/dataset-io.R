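# Writing and reading the on-disk dataset: gzipped NIfTI-1 volumes with
# sform/qform set from the RAS affine, up to three JSON sidecars per
# volume, and the participants.tsv table. JSON is written UTF-8 with
# 2-space indentation and stable key order so curated datasets diff
# cleanly under version control.

.write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = 2,
                       null = "null")
  invisible(path)
}

.read_json_file <- function(path, simplify = TRUE) {
  jsonlite::read_json(path, simplifyVector = simplify)
}

#' Write one converted volume and its sidecars
#'
#' Writes the gzipped NIfTI file at [compose_filename()] under `root`,
#' always writes the main sidecar, and writes the patient/extra sidecars
#' when enabled and present. Re-running with `overwrite = TRUE` is
#' idempotent.
#'
#' @param volume A `mids_volume`.
#' @param sidecars List with elements `main` (required), `patient`,
#'   `extra` (optional).
#' @param key An [entity_key()].
#' @param root Dataset root directory.
#' @param write_patient,write_extra Whether to emit the optional sidecars.
#' @param overwrite Allow replacing existing files.
#' @param derivatives Write under the `derivatives/` subtree (same
#'   subject/session layout) instead of the source tree.
#' @return Character vector of written paths (2-4 files).
#' @export
write_converted <- function(volume, sidecars, key, root,
                            write_patient = TRUE, write_extra = TRUE,
                            overwrite = FALSE, derivatives = FALSE) {
  stopifnot(inherits(volume, "mids_volume"), inherits(key, "mids_key"))
  main <- sidecars$main
  if (is.null(main)) stop("main sidecar is required")
  et <- main$EchoTime
  if (!is.null(et) && length(et) > 1L) {
    if (length(volume$dim_labels) < 4L ||
        dim(volume$voxels)[4L] != length(et))
      stop("EchoTime length (", length(et),
           ") does not match the volume's echo axis")
  }
  base <- if (derivatives) file.path(root, "derivatives") else root
  rel <- compose_filename(key, ".nii.gz")
  img_path <- file.path(base, rel)
  dir.create(dirname(img_path), recursive = TRUE, showWarnings = FALSE)
  targets <- img_path
  if (!overwrite && file.exists(img_path))
    stop("refusing to overwrite existing file: ", img_path)

  img <- RNifti::asNifti(.storage_cast(volume))
  aff <- matrix(as.numeric(volume$affine), 4L, 4L)
  nd <- length(dim(volume$voxels))
  # pixdim (full length, one per axis) must be set before the quaternion
  # form, which factors the grid spacing out of the rotation
  pd <- c(sqrt(colSums(aff[1:3, 1:3]^2)), rep(1, 4L))[seq_len(nd)]
  img <- RNifti::`pixdim<-`(img, pd)
  img <- RNifti::`qform<-`(img, structure(aff, code = 1L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, img_path)

  main_path <- file.path(base, compose_filename(key, ".json"))
  if (!overwrite && file.exists(main_path))
    stop("refusing to overwrite existing file: ", main_path)
  .write_json_file(main, main_path)
  targets <- c(targets, main_path)

  if (write_patient && !is.null(sidecars$patient) &&
      length(sidecars$patient)) {
    p <- file.path(base, compose_filename(key, "_patient.json"))
    .write_json_file(sidecars$patient, p)
    targets <- c(targets, p)
  }
  if (write_extra && !is.null(sidecars$extra)) {
    p <- file.path(base, compose_filename(key, "_extra.json"))
    .write_json_file(sidecars$extra, p)
    targets <- c(targets, p)
  }
  targets
}

.storage_cast <- function(volume) {
  if (volume$dtype_hint == "int16") {
    storage.mode(volume$voxels) <- "integer"
    volume$voxels
  } else {
    volume$voxels
  }
}

#' Write the participants table
#'
#' BIDS-dialect TSV: tab separators, first column `participant_id`
#' (values `sub-<label>`), missing cells as `"n/a"`, stable column order.
#'
#' @param rows data.frame with column `participant_id` plus free-form
#'   health-data columns.
#' @param root Dataset root.
#' @return Path of the written file.
#' @export
write_participants <- function(rows, root) {
  stopifnot(is.data.frame(rows), "participant_id" %in% names(rows))
  if (anyDuplicated(rows$participant_id))
    stop("duplicate participant_id in participants table")
  rows <- rows[c("participant_id", setdiff(names(rows), "participant_id"))]
  m <- as.matrix(format(rows, trim = TRUE))
  m[is.na(rows) | m == "NA"] <- "n/a"
  path <- file.path(root, "participants.tsv")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(m), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) writeLines(paste(m[i, ], collapse = "\t"), con)
  path
}

#' Read a participants.tsv table
#'
#' @param path Path to the TSV file.
#' @return data.frame with `"n/a"` cells restored to `NA`.
#' @export
read_participants <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  df[df == "n/a"] <- NA
  for (j in setdiff(names(df), "participant_id")) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num[!is.na(df[[j]])])) df[[j]] <- num
  }
  df
}

#' Index an existing dataset tree
#'
#' Walks the tree, parses every filename, and pairs image files with
#' their sidecars. Unknown files are listed separately, images lacking a
#' main sidecar are recorded as warnings; neither is fatal.
#'
#' @param root Dataset root.
#' @return A `mids_index`: `entries` (list with `key`, `image`, `sidecars`),
#'   `participants` (data.frame or NULL), `unknown`, `warnings`, `root`.
#' @export
load_dataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  files <- list.files(root, recursive = TRUE, full.names = FALSE)
  files <- files[!startsWith(files, "derivatives/")]
  entries <- list()
  unknown <- character(0)
  warnings <- character(0)
  imgs <- files[endsWith(files, ".nii.gz")]
  for (rel in imgs) {
    key <- tryCatch(parse_filename(rel), error = function(e) NULL)
    if (is.null(key)) { unknown <- c(unknown, rel); next }
    base <- substr(rel, 1L, nchar(rel) - nchar(".nii.gz"))
    sc <- c(main = paste0(base, ".json"),
            patient = paste0(base, "_patient.json"),
            extra = paste0(base, "_extra.json"))
    present <- vapply(sc, function(p)
      file.exists(file.path(root, p)), logical(1))
    if (!present[["main"]])
      warnings <- c(warnings, paste0("image without main sidecar: ", rel))
    entries[[rel]] <- list(key = key, image = rel,
                           sidecars = as.list(sc[present]))
  }
  nonimg <- setdiff(files, c(imgs, "participants.tsv"))
  sidecarish <- unlist(lapply(entries, function(e) unlist(e$sidecars)),
                       use.names = FALSE)
  unknown <- c(unknown, setdiff(nonimg, sidecarish))
  participants <- NULL
  ppath <- file.path(root, "participants.tsv")
  if (file.exists(ppath)) {
    participants <- read_participants(ppath)
    subj <- unique(vapply(entries, function(e)
      paste0("sub-", e$key$subject), character(1)))
    miss <- setdiff(subj, participants$participant_id)
    if (length(subj) && length(miss))
      warnings <- c(warnings,
                    paste0("subjects missing from participants.tsv: ",
                           paste(miss, collapse = ", ")))
  }
  structure(list(root = root, entries = entries, participants = participants,
                 unknown = unknown, warnings = warnings),
            class = "mids_index")
}

#' @export
format.mids_index <- function(x, ...) {
  paste0("<dataset ", x$root, ": ", length(x$entries), " volume(s), ",
         length(x$unknown), " unknown file(s)>")
}

#' @export
print.mids_index <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

.match_entry <- function(index, key) {
  rel <- compose_filename(key, ".nii.gz")
  e <- index$entries[[rel]]
  if (is.null(e)) stop("no such volume in dataset: ", rel)
  e
}

#' Load one volume and its sidecars from an indexed dataset
#'
#' Voxels and affine come from the NIfTI file; part and suffix are
#' re-derived from the filename; the 4th axis is labelled `echo` when the
#' main sidecar carries an EchoTime array.
#'
#' @param index A `mids_index` from [load_dataset()].
#' @param key The [entity_key()] to load.
#' @return `list(volume = <mids_volume>, sidecars = list(main, patient,
#'   extra))` (`extra` still in serialized form).
#' @export
load_volume <- function(index, key) {
  e <- .match_entry(index, key)
  img <- RNifti::readNifti(file.path(index$root, e$image))
  vox <- array(as.numeric(img), dim = dim(img))
  affine <- structure(unclass(RNifti::xform(img)),
                      class = c("mids_affine", "matrix", "array"))
  main <- .read_json_file(file.path(index$root, e$sidecars$main))
  et <- main$EchoTime
  nd <- length(dim(vox))
  labels <- switch(as.character(nd),
                   "2" = c("x", "y"),
                   "3" = c("x", "y", "z"),
                   "4" = c("x", "y", "z",
                           if (!is.null(et) && length(et) > 1L) "echo"
                           else "time"))
  patient <- NULL
  if (!is.null(e$sidecars$patient))
    patient <- .read_json_file(file.path(index$root, e$sidecars$patient))
  extra <- NULL
  if (!is.null(e$sidecars$extra))
    extra <- .read_json_file(file.path(index$root, e$sidecars$extra),
                             simplify = FALSE)
  vol <- new_volume(voxels = vox, affine = affine, dim_labels = labels,
                    part = key$part %||% "none",
                    dtype_hint = if (is.integer(img[1])) "int16" else "float32",
                    echo_times = if (!is.null(et) && length(et) > 1L)
                      as.numeric(et) else NULL)
  list(volume = vol, sidecars = list(main = main, patient = patient,
                                     extra = extra))
}
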