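# End-to-end conversion: read -> detect -> assemble -> extract -> split
# -> write, per series, with per-series disposition reporting. This is
# the function the command-line front end wraps.

.series_extra_payload <- function(group, frame_idx, anonymize) {
  headers <- if (group$source_kind == "enhanced") group$datasets
             else group$datasets[frame_idx]
  headers <- lapply(headers, function(ds) {
    if (anonymize) ds <- scrub_patient_tags(ds)
    serialize_extra(ds)
  })
  list(encoding = "dicom-tags-v1", source_kind = group$source_kind,
       headers = headers)
}

#' Convert a directory of DICOM series into a standards-compliant dataset
#'
#' Every readable series is matched against the converter registry;
#' recognized series are assembled into part-separated volumes (echoes on
#' the 4th axis), their interpretive sidecar extracted, the full header
#' split into patient and extra sidecars, and everything written under
#' `out_root`. Unrecognized series are skipped, never force-converted.
#'
#' @param in_dir Directory of DICOM files.
#' @param out_root Output dataset root.
#' @param subject Participant label for the output filenames (required:
#'   DICOM patient identifiers must not leak into paths).
#' @param session Optional session label.
#' @param anonymize Drop the patient sidecar and scrub patient tags from
#'   the extra sidecar.
#' @param write_patient,write_extra Emit the optional sidecars.
#' @param overwrite Replace existing output files.
#' @param registry Converter registry.
#' @return A data.frame report: one row per (series, part) with columns
#'   `series_uid`, `disposition` (`converted`/`skipped`/`rejected`),
#'   `suffix`, `part`, `n_files`, `message`.
#' @export
convert_dicom_dataset <- function(in_dir, out_root, subject, session = NULL,
                                  anonymize = FALSE, write_patient = TRUE,
                                  write_extra = TRUE, overwrite = FALSE,
                                  registry = converter_registry()) {
  groups <- read_dicom_tree(in_dir)
  if (anonymize) write_patient <- FALSE
  rows <- list()
  note <- function(uid, disp, suffix = NA_character_, part = NA_character_,
                   n = 0L, msg = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      series_uid = uid, disposition = disp, suffix = suffix, part = part,
      n_files = n, message = msg, stringsAsFactors = FALSE)
  }
  for (group in groups) {
    spec <- detect_acquisition(group, registry)
    if (is.null(spec)) {
      note(group$uid, "skipped", msg = "unrecognized acquisition")
      next
    }
    parts <- tryCatch(split_parts(group), error = function(e) e)
    if (inherits(parts, "error")) {
      note(group$uid, "rejected", spec$suffix, msg = conditionMessage(parts))
      next
    }
    for (part in names(parts)) {
      res <- tryCatch({
        frames <- parts[[part]]
        volume <- stack_volume(frames, part)
        main <- extract_metadata(group, spec, volume)
        split <- split_patient_fields(group$datasets[[1L]])
        frame_idx <- which(vapply(group$frames, function(fr)
          .part_from_image_type(fr$tags$image_type), character(1)) == part)
        extra <- .series_extra_payload(group, frame_idx, anonymize)
        key <- entity_key(subject = subject, suffix = spec$suffix,
                          session = session,
                          part = if (part == "none") NULL else part)
        paths <- write_converted(
          volume,
          list(main = main,
               patient = if (!anonymize) split$patient,
               extra = extra),
          key, out_root, write_patient = write_patient,
          write_extra = write_extra, overwrite = overwrite)
        note(group$uid, "converted", spec$suffix, part, length(paths))
        TRUE
      }, error = function(e) e)
      if (inherits(res, "error"))
        note(group$uid, "rejected", spec$suffix, part,
             msg = conditionMessage(res))
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("mids_report", class(report))
  report
}

#' @export
print.mids_report <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    line <- switch(x$disposition[i],
      converted = sprintf("series %s: converted as %s%s (%d files)",
                          x$series_uid[i], x$suffix[i],
                          if (!is.na(x$part[i]) && x$part[i] != "none")
                            paste0(" part-", x$part[i]) else "",
                          x$n_files[i]),
      skipped = sprintf("series %s: skipped: %s", x$series_uid[i],
                        x$message[i]),
      rejected = sprintf("series %s: rejected: %s", x$series_uid[i],
                         x$message[i]))
    cat(line, "\n")
  }
  invisible(x)
}

#' Summarize a dataset tree
#'
#' Human-readable inventory: one row per indexed volume with entities,
#' image dimensions, echo times, and required-field presence.
#'
#' @param root Dataset root.
#' @return data.frame (invisibly printed nicely); empty when no entries.
#' @export
inspect_dataset <- function(root) {
  idx <- load_dataset(root)
  if (!length(idx$entries)) {
    message("no entries under ", root)
    return(invisible(data.frame()))
  }
  rows <- lapply(idx$entries, function(e) {
    hdr <- RNifti::niftiHeader(file.path(root, e$image))
    nd <- hdr$dim[1L]
    dims <- paste(hdr$dim[2:(1 + nd)], collapse = "x")
    main <- tryCatch(
      .read_json_file(file.path(root, e$sidecars$main)),
      error = function(x) list())
    miss <- check_required_fields(main, e$key$suffix)
    data.frame(subject = e$key$subject,
               session = e$key$session %||% "",
               part = e$key$part %||% "",
               suffix = e$key$suffix, dims = dims,
               echo_times = if (!is.null(main$EchoTime))
                 paste(unlist(main$EchoTime), collapse = ",") else "",
               missing_fields = paste(miss, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round-trip one stored volume back to DICOM
#'
#' Convenience wrapper: loads `key` from the dataset at `root` and calls
#' [reconstruct_dicom()] with its extra sidecar.
#'
#' @param root Dataset root.
#' @param key An [entity_key()].
#' @param out_dir Output directory for the reconstructed files.
#' @return Written file paths.
#' @export
roundtrip_volume <- function(root, key, out_dir) {
  idx <- load_dataset(root)
  lv <- load_volume(idx, key)
  reconstruct_dicom(lv$volume, lv$sidecars$extra, out_dir)
}
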