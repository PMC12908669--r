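# Conformance validation of an existing dataset tree. Rules carry stable
# codes V1-V8; an empty error list means the tree is compliant. The
# validator and the converter share one registry, so a tree produced by
# this package's own converter cannot drift out of conformance.

.issue <- function(severity, code, path, message) {
  data.frame(severity = severity, code = code, path = path,
             message = message, stringsAsFactors = FALSE)
}

.no_issues <- function() {
  data.frame(severity = character(0), code = character(0),
             path = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

#' Missing required sidecar fields for a suffix
#'
#' Pure lookup against the converter registry: which of the suffix's
#' required JSON fields are absent from a main-sidecar payload.
#'
#' @param sidecar Named list (decoded main sidecar).
#' @param suffix Acquisition suffix.
#' @param registry Converter registry.
#' @return Character vector of missing field names (empty = pass).
#' @export
check_required_fields <- function(sidecar, suffix,
                                  registry = converter_registry()) {
  req <- required_fields_for(suffix, registry)
  req[!req %in% names(sidecar)]
}

.nifti_ndim <- function(path) {
  hdr <- RNifti::niftiHeader(path)
  as.integer(hdr$dim[1L])
}

.nifti_dim4 <- function(path) {
  hdr <- RNifti::niftiHeader(path)
  if (hdr$dim[1L] < 4L) NA_integer_ else as.integer(hdr$dim[5L])
}

#' Validate a dataset tree
#'
#' Checks, each with a stable code:
#' \describe{
#'   \item{V1}{every filename parses under the entity grammar}
#'   \item{V2}{suffix/folder pairing matches the registry}
#'   \item{V3}{main sidecar exists and carries every required field, with
#'     arrays where the standard demands arrays (EchoTime)}
#'   \item{V4}{image dimensionality matches the suffix contract (multi-echo
#'     MR 4D, ct 3D, cr 2D)}
#'   \item{V5}{EchoTime array length equals the 4th-axis length}
#'   \item{V6}{no patient-identifying key in a main sidecar}
#'   \item{V7}{participants.tsv well-formed and covering all subjects
#'     (warning)}
#'   \item{V8}{reserved suffixes are flagged "reserved, not yet specified"
#'     (warning)}
#' }
#' Files under `derivatives/` are checked for grammar (V1) only. Unknown
#' extra keys in a main sidecar are warnings unless `strict = TRUE`.
#'
#' @param root Dataset root directory.
#' @param strict Upgrade warnings about extra sidecar keys to errors.
#' @param registry Converter registry.
#' @return data.frame of issues (`severity`, `code`, `path`, `message`);
#'   zero rows with severity `"error"` means compliant.
#' @export
validate_dataset <- function(root, strict = FALSE,
                             registry = converter_registry()) {
  if (!dir.exists(root)) stop("cannot validate: unreadable root ", root)
  issues <- .no_issues()
  add <- function(...) issues <<- rbind(issues, .issue(...))
  reg <- suffix_registry()
  files <- list.files(root, recursive = TRUE, full.names = FALSE)
  deriv <- files[startsWith(files, "derivatives/")]
  files <- setdiff(files, deriv)

  for (rel in deriv) {
    if (!grepl("\\.(nii\\.gz|json|tsv)$", rel)) next
    sub_rel <- sub("^derivatives/", "", rel)
    if (grepl("\\.nii\\.gz$", sub_rel)) {
      ok <- tryCatch({ parse_filename(sub_rel); TRUE },
                     error = function(e) FALSE)
      if (!ok) add("error", "V1", rel, "derivatives filename does not parse")
    }
  }

  imgs <- files[endsWith(files, ".nii.gz")]
  subjects <- character(0)
  for (rel in imgs) {
    key <- tryCatch(parse_filename(rel), error = function(e) e)
    if (inherits(key, "error")) {
      add("error", "V1", rel,
          paste0("filename does not parse: ", conditionMessage(key)))
      next
    }
    subjects <- union(subjects, key$subject)
    row <- reg[reg$suffix == key$suffix, ]
    if (nrow(row) == 1L) {
      folder <- strsplit(rel, "/", fixed = TRUE)[[1L]]
      folder <- folder[length(folder) - 1L]
      if (!identical(folder, row$folder))
        add("error", "V2", rel,
            paste0("suffix '", key$suffix, "' must live under '",
                   row$folder, "', found '", folder, "'"))
      if (row$status == "reserved")
        add("warning", "V8", rel,
            paste0("suffix '", key$suffix,
                   "' is reserved, not yet specified"))
    } else {
      add("warning", "V8", rel,
          paste0("unrecognized suffix '", key$suffix, "'"))
    }
    base <- substr(rel, 1L, nchar(rel) - nchar(".nii.gz"))
    main_path <- file.path(root, paste0(base, ".json"))
    if (!file.exists(main_path)) {
      add("error", "V3", rel, "main sidecar is missing")
      next
    }
    main <- tryCatch(.read_json_file(main_path), error = function(e) e)
    if (inherits(main, "error")) {
      add("error", "V3", paste0(base, ".json"), "main sidecar is not valid JSON")
      next
    }
    miss <- check_required_fields(main, key$suffix, registry)
    for (f in miss)
      add("error", "V3", paste0(base, ".json"),
          paste0("required field missing: ", f))
    if (key$suffix %in% c("megre", "mese") && "EchoTime" %in% names(main) &&
        length(main$EchoTime) < 2L)
      add("error", "V3", paste0(base, ".json"),
          "EchoTime must be an array for multi-echo suffixes")
    known <- c(required_fields_for(key$suffix, registry),
               .optional_fields_for(key$suffix, registry))
    extra_keys <- setdiff(names(main), known)
    if (length(extra_keys) && length(required_fields_for(key$suffix, registry)))
      add(if (strict) "error" else "warning", "V3x", paste0(base, ".json"),
          paste0("keys beyond the standard's field list: ",
                 paste(extra_keys, collapse = ", ")))
    leaked <- intersect(names(main), patient_fields())
    for (f in leaked)
      add("error", "V6", paste0(base, ".json"),
          paste0("patient-identifying key in main sidecar: ", f))
    nd <- tryCatch(.nifti_ndim(file.path(root, rel)), error = function(e) NA)
    if (nrow(row) == 1L && row$status == "included" && !is.na(nd)) {
      want <- row$dims
      et_len <- length(main$EchoTime)
      if (key$suffix %in% c("megre", "mese")) {
        want <- if (et_len > 1L) 4L else 3L
      }
      if (nd != want)
        add("error", "V4", rel,
            paste0("expected ", want, "D volume for suffix '", key$suffix,
                   "', found ", nd, "D"))
      if (nd == 4L && et_len >= 1L) {
        n4 <- .nifti_dim4(file.path(root, rel))
        if (!is.na(n4) && n4 != et_len)
          add("error", "V5", rel,
              paste0("EchoTime length (", et_len,
                     ") does not match 4th-axis length (", n4, ")"))
      }
    }
  }
  ppath <- file.path(root, "participants.tsv")
  if (file.exists(ppath)) {
    tab <- tryCatch(read_participants(ppath), error = function(e) e)
    if (inherits(tab, "error") || !"participant_id" %in% names(tab)) {
      add("warning", "V7", "participants.tsv",
          "participants.tsv is malformed")
    } else {
      miss <- setdiff(paste0("sub-", subjects), tab$participant_id)
      if (length(miss))
        add("warning", "V7", "participants.tsv",
            paste0("subjects not covered: ", paste(miss, collapse = ", ")))
    }
  } else if (length(subjects)) {
    add("warning", "V7", "participants.tsv", "participants.tsv is missing")
  }
  issues
}

#' Write a machine-readable validation report
#'
#' One JSON object per line (`severity`, `code`, `path`, `message`).
#'
#' @param issues Issue data.frame from [validate_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(issues, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(issues))) {
    writeLines(as.character(
      jsonlite::toJSON(as.list(issues[i, ]), auto_unbox = TRUE)), con)
  }
  invisible(path)
}
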