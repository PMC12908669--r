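# Filename and folder grammar. Follows the BIDS entity convention
# (`sub-`, `ses-`, `part-` key-value tokens, underscore-separated, suffix
# last) over the MSK-MIDS folder layout: modality folders `ct`, `cr`,
# `mr-anat`, `mr-quant`, `us`, `seg` directly under each subject (or
# session) folder.

#' Registry of file-name suffixes
#'
#' One row per acquisition suffix the standard names: the target modality
#' folder, whether a converter exists (`status = "included"`) or the suffix
#' is merely reserved for future acquisition types, whether complex-part
#' entities (`part-mag` etc.) are meaningful, and the expected image
#' dimensionality.
#'
#' @return A data.frame with columns `suffix`, `folder`, `status`,
#'   `part_allowed`, `dims`.
#' @export
suffix_registry <- function() {
  data.frame(
    suffix = c("ct", "pcct", "hrpqct", "cr",
               "t1", "t2", "wt2",
               "dess", "dess-fid", "dess_echo",
               "megre", "mese",
               "vel", "diff", "seg", "us"),
    folder = c("ct", "ct", "ct", "cr",
               "mr-quant", "mr-quant", "mr-quant",
               "mr-anat", "mr-anat", "mr-anat",
               "mr-anat", "mr-anat",
               "mr-quant", "mr-quant", "seg", "us"),
    status = c(rep("included", 12L), rep("reserved", 4L)),
    part_allowed = c(FALSE, FALSE, FALSE, FALSE,
                     TRUE, TRUE, TRUE,
                     TRUE, TRUE, TRUE,
                     TRUE, TRUE,
                     TRUE, TRUE, FALSE, FALSE),
    dims = c(3L, 3L, 3L, 2L,
             3L, 3L, 3L,
             3L, 3L, 3L,
             4L, 4L,
             5L, 4L, 3L, 3L),
    stringsAsFactors = FALSE
  )
}

.modality_folders <- c("ct", "cr", "mr-anat", "mr-quant", "us", "seg")
.part_labels <- c("mag", "phase", "real", "imag")
.known_extensions <- c("_patient.json", "_extra.json", ".nii.gz", ".json")

.valid_label <- function(x) {
  is.character(x) && length(x) == 1L && grepl("^[A-Za-z0-9]+$", x)
}

#' Construct an entity key
#'
#' The entity key names one image volume: participant, optional session,
#' optional complex-part label, acquisition suffix, and modality folder.
#' Labels are restricted to alphanumerics (BIDS rule: separators are
#' structural).
#'
#' @param subject Participant label (alphanumeric).
#' @param suffix Acquisition suffix (see [suffix_registry()]).
#' @param folder Modality folder; defaults to the registry folder for the
#'   suffix.
#' @param session Optional session label.
#' @param part Optional complex-part label (`mag`, `phase`, `real`, `imag`);
#'   only valid for MR suffixes.
#' @return An object of class `mids_key`.
#' @export
entity_key <- function(subject, suffix, folder = NULL, session = NULL,
                       part = NULL) {
  reg <- suffix_registry()
  if (!.valid_label(subject))
    stop("invalid subject label (alphanumeric only): ", subject)
  if (!is.null(session) && !.valid_label(session))
    stop("invalid session label (alphanumeric only): ", session)
  row <- reg[reg$suffix == suffix, ]
  known <- nrow(row) == 1L
  if (is.null(folder)) {
    if (!known) stop("unknown suffix '", suffix, "' requires an explicit folder")
    folder <- row$folder
  }
  if (!folder %in% .modality_folders)
    stop("unknown modality folder: ", folder)
  if (known && !identical(folder, row$folder))
    stop("suffix '", suffix, "' belongs in folder '", row$folder,
         "', not '", folder, "'")
  if (!is.null(part)) {
    if (!part %in% .part_labels) stop("invalid part label: ", part)
    if (known && !row$part_allowed)
      stop("part entity is not valid for suffix '", suffix, "'")
  }
  structure(list(subject = subject, session = session, part = part,
                 suffix = suffix, folder = folder,
                 recognized = known,
                 reserved = known && row$status == "reserved"),
            class = "mids_key")
}

#' @export
format.mids_key <- function(x, ...) {
  paste0("<", x$subject,
         if (!is.null(x$session)) paste0("/", x$session),
         " ", x$folder, "/", x$suffix,
         if (!is.null(x$part)) paste0(" part-", x$part), ">")
}

#' @export
print.mids_key <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Compose the relative path of a dataset file
#'
#' Deterministic BIDS-style naming:
#' `sub-<s>[/ses-<ses>]/<folder>/sub-<s>[_ses-<ses>][_part-<p>]_<suffix><ext>`.
#' Entity order is fixed; `/` is the internal separator.
#'
#' @param key An [entity_key()].
#' @param extension One of `".nii.gz"`, `".json"`, `"_patient.json"`,
#'   `"_extra.json"`.
#' @return Relative path string.
#' @export
compose_filename <- function(key, extension = ".nii.gz") {
  stopifnot(inherits(key, "mids_key"))
  if (!extension %in% .known_extensions)
    stop("unknown extension: ", extension)
  base <- paste0("sub-", key$subject,
                 if (!is.null(key$session)) paste0("_ses-", key$session),
                 if (!is.null(key$part)) paste0("_part-", key$part),
                 "_", key$suffix)
  dir <- paste0("sub-", key$subject,
                if (!is.null(key$session)) paste0("/ses-", key$session),
                "/", key$folder)
  paste0(dir, "/", base, extension)
}

#' Parse a dataset-relative path into an entity key
#'
#' Inverse of [compose_filename()] on its image. The suffix is matched
#' longest-first against the registry before entity tokenization, so
#' registered suffixes containing an underscore (`dess_echo`) survive.
#' Unknown suffixes parse with `recognized = FALSE` rather than failing
#' (forward compatibility); unknown BIDS entities (`acq-`, `run-`, ...)
#' are accepted and retained under `extra_entities` but never re-emitted.
#'
#' @param path Relative path with `/` separators.
#' @return A `mids_key` with attribute `extension`.
#' @export
parse_filename <- function(path) {
  comps <- strsplit(path, "/", fixed = TRUE)[[1L]]
  if (length(comps) < 3L)
    stop("path has too few components (need sub-*/<folder>/<file>): ", path)
  fname <- comps[length(comps)]
  folder <- comps[length(comps) - 1L]
  if (!folder %in% .modality_folders)
    stop("unknown modality folder in path: ", folder)
  ext <- NULL
  for (e in .known_extensions) {
    if (endsWith(fname, e)) { ext <- e; break }
  }
  if (is.null(ext)) stop("unknown file extension: ", fname)
  base <- substr(fname, 1L, nchar(fname) - nchar(ext))

  reg <- suffix_registry()
  sufs <- reg$suffix[order(-nchar(reg$suffix))]
  suffix <- NULL
  for (s in sufs) {
    if (endsWith(base, paste0("_", s))) { suffix <- s; break }
  }
  if (is.null(suffix)) {
    # unknown suffix: last underscore token
    toks <- strsplit(base, "_", fixed = TRUE)[[1L]]
    suffix <- toks[length(toks)]
    if (!nzchar(suffix) || grepl("-", suffix, fixed = TRUE))
      stop("cannot parse suffix from: ", fname)
  }
  entity_str <- substr(base, 1L, nchar(base) - nchar(suffix) - 1L)
  toks <- strsplit(entity_str, "_", fixed = TRUE)[[1L]]
  ents <- list()
  extra <- list()
  for (tok in toks) {
    kv <- regmatches(tok, regexec("^([a-z]+)-(.*)$", tok))[[1L]]
    if (length(kv) != 3L || !nzchar(kv[3L]))
      stop("malformed entity token '", tok, "' in ", fname)
    if (kv[2L] %in% c("sub", "ses", "part")) ents[[kv[2L]]] <- kv[3L]
    else extra[[kv[2L]]] <- kv[3L]
  }
  if (is.null(ents$sub)) stop("filename lacks a sub- entity: ", fname)
  known <- suffix %in% reg$suffix
  key <- entity_key(subject = ents$sub, suffix = suffix,
                    folder = if (known) NULL else folder,
                    session = ents$ses, part = ents$part)
  # a known suffix under the wrong folder still parses; conformance
  # checking of the pairing is the validator's job (rule V2)
  attr(key, "observed_folder") <- folder
  attr(key, "extension") <- ext
  if (length(extra)) attr(key, "extra_entities") <- extra
  key
}
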