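# DICOM Part-10 reader/writer. Scope: uncompressed little-endian transfer
# syntaxes (implicit and explicit VR), classic single-frame and enhanced
# multi-frame datasets with nested sequences. Datasets are represented as
# named lists keyed by "ggggeeee" hex tag, each element a
# list(vr = <chr>, value = <vector | raw | list-of-item-datasets>).

.DCM_UNDEF <- 4294967295 # 0xFFFFFFFF

# ---- byte-level helpers -----------------------------------------------------

.u16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}

.u32 <- function(bytes, at) {
  # returned as double: lengths may exceed .Machine$integer.max sentinel-wise
  as.numeric(bytes[at]) + 256 * as.numeric(bytes[at + 1L]) +
    65536 * as.numeric(bytes[at + 2L]) + 16777216 * as.numeric(bytes[at + 3L])
}

.raw_u16 <- function(x) {
  x <- as.integer(round(x))
  as.raw(c(x %% 256L, x %/% 256L))
}

.raw_u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.tag_bytes <- function(tag) {
  g <- strtoi(substr(tag, 1L, 4L), 16L)
  e <- strtoi(substr(tag, 5L, 8L), 16L)
  c(.raw_u16(g), .raw_u16(e))
}

.tag_hex <- function(group, element) {
  sprintf("%04X%04X", group, element)
}

# ---- value decoding ---------------------------------------------------------

.decode_value <- function(vr, bytes) {
  n <- length(bytes)
  if (vr %in% .dcm_string_vrs) {
    s <- rawToChar(bytes[bytes != as.raw(0L)])
    s <- sub("[ ]+$", "", s)
    if (vr %in% .dcm_text_vrs) return(s)
    return(strsplit(s, "\\", fixed = TRUE)[[1L]])
  }
  switch(vr,
    DS = {
      s <- sub("[ ]+$", "", rawToChar(bytes[bytes != as.raw(0L)]))
      if (!nzchar(s)) return(numeric(0))
      as.numeric(strsplit(s, "\\", fixed = TRUE)[[1L]])
    },
    IS = {
      s <- sub("[ ]+$", "", rawToChar(bytes[bytes != as.raw(0L)]))
      if (!nzchar(s)) return(numeric(0))
      as.numeric(strsplit(s, "\\", fixed = TRUE)[[1L]])
    },
    US = readBin(bytes, "integer", n = n %/% 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    SS = readBin(bytes, "integer", n = n %/% 2L, size = 2L,
                 signed = TRUE, endian = "little"),
    UL = readBin(bytes, "integer", n = n %/% 4L, size = 4L,
                 endian = "little"),
    SL = readBin(bytes, "integer", n = n %/% 4L, size = 4L,
                 endian = "little"),
    FL = readBin(bytes, "double", n = n %/% 4L, size = 4L,
                 endian = "little"),
    FD = readBin(bytes, "double", n = n %/% 8L, size = 8L,
                 endian = "little"),
    AT = {
      k <- n %/% 4L
      vapply(seq_len(k), function(i) {
        at <- (i - 1L) * 4L + 1L
        .tag_hex(.u16(bytes, at), .u16(bytes, at + 2L))
      }, character(1))
    },
    bytes # OB/OW/OF/UN and anything unrecognized stays raw
  )
}

# ---- dataset reading --------------------------------------------------------

# cursor over a raw vector (environment avoids copying)
.cursor <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes
  env$pos <- 1L
  env
}

.cur_left <- function(cur) length(cur$bytes) - cur$pos + 1L

.cur_take <- function(cur, n) {
  n <- as.integer(n)
  if (n > .cur_left(cur)) stop("truncated DICOM stream")
  out <- cur$bytes[seq.int(cur$pos, length.out = n)]
  cur$pos <- cur$pos + n
  out
}

# read one dataset from the cursor; `end` is one-past-last byte position
# (NA = to end of stream); stops early at an item-delimitation tag.
.read_dataset <- function(cur, explicit, end = NA) {
  ds <- list()
  repeat {
    if (!is.na(end) && cur$pos >= end) break
    if (.cur_left(cur) < 8L) break
    hdr <- .cur_take(cur, 4L)
    group <- .u16(hdr, 1L)
    element <- .u16(hdr, 3L)
    if (group == 0xFFFE) {
      len <- .u32(.cur_take(cur, 4L), 1L)
      if (element == 0xE00D || element == 0xE0DD) break # delimiter
      stop("unexpected item tag outside sequence")
    }
    tag <- .tag_hex(group, element)
    if (explicit) {
      vr <- rawToChar(.cur_take(cur, 2L))
      if (vr %in% .dcm_long_vrs) {
        .cur_take(cur, 2L)
        len <- .u32(.cur_take(cur, 4L), 1L)
      } else {
        len <- .u16(.cur_take(cur, 2L), 1L)
      }
    } else {
      vr <- dcm_vr_for_tag(tag)
      len <- .u32(.cur_take(cur, 4L), 1L)
    }
    if (vr == "SQ" || (vr == "UN" && len == .DCM_UNDEF)) {
      ds[[tag]] <- list(vr = "SQ", value = .read_items(cur, explicit, len))
    } else {
      if (len == .DCM_UNDEF) stop("undefined length outside a sequence: ", tag)
      ds[[tag]] <- list(vr = vr, value = .decode_value(vr, .cur_take(cur, len)))
    }
  }
  ds
}

.read_items <- function(cur, explicit, sq_len) {
  items <- list()
  sq_end <- if (sq_len == .DCM_UNDEF) NA else cur$pos + sq_len
  repeat {
    if (!is.na(sq_end) && cur$pos >= sq_end) break
    if (.cur_left(cur) < 8L) break
    hdr <- .cur_take(cur, 4L)
    group <- .u16(hdr, 1L)
    element <- .u16(hdr, 3L)
    len <- .u32(.cur_take(cur, 4L), 1L)
    if (group == 0xFFFE && element == 0xE0DD) break # sequence delimitation
    if (!(group == 0xFFFE && element == 0xE000)) stop("malformed sequence item")
    item_end <- if (len == .DCM_UNDEF) NA else cur$pos + len
    items[[length(items) + 1L]] <- .read_dataset(cur, explicit, item_end)
  }
  items
}

#' Read a DICOM Part-10 file
#'
#' Parses a classic or enhanced DICOM file stored in an uncompressed
#' little-endian transfer syntax (implicit or explicit VR). Sequences,
#' including the shared/per-frame functional groups of enhanced multi-frame
#' files, are parsed recursively.
#'
#' @param path Path to a DICOM Part-10 file.
#' @return A list with components `meta` (file-meta group) and `dataset`,
#'   each a named list keyed by hex tag `"ggggeeee"` with elements
#'   `list(vr, value)`.
#' @export
read_dicom_file <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 140) stop("not a DICOM part-10 file: ", path)
  bytes <- readBin(path, "raw", n)
  if (rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM magic): ", path)
  cur <- .cursor(bytes)
  cur$pos <- 133L
  # file meta group is always explicit VR LE; its length is given first
  hdr <- .cur_take(cur, 4L)
  if (.u16(hdr, 1L) != 2L || .u16(hdr, 3L) != 0L)
    stop("file meta group does not start with (0002,0000): ", path)
  vr <- rawToChar(.cur_take(cur, 2L))
  len <- .u16(.cur_take(cur, 2L), 1L)
  meta_len <- .decode_value("UL", .cur_take(cur, len))
  meta <- .read_dataset(cur, explicit = TRUE, end = cur$pos + meta_len)
  meta[["00020000"]] <- list(vr = "UL", value = meta_len)
  ts <- meta[["00020010"]]$value
  if (is.null(ts)) ts <- .uid_explicit_le
  if (!ts %in% c(.uid_implicit_le, .uid_explicit_le))
    stop("unsupported transfer syntax ", ts, " in ", path,
         " (only uncompressed little endian is supported)")
  dataset <- .read_dataset(cur, explicit = identical(ts, .uid_explicit_le))
  list(meta = meta, dataset = dataset, path = path)
}

#' Test whether a file looks like DICOM Part-10
#'
#' @param path File path.
#' @return `TRUE` if the file carries the `DICM` magic at offset 128.
#' @export
is_dicom_file <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 132 || dir.exists(path)) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 128L)
  identical(rawToChar(readBin(con, "raw", 4L)), "DICM")
}

# ---- value encoding ---------------------------------------------------------

.format_ds <- function(x) {
  # shortest decimal that round-trips within DS's 16-byte budget
  vapply(x, function(v) {
    s <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
    if (nchar(s) > 16) s <- sprintf("%.8e", v)
    if (nchar(s) > 16) stop("DS value does not fit in 16 bytes: ", v)
    s
  }, character(1))
}

.encode_value <- function(vr, value) {
  if (vr == "SQ") stop("sequences are encoded by .encode_element")
  if (is.raw(value)) {
    bytes <- value
  } else if (vr %in% .dcm_string_vrs || vr %in% c("DS", "IS")) {
    parts <- switch(vr,
      DS = .format_ds(value),
      IS = sprintf("%d", as.integer(round(value))),
      as.character(value))
    bytes <- charToRaw(paste(parts, collapse = "\\"))
  } else {
    bytes <- switch(vr,
      US = , SS = {
        x <- as.integer(round(value))
        x[x >= 32768L] <- x[x >= 32768L] - 65536L # encode as two's complement
        writeBin(x, raw(), size = 2L, endian = "little")
      },
      UL = , SL = writeBin(as.integer(value), raw(), size = 4L,
                           endian = "little"),
      FL = writeBin(as.numeric(value), raw(), size = 4L, endian = "little"),
      FD = writeBin(as.numeric(value), raw(), size = 8L, endian = "little"),
      stop("cannot encode VR ", vr, " from a non-raw value")
    )
  }
  if (length(bytes) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB", "UN")) as.raw(0L) else charToRaw(" ")
    bytes <- c(bytes, pad)
  }
  bytes
}

.encode_element <- function(tag, vr, value) {
  head <- .tag_bytes(tag)
  if (vr == "SQ") {
    body <- do.call(c, c(list(raw(0)), lapply(value, function(item) {
      ib <- .encode_dataset(item)
      c(.raw_u16(0xFFFE), .raw_u16(0xE000), .raw_u32(length(ib)), ib)
    })))
    return(c(head, charToRaw("SQ"), as.raw(c(0L, 0L)),
             .raw_u32(length(body)), body))
  }
  bytes <- .encode_value(vr, value)
  if (vr %in% .dcm_long_vrs) {
    c(head, charToRaw(vr), as.raw(c(0L, 0L)), .raw_u32(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534) stop("value too long for short VR ", vr)
    c(head, charToRaw(vr), .raw_u16(length(bytes)), bytes)
  }
}

.encode_dataset <- function(ds) {
  tags <- names(ds)
  tags <- tags[order(tags)]
  do.call(c, c(list(raw(0)), lapply(tags, function(tag) {
    .encode_element(tag, ds[[tag]]$vr, ds[[tag]]$value)
  })))
}

#' Write a DICOM Part-10 file
#'
#' Serializes a dataset (as produced by [read_dicom_file()] or built
#' programmatically) in the explicit VR little endian transfer syntax,
#' with a standard preamble and file-meta group.
#'
#' @param path Output file path.
#' @param dataset Named list of `list(vr, value)` elements keyed by hex tag.
#' @param sop_class_uid SOP class UID for the file-meta group; defaults to
#'   the dataset's own SOPClassUID.
#' @return `path`, invisibly.
#' @export
write_dicom_file <- function(path, dataset, sop_class_uid = NULL) {
  if (is.null(sop_class_uid)) sop_class_uid <- dataset[["00080016"]]$value
  sop_instance <- dataset[["00080018"]]$value
  if (is.null(sop_class_uid) || is.null(sop_instance))
    stop("dataset must carry SOPClassUID and SOPInstanceUID")
  meta <- list(
    "00020001" = list(vr = "OB", value = as.raw(c(0L, 1L))),
    "00020002" = list(vr = "UI", value = sop_class_uid),
    "00020003" = list(vr = "UI", value = sop_instance),
    "00020010" = list(vr = "UI", value = .uid_explicit_le),
    "00020012" = list(vr = "UI", value = "2.25.8899241921523541")
  )
  meta_bytes <- .encode_dataset(meta)
  glen <- .encode_element("00020000", "UL", length(meta_bytes))
  body <- .encode_dataset(dataset)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(glen, meta_bytes, body), con)
  invisible(path)
}

# ---- small conveniences -----------------------------------------------------

ds_get <- function(ds, keyword, default = NULL) {
  e <- ds[[.dcm_keyword_to_tag[[keyword]]]]
  if (is.null(e)) default else e$value
}

ds_set <- function(ds, keyword, value, vr = NULL) {
  tag <- dcm_tag(keyword)
  if (is.null(vr)) vr <- dcm_vr_for_tag(tag)
  ds[[tag]] <- list(vr = vr, value = value)
  ds
}

#' Generate a DICOM UID
#'
#' Deterministic given R's RNG state; uses the 2.25 (UUID-derived) root.
#'
#' @return A UID string.
#' @export
dcm_uid <- function() {
  digits <- sample.int(10L, 30L, replace = TRUE) - 1L
  if (digits[1L] == 0L) digits[1L] <- 1L
  paste0("2.25.", paste(digits, collapse = ""))
}
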