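# Partition of the full DICOM header into the sensitive patient sidecar
# and the residual "extra" sidecar, plus lossless serialization of the
# latter. Anonymization is by construction: the main sidecar only ever
# receives whitelisted interpretive fields, the patient sidecar can be
# dropped as one file, and anonymize mode additionally scrubs patient
# tags from the serialized extra header (removal, not blanking — a
# blanked header still advertises what was there).

#' The frozen list of patient-identifying DICOM attributes
#'
#' Seeded from the DICOM PS3.15 basic confidentiality profile plus the
#' fields this standard relocates out of the interpretive header (notably
#' InstitutionName). Frozen and versioned in code so the anonymization
#' contract is testable; not user-configurable.
#'
#' @return Character vector of DICOM keywords.
#' @export
patient_fields <- function() {
  c("PatientName", "PatientID", "PatientBirthDate", "PatientSex",
    "PatientAge", "PatientWeight", "PatientSize", "PatientAddress",
    "PatientTelephoneNumbers", "AccessionNumber", "InstitutionName",
    "InstitutionAddress", "ReferringPhysicianName",
    "PerformingPhysicianName", "OperatorsName", "DeviceSerialNumber",
    "StationName", "StudyDate", "SeriesDate", "AcquisitionDate",
    "ContentDate", "StudyTime", "SeriesTime", "AcquisitionTime",
    "ContentTime", "ImageComments", "PatientComments",
    "AdditionalPatientHistory")
}

.patient_tags <- function() {
  unname(vapply(patient_fields(), dcm_tag, character(1)))
}

#' Split a DICOM tag map into patient and residual maps
#'
#' @param tags Named list of dataset elements (hex-tag keys).
#' @return `list(patient = <keyword-keyed list>, residual = <tag map>)`;
#'   the union reconstructs the input, the intersection is empty. Absent
#'   patient fields are simply omitted.
#' @export
split_patient_fields <- function(tags) {
  ptags <- .patient_tags()
  is_patient <- names(tags) %in% ptags
  patient <- tags[is_patient]
  if (length(patient))
    names(patient) <- vapply(names(patient), dcm_keyword_for_tag, character(1))
  patient_values <- lapply(patient, `[[`, "value")
  list(patient = patient_values, residual = tags[!is_patient])
}

#' Remove patient-identifying tags from a dataset, recursively
#'
#' @param tags Tag map; sequences are scrubbed item by item.
#' @return The scrubbed tag map.
#' @export
scrub_patient_tags <- function(tags) {
  ptags <- .patient_tags()
  tags <- tags[!(names(tags) %in% ptags)]
  for (tag in names(tags)) {
    if (identical(tags[[tag]]$vr, "SQ"))
      tags[[tag]]$value <- lapply(tags[[tag]]$value, scrub_patient_tags)
  }
  tags
}

# ---- lossless tag serialization --------------------------------------------

.serialize_element <- function(el) {
  if (identical(el$vr, "SQ"))
    return(list(vr = "SQ", items = lapply(el$value, serialize_extra)))
  v <- el$value
  if (is.raw(v))
    return(list(vr = el$vr, b64 = jsonlite::base64_enc(v)))
  list(vr = el$vr, value = as.list(v))
}

#' Serialize a DICOM tag map to a JSON-able structure
#'
#' Every non-pixel element becomes `{"<ggggeeee>": {"vr": ..., "value":
#' [...]}}`; binary payloads are base64-encoded under `b64`; sequences
#' (including the per-frame functional groups of enhanced files) recurse
#' under `items`. The representation is lossless:
#' [deserialize_extra()] is its exact inverse, which is what makes
#' dataset-to-DICOM round-tripping possible.
#'
#' @param tags Tag map from [read_dicom_file()].
#' @return Nested list ready for JSON encoding.
#' @export
serialize_extra <- function(tags) {
  tags <- tags[names(tags) != dcm_tag("PixelData")]
  lapply(tags, .serialize_element)
}

.deserialize_element <- function(se) {
  if (identical(se$vr, "SQ"))
    return(list(vr = "SQ", value = lapply(se$items, deserialize_extra)))
  if (!is.null(se$b64))
    return(list(vr = se$vr, value = jsonlite::base64_dec(se$b64)))
  v <- unlist(se$value, use.names = FALSE)
  if (is.null(v)) v <- if (se$vr %in% .dcm_string_vrs) character(0) else numeric(0)
  list(vr = se$vr, value = v)
}

#' Inverse of [serialize_extra()]
#'
#' @param ser Structure produced by [serialize_extra()] (possibly after a
#'   JSON round trip).
#' @return Tag map.
#' @export
deserialize_extra <- function(ser) {
  lapply(ser, .deserialize_element)
}
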