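# Minimal DICOM data dictionary: only the attributes this package reads,
# writes, or must name when anonymizing. Keys are 8-digit uppercase hex
# "ggggeeee" strings (group + element).

.dcm_dict <- list(
  # file meta (group 0002, always explicit VR little endian)
  "00020000" = c("UL", "FileMetaInformationGroupLength"),
  "00020001" = c("OB", "FileMetaInformationVersion"),
  "00020002" = c("UI", "MediaStorageSOPClassUID"),
  "00020003" = c("UI", "MediaStorageSOPInstanceUID"),
  "00020010" = c("UI", "TransferSyntaxUID"),
  "00020012" = c("UI", "ImplementationClassUID"),
  # identification / acquisition context
  "00080005" = c("CS", "SpecificCharacterSet"),
  "00080008" = c("CS", "ImageType"),
  "00080016" = c("UI", "SOPClassUID"),
  "00080018" = c("UI", "SOPInstanceUID"),
  "00080020" = c("DA", "StudyDate"),
  "00080021" = c("DA", "SeriesDate"),
  "00080022" = c("DA", "AcquisitionDate"),
  "00080023" = c("DA", "ContentDate"),
  "00080030" = c("TM", "StudyTime"),
  "00080031" = c("TM", "SeriesTime"),
  "00080032" = c("TM", "AcquisitionTime"),
  "00080033" = c("TM", "ContentTime"),
  "00080050" = c("SH", "AccessionNumber"),
  "00080060" = c("CS", "Modality"),
  "00080070" = c("LO", "Manufacturer"),
  "00080080" = c("LO", "InstitutionName"),
  "00080081" = c("ST", "InstitutionAddress"),
  "00080090" = c("PN", "ReferringPhysicianName"),
  "00081010" = c("SH", "StationName"),
  "00081030" = c("LO", "StudyDescription"),
  "0008103E" = c("LO", "SeriesDescription"),
  "00081050" = c("PN", "PerformingPhysicianName"),
  "00081070" = c("PN", "OperatorsName"),
  "00089007" = c("CS", "FrameType"),
  # patient
  "00100010" = c("PN", "PatientName"),
  "00100020" = c("LO", "PatientID"),
  "00100030" = c("DA", "PatientBirthDate"),
  "00100040" = c("CS", "PatientSex"),
  "00101010" = c("AS", "PatientAge"),
  "00101020" = c("DS", "PatientSize"),
  "00101030" = c("DS", "PatientWeight"),
  "00101040" = c("LO", "PatientAddress"),
  "00102154" = c("SH", "PatientTelephoneNumbers"),
  "001021B0" = c("LT", "AdditionalPatientHistory"),
  "00104000" = c("LT", "PatientComments"),
  # acquisition parameters
  "00180015" = c("CS", "BodyPartExamined"),
  "00180020" = c("CS", "ScanningSequence"),
  "00180021" = c("CS", "SequenceVariant"),
  "00180024" = c("SH", "SequenceName"),
  "00180050" = c("DS", "SliceThickness"),
  "00180060" = c("DS", "KVP"),
  "00180080" = c("DS", "RepetitionTime"),
  "00180081" = c("DS", "EchoTime"),
  "00180087" = c("DS", "MagneticFieldStrength"),
  "00180088" = c("DS", "SpacingBetweenSlices"),
  "00180095" = c("DS", "PixelBandwidth"),
  "00181000" = c("LO", "DeviceSerialNumber"),
  "00181030" = c("LO", "ProtocolName"),
  "00181150" = c("IS", "ExposureTime"),
  "00181151" = c("IS", "XRayTubeCurrent"),
  "00181152" = c("IS", "Exposure"),
  "00181210" = c("SH", "ConvolutionKernel"),
  "00181314" = c("DS", "FlipAngle"),
  "00187004" = c("CS", "DetectorType"),
  "00189008" = c("CS", "EchoPulseSequence"),
  "00189082" = c("FD", "EffectiveEchoTime"),
  "00189112" = c("SQ", "MRTimingAndRelatedParametersSequence"),
  "00189114" = c("SQ", "MREchoSequence"),
  "00189226" = c("SQ", "MRImageFrameTypeSequence"),
  # relationship / geometry
  "0020000D" = c("UI", "StudyInstanceUID"),
  "0020000E" = c("UI", "SeriesInstanceUID"),
  "00200010" = c("SH", "StudyID"),
  "00200011" = c("IS", "SeriesNumber"),
  "00200012" = c("IS", "AcquisitionNumber"),
  "00200013" = c("IS", "InstanceNumber"),
  "00200032" = c("DS", "ImagePositionPatient"),
  "00200037" = c("DS", "ImageOrientationPatient"),
  "00201041" = c("DS", "SliceLocation"),
  "00204000" = c("LT", "ImageComments"),
  "00209113" = c("SQ", "PlanePositionSequence"),
  "00209116" = c("SQ", "PlaneOrientationSequence"),
  # image pixel description
  "00280002" = c("US", "SamplesPerPixel"),
  "00280004" = c("CS", "PhotometricInterpretation"),
  "00280008" = c("IS", "NumberOfFrames"),
  "00280010" = c("US", "Rows"),
  "00280011" = c("US", "Columns"),
  "00280030" = c("DS", "PixelSpacing"),
  "00280100" = c("US", "BitsAllocated"),
  "00280101" = c("US", "BitsStored"),
  "00280102" = c("US", "HighBit"),
  "00280103" = c("US", "PixelRepresentation"),
  "00281052" = c("DS", "RescaleIntercept"),
  "00281053" = c("DS", "RescaleSlope"),
  "00289110" = c("SQ", "PixelMeasuresSequence"),
  "00289145" = c("SQ", "PixelValueTransformationSequence"),
  # Philips-style private: water-fat shift in pixels, when the vendor stores it
  "20010010" = c("LO", "PrivateCreator2001"),
  "20011022" = c("FL", "WaterFatShift"),
  # Scanco-style private calibration block (synthetic layout, see vignette)
  "00290010" = c("LO", "PrivateCreator0029"),
  "00291004" = c("DS", "ScancoMuScaling"),
  "00291005" = c("DS", "ScancoDensitySlope"),
  "00291006" = c("DS", "ScancoDensityIntercept"),
  "00291007" = c("DS", "ScancoMuWater"),
  # enhanced multi-frame scaffolding
  "52009229" = c("SQ", "SharedFunctionalGroupsSequence"),
  "52009230" = c("SQ", "PerFrameFunctionalGroupsSequence"),
  "7FE00010" = c("OW", "PixelData")
)

.dcm_keyword_to_tag <- local({
  kw <- vapply(.dcm_dict, `[`, character(1), 2L)
  stats::setNames(names(.dcm_dict), kw)
})

#' Look up a DICOM tag by keyword
#'
#' Returns the 8-digit hex tag string ("ggggeeee") for a DICOM attribute
#' keyword known to the package dictionary.
#'
#' @param keyword DICOM attribute keyword, e.g. `"EchoTime"`.
#' @return Uppercase hex tag string.
#' @export
dcm_tag <- function(keyword) {
  tag <- .dcm_keyword_to_tag[[keyword]]
  if (is.null(tag)) stop("unknown DICOM keyword: ", keyword)
  tag
}

dcm_vr_for_tag <- function(tag) {
  e <- .dcm_dict[[tag]]
  if (is.null(e)) "UN" else e[[1L]]
}

dcm_keyword_for_tag <- function(tag) {
  e <- .dcm_dict[[tag]]
  if (is.null(e)) NA_character_ else e[[2L]]
}

# VRs whose explicit-VR encoding uses a 2-byte reserved field + 4-byte length
.dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# string-like VRs (character payload); LT/ST/UT never split on backslash
.dcm_string_vrs <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH",
                     "ST", "TM", "UC", "UI", "UR", "UT")
.dcm_text_vrs <- c("LT", "ST", "UT")

.uid_implicit_le <- "1.2.840.10008.1.2"
.uid_explicit_le <- "1.2.840.10008.1.2.1"
.uid_mr_storage <- "1.2.840.10008.5.1.4.1.1.4"
.uid_enhanced_mr_storage <- "1.2.840.10008.5.1.4.1.1.4.1"
.uid_ct_storage <- "1.2.840.10008.5.1.4.1.1.2"
.uid_cr_storage <- "1.2.840.10008.5.1.4.1.1.1"
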