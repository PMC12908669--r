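# Low-level DICOM Part-10 serialization, checked against itself
# (write/read identity) and against pydicom as an independent oracle.

make_toy_dataset <- function() {
  ds <- list()
  ds <- mskmids:::ds_set(ds, "SOPClassUID", "1.2.840.10008.5.1.4.1.1.4")
  ds <- mskmids:::ds_set(ds, "SOPInstanceUID", "2.25.123456789")
  ds <- mskmids:::ds_set(ds, "Modality", "MR")
  ds <- mskmids:::ds_set(ds, "PatientName", "Toy^Patient")
  ds <- mskmids:::ds_set(ds, "ImageType", c("ORIGINAL", "PRIMARY", "MAGNITUDE"))
  ds <- mskmids:::ds_set(ds, "ImagePositionPatient", c(-12.5, 3.25, 7))
  ds <- mskmids:::ds_set(ds, "EchoTime", 12.345)
  ds <- mskmids:::ds_set(ds, "Rows", 2L)
  ds <- mskmids:::ds_set(ds, "Columns", 3L)
  ds <- mskmids:::ds_set(ds, "BitsAllocated", 16L)
  ds <- mskmids:::ds_set(ds, "BitsStored", 16L)
  ds <- mskmids:::ds_set(ds, "HighBit", 15L)
  ds <- mskmids:::ds_set(ds, "PixelRepresentation", 1L)
  ds <- mskmids:::ds_set(ds, "SamplesPerPixel", 1L)
  ds <- mskmids:::ds_set(ds, "PhotometricInterpretation", "MONOCHROME2")
  ds[[dcm_tag("SharedFunctionalGroupsSequence")]] <- list(
    vr = "SQ",
    value = list(
      mskmids:::ds_set(list(), "EffectiveEchoTime", 10),
      mskmids:::ds_set(list(), "EffectiveEchoTime", 20)
    ))
  ds <- mskmids:::ds_set(ds, "PixelData",
                         mskmids:::.pixels_raw(matrix(c(-5L, 0L, 7L,
                                                        300L, -300L, 12L),
                                                      2L, 3L, byrow = TRUE)),
                         vr = "OW")
  ds
}

test_that("write/read round-trips tags, sequences and pixels", {
  ds <- make_toy_dataset()
  tf <- tempfile(fileext = ".dcm")
  write_dicom_file(tf, ds)
  back <- read_dicom_file(tf)
  expect_identical(back$dataset[["00080060"]]$value, "MR")
  expect_identical(back$dataset[[dcm_tag("ImageType")]]$value,
                   c("ORIGINAL", "PRIMARY", "MAGNITUDE"))
  expect_equal(back$dataset[[dcm_tag("ImagePositionPatient")]]$value,
               c(-12.5, 3.25, 7))
  expect_equal(back$dataset[[dcm_tag("EchoTime")]]$value, 12.345)
  sq <- back$dataset[[dcm_tag("SharedFunctionalGroupsSequence")]]
  expect_identical(sq$vr, "SQ")
  expect_length(sq$value, 2L)
  expect_equal(sq$value[[2L]][[dcm_tag("EffectiveEchoTime")]]$value, 20)
  expect_identical(back$dataset[[dcm_tag("PixelData")]]$value,
                   ds[[dcm_tag("PixelData")]]$value)
  expect_identical(back$meta[["00020010"]]$value, "1.2.840.10008.1.2.1")
})

test_that("non-DICOM input is recognized and rejected", {
  tf <- tempfile()
  writeLines("definitely not dicom, just text that is long enough to matter",
             tf)
  expect_false(is_dicom_file(tf))
  expect_error(read_dicom_file(tf), "DICOM")
})

test_that("pydicom reads files written by this package identically", {
  ds <- make_toy_dataset()
  tf <- tempfile(fileext = ".dcm")
  write_dicom_file(tf, ds)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "import pydicom",
    "d = pydicom.dcmread(sys.argv[1])",
    "out = {",
    " 'modality': str(d.Modality),",
    " 'image_type': list(d.ImageType),",
    " 'ipp': [float(x) for x in d.ImagePositionPatient],",
    " 'te': float(d.EchoTime),",
    " 'rows': int(d.Rows), 'cols': int(d.Columns),",
    " 'n_items': len(d.SharedFunctionalGroupsSequence),",
    " 'ete2': float(d.SharedFunctionalGroupsSequence[1].EffectiveEchoTime),",
    " 'pixels': [int(x) for x in d.pixel_array.flatten()],",
    "}",
    "print(json.dumps(out))"), script)
  res <- system2(python_bin(), c(script, tf), stdout = TRUE, stderr = TRUE)
  parsed <- jsonlite::fromJSON(res[length(res)])
  expect_identical(parsed$modality, "MR")
  expect_identical(parsed$image_type, c("ORIGINAL", "PRIMARY", "MAGNITUDE"))
  expect_equal(parsed$ipp, c(-12.5, 3.25, 7))
  expect_equal(parsed$te, 12.345)
  expect_identical(parsed$n_items, 2L)
  expect_equal(parsed$ete2, 20)
  expect_identical(parsed$pixels,
                   c(-5L, 0L, 7L, 300L, -300L, 12L))
})

test_that("this package reads files written by pydicom (incl. implicit VR)", {
  for (implicit in c(FALSE, TRUE)) {
    out <- tempfile(fileext = ".dcm")
    script <- tempfile(fileext = ".py")
    writeLines(c(
      "import sys",
      "import numpy as np",
      "import pydicom",
      "from pydicom.dataset import Dataset, FileMetaDataset",
      "from pydicom.uid import ImplicitVRLittleEndian, ExplicitVRLittleEndian",
      "meta = FileMetaDataset()",
      "meta.MediaStorageSOPClassUID = '1.2.840.10008.5.1.4.1.1.4'",
      "meta.MediaStorageSOPInstanceUID = '2.25.42'",
      sprintf("meta.TransferSyntaxUID = %s",
              if (implicit) "ImplicitVRLittleEndian"
              else "ExplicitVRLittleEndian"),
      "ds = Dataset()",
      "ds.file_meta = meta",
      "ds.SOPClassUID = '1.2.840.10008.5.1.4.1.1.4'",
      "ds.SOPInstanceUID = '2.25.42'",
      "ds.Modality = 'MR'",
      "ds.EchoTime = '7.5'",
      "ds.ImageOrientationPatient = [1,0,0,0,1,0]",
      "ds.Rows = 2; ds.Columns = 2",
      "ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15",
      "ds.PixelRepresentation = 1; ds.SamplesPerPixel = 1",
      "ds.PixelData = np.array([[1, -2], [30000, 4]], dtype=np.int16).tobytes()",
      "ds.save_as(sys.argv[1], enforce_file_format=True)"), script)
    res <- system2(python_bin(), c(script, out), stdout = TRUE, stderr = TRUE)
    expect_true(file.exists(out), info = paste(res, collapse = "\n"))
    back <- read_dicom_file(out)
    expect_identical(mskmids:::ds_get(back$dataset, "Modality"), "MR")
    expect_equal(mskmids:::ds_get(back$dataset, "EchoTime"), 7.5)
    expect_equal(mskmids:::ds_get(back$dataset, "ImageOrientationPatient"),
                 c(1, 0, 0, 0, 1, 0))
    px <- mskmids:::.decode_pixels(back$dataset[[dcm_tag("PixelData")]]$value,
                                   2L, 2L, signed = TRUE)
    expect_identical(as.vector(t(px)), c(1L, -2L, 30000L, 4L))
  }
})
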