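# Conformance validation: self-consistency on converter output, and
# mutation coverage — every rule must fire exactly once on its designed
# defect and never on intact trees.

n_code <- function(issues, code) sum(issues$code == code)

test_that("the converter's own output validates with zero errors", {
  issues <- validate_dataset(converted_root())
  expect_identical(nrow(issues[issues$severity == "error", ]), 0L)
})

test_that("check_required_fields is a pure registry lookup", {
  ct <- list(XRayEnergy = 120, XRayExposure = 100, ConvolutionKernel = "B30",
             RescaleIntercept = -1024, RescaleSlope = 1)
  expect_identical(check_required_fields(ct, "ct"), character(0))
  ct$ConvolutionKernel <- NULL
  expect_identical(check_required_fields(ct, "ct"), "ConvolutionKernel")
  expect_setequal(check_required_fields(ct[1:2], "hrpqct"),
                  c("ConvolutionKernel", "RescaleIntercept", "RescaleSlope",
                    "ScancoMuScaling", "ScancoDensitySlope",
                    "ScancoDensityIntercept", "ScancoMuWater"))
})

test_that("each validation rule fires exactly once on its designed mutation", {
  # V1: unparseable filename
  root <- copy_tree(converted_root())
  file.copy(file.path(root, "sub-01/ct/sub-01_ct.nii.gz"),
            file.path(root, "sub-01/ct/badname.nii.gz"))
  issues <- validate_dataset(root)
  expect_identical(n_code(issues, "V1"), 1L)
  expect_identical(sum(issues$severity == "error"), 1L)

  # V2: suffix moved under the wrong modality folder
  root <- copy_tree(converted_root())
  dir.create(file.path(root, "sub-01/mr-quant"), showWarnings = FALSE)
  for (ext in c(".nii.gz", ".json")) {
    file.rename(file.path(root, paste0("sub-01/ct/sub-01_ct", ext)),
                file.path(root, paste0("sub-01/mr-quant/sub-01_ct", ext)))
  }
  issues <- validate_dataset(root)
  expect_identical(n_code(issues, "V2"), 1L)

  # V3: required field deleted from a mese sidecar
  root <- copy_tree(converted_root())
  p <- file.path(root, "sub-01/mr-anat/sub-01_part-mag_mese.json")
  main <- jsonlite::read_json(p, simplifyVector = TRUE)
  main$RefocusingFlipAngle <- NULL
  jsonlite::write_json(main, p, auto_unbox = TRUE, digits = NA)
  issues <- validate_dataset(root)
  expect_identical(n_code(issues, "V3"), 1L)
  expect_true(grepl("RefocusingFlipAngle",
                    issues$message[issues$code == "V3"]))

  # V4: ct volume replaced by a 2D image
  root <- copy_tree(converted_root())
  flat <- RNifti::asNifti(matrix(0, 8, 8))
  RNifti::writeNifti(flat, file.path(root, "sub-01/ct/sub-01_ct.nii.gz"))
  issues <- validate_dataset(root)
  expect_identical(n_code(issues, "V4"), 1L)

  # V5: EchoTime array truncated relative to the 4th axis
  root <- copy_tree(converted_root())
  p <- file.path(root, "sub-01/mr-anat/sub-01_part-mag_megre.json")
  main <- jsonlite::read_json(p, simplifyVector = TRUE)
  main$EchoTime <- main$EchoTime[1:2]
  jsonlite::write_json(main, p, auto_unbox = TRUE, digits = NA)
  issues <- validate_dataset(root)
  expect_identical(n_code(issues, "V5"), 1L)

  # V6: patient-identifying key injected into a main sidecar
  root <- copy_tree(converted_root())
  p <- file.path(root, "sub-01/cr/sub-01_cr.json")
  main <- jsonlite::read_json(p, simplifyVector = TRUE)
  main$PatientName <- "SENTINEL^PHI"
  jsonlite::write_json(main, p, auto_unbox = TRUE, digits = NA)
  issues <- validate_dataset(root)
  expect_identical(n_code(issues, "V6"), 1L)

  # V7: a subject missing from participants.tsv
  root <- copy_tree(converted_root())
  write_participants(data.frame(participant_id = "sub-99"), root)
  issues <- validate_dataset(root)
  expect_identical(n_code(issues, "V7"), 1L)
  expect_identical(issues$severity[issues$code == "V7"], "warning")

  # V8: a reserved suffix present in the tree
  root <- copy_tree(converted_root())
  img <- RNifti::asNifti(array(0, c(4, 4, 2)))
  dir.create(file.path(root, "sub-01/mr-quant"), showWarnings = FALSE)
  RNifti::writeNifti(img, file.path(root,
                                    "sub-01/mr-quant/sub-01_vel.nii.gz"))
  jsonlite::write_json(list(), file.path(root,
                                         "sub-01/mr-quant/sub-01_vel.json"))
  issues <- validate_dataset(root)
  expect_identical(n_code(issues, "V8"), 1L)
  expect_identical(issues$severity[issues$code == "V8"], "warning")
})

test_that("strictness upgrades unknown-key warnings to errors", {
  root <- copy_tree(converted_root())
  p <- file.path(root, "sub-01/ct/sub-01_ct.json")
  main <- jsonlite::read_json(p, simplifyVector = TRUE)
  main$MyCustomField <- 7
  jsonlite::write_json(main, p, auto_unbox = TRUE, digits = NA)
  lax <- validate_dataset(root)
  expect_identical(sum(lax$severity == "error"), 0L)
  strict <- validate_dataset(root, strict = TRUE)
  expect_identical(sum(strict$severity == "error"), 1L)
})

test_that("validation reports serialize as JSON lines", {
  issues <- rbind(
    mskmids:::.issue("error", "V3", "x.json", "missing field"),
    mskmids:::.issue("warning", "V7", "participants.tsv", "not covered"))
  tf <- tempfile(fileext = ".jsonl")
  write_validation_report(issues, tf)
  lines <- readLines(tf)
  expect_length(lines, 2L)
  parsed <- jsonlite::fromJSON(lines[1L])
  expect_identical(parsed$code, "V3")
})
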