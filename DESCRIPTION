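Package: mskmids
Title: Curation, Conversion and Validation of Musculoskeletal Imaging Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for curating musculoskeletal (MSK) imaging studies in a
    BIDS/MIDS-style directory standard: detection of supported DICOM
    acquisitions (multi-echo gradient- and spin-echo MRI, DESS, conventional
    and photon-counting CT, HR-pQCT, plain radiography), conversion to
    gzipped NIfTI volumes with up to three JSON sidecars (minimal
    interpretive header, sensitive patient header, full serialized DICOM
    header), multi-echo stacking on the fourth image axis, anonymization by
    construction, dataset conformance validation, and lossless
    reconstruction of the original DICOM series from a converted dataset.
    Includes a deterministic synthetic DICOM fixture generator covering
    every supported acquisition so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
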