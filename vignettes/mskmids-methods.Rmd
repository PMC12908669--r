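---
title: "Converting and curating musculoskeletal imaging data with mskmids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting and curating musculoskeletal imaging data with mskmids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mskmids)
```

## The data model

`mskmids` organizes musculoskeletal imaging studies the way the
BIDS/MIDS family of standards organizes neuroimaging: one folder per
participant (optionally per session), one modality folder per data kind,
one NIfTI file per image volume, JSON sidecars next to each volume, and
a `participants.tsv` table at the root. Unlike brain-centric BIDS, the
modality folders sit side by side at the same level: `ct` (all CT
flavors), `cr` (projectional radiography), `mr-anat` (anatomical MRI,
including multi-echo series), `mr-quant` (quantitative maps), with `us`
and `seg` reserved.

The unit of conversion is the **image volume**: a 2–4 axis voxel array
with a 4×4 RAS affine, ordered axis labels, and a complex-part label.
Three design rules shape everything downstream:

1. **Echoes live on the 4th axis.** Multi-echo gradient-echo (`megre`)
   and spin-echo (`mese`) series become single 4D files with axes
   `(x, y, z, echo)`, the sidecar's `EchoTime` array giving the echo
   times in 4th-axis order (ms, strictly increasing). Stacks with
   unequal slice counts per echo or duplicated (echo, position) frames
   are rejected rather than repaired.
2. **Complex parts are separate files.** Magnitude/phase (or
   real/imaginary) components become `part-mag`/`part-phase`
   (`part-real`/`part-imag`) volumes, following the BIDS convention even
   though NIfTI could store complex voxels; a mixed series whose frames
   carry no distinguishing image-type token is rejected as ambiguous.
3. **Strict conversion beats broad conversion.** The converter registry
   only converts what it positively recognizes. A single-echo MR series
   with no sequence token matches nothing and is skipped with a
   disposition message. This is what makes the output guarantee
   meaningful: every main sidecar contains all — and essentially only —
   the fields its suffix requires.

## Geometry

DICOM stores patient-space geometry in LPS coordinates:
`ImagePositionPatient` is the center of the first transmitted voxel and
`ImageOrientationPatient` holds the row and column direction cosines.
With voxel index convention `(i, j, k)` = (column, row, slice) —
matching NIfTI's x-fastest storage — the affine columns are the row
direction scaled by the column spacing, the column direction scaled by
the row spacing, and the inter-slice displacement vector (or
normal × slice thickness for a single slice); the origin is the first
slice's position. The LPS→RAS conversion negates the first two
coordinate rows exactly once, in the affine; voxel data are never
flipped, which keeps DICOM reconstruction lossless.

Numerical guards, pinned so tests can assert them: orientation cosines
must agree across frames within 10⁻³ per component; inter-slice gaps
must be uniform within 1% (irregular stacks are rejected, not
resampled); slices are ordered by the projection of their position onto
the slice normal, ties broken by instance number, so the result is
independent of file enumeration order. Echo times are clustered with a
10⁻³ ms tolerance to absorb vendor header jitter. Projectional images
(CR) carry no patient-space frame; they get a 2D volume whose affine
encodes only the detector pixel spacing.

Phase images are delivered in radians in `[-π, π]`. After the linear
rescale, values already inside that interval are taken as radians;
otherwise the stored range is mapped linearly so its extremes land on
±π. Vendors do not standardize phase storage, so this heuristic is
deliberately simple and overridable per converter plugin; it is exactly
invertible (and hence round-trippable) only when the stored rescale maps
directly into radians, which the tests exercise.

## Vendor metadata mapping

The sidecar extractor takes required fields from their canonical DICOM
attributes and fills vendor gaps explicitly:

- **WaterFatShift** (pixels, `megre`): read from the vendor tag when one
  is present, otherwise computed as the water–fat frequency shift
  divided by the readout bandwidth,
  `B0 [T] × 42.577 [MHz/T] × 3.4 [ppm] / PixelBandwidth [Hz/px]`,
  and flagged with `WaterFatShiftComputed: true` so downstream fitting
  knows its provenance.
- **RefocusingFlipAngle** (degrees, `mese`): public DICOM defines no
  attribute for the refocusing-train angle. The reader takes the
  `FlipAngle` inside `MRTimingAndRelatedParametersSequence` of enhanced
  files (where spin-echo vendors record the echo-train angle), falling
  back to the top-level `FlipAngle` for classic spin-echo files. This is
  a documented mapping choice, not a standard guarantee.
- **Scanco calibration** (`hrpqct`): the four density-calibration values
  (`ScancoMuScaling`, `ScancoDensitySlope`, `ScancoDensityIntercept`,
  `ScancoMuWater`) are read from a private block; the synthetic fixtures
  use a clearly-labelled private layout (group `0029`, creator
  `"SCANCO-style-fixture"`) rather than imitating any real device's
  private dictionary.
- **Sequence-kind detection** resolves the well-known ambiguity between
  `ScanningSequence` and `EchoPulseSequence` by checking the former
  first, then the latter, then sequence-name tokens. Quantitative maps
  (`t1`/`t2`/`wt2`) have no dedicated DICOM tag at all, so they are
  detected via configurable series-description tokens — a configuration
  point, not a heuristic the package pretends is reliable.
- Where the modality table prints `X-RayTubeCurrent`, the JSON key is
  the DICOM keyword spelling `XRayTubeCurrent`; and although the table
  assigns radiography no file suffix, files need one, so the `cr` folder
  uses suffix `cr`.

## Anonymization model

Anonymity is by construction, not by redaction. The main sidecar is
assembled only from whitelisted interpretive fields, so it can never
contain identifying data (validator rule V6 double-checks). Everything
identifying — a frozen, versioned list seeded from the DICOM basic
confidentiality profile plus fields this standard relocates, such as
`InstitutionName` — goes to the `_patient.json` sidecar, which can be
deleted as a single file. In anonymize mode the patient sidecar is not
written *and* the same tags are removed (not blanked — a blanked tag
still advertises what was measured) from the serialized extra header,
recursively through sequence items, because an unscrubbed full header
would re-leak everything. The fixture generator plants sentinel strings
(`SENTINEL^PHI` etc.) in every identifying field so the test suite can
assert, byte-wise over every output file, that nothing leaks.

The extra sidecar serializes every non-pixel tag as
`{"ggggeeee": {"vr": ..., "value": [...]}}` (binary payloads base64,
sequences recursing under `items`), which is exactly invertible and is
what makes DICOM reconstruction possible: pixel planes are re-derived
from the voxels by inverting the stored rescale and rounding to the
nearest stored integer — exact for unmodified integer data, documented
as approximate for float-valued derived volumes. Reconstruction
generates fresh SOP instance UIDs (re-importing processed data into a
PACS must not collide with originals) while restoring series and study
UIDs verbatim.

## What the synthetic fixtures emulate — and what they don't

The generators produce the acquisition structures the converters must
handle: a classic one-file-per-frame gradient-echo series with GE-style
tags (magnitude and phase parts, 3 echoes × 4 slices by default), a
single enhanced multi-frame file with Philips-style shared/per-frame
functional groups (5 echoes × 3 slices), CT variants differing exactly
in their discriminating tags (Scanco-style manufacturer for HR-pQCT,
photon-counting detector type for PC-CT), and a 2D radiograph. Phantoms
carry known physics so quantitative checks have ground truth: the MR
disk decays mono-exponentially (S0 = 1000; T2* = 20 ms for gradient
echo, T2 = 50 ms for spin echo) with seeded Gaussian noise at 2% of S0;
the CT cylinder is water (≈0 HU) around a bone-like core (≈+700 HU)
under a slope 1 / intercept −1024 rescale. Manufacturer strings say
`"-style-fixture"` — fixtures are vendor-shaped, never forged — and
detection predicates match structural tokens, not vendor names, so real
data and fixtures take the same code path.

What passing tests therefore demonstrate: correct parsing of both DICOM
encodings, correct geometry, echo ordering, part separation, sidecar
extraction, anonymization and bidirectionality *for well-formed
little-endian uncompressed data*. What they cannot demonstrate: behavior
on compressed transfer syntaxes, real private-tag dialects beyond the
fields read here, gantry-tilted or irregularly spaced acquisitions
(rejected by design), or vendor phase conventions beyond the default
heuristic.

## Open choices this package had to make

- The modality table lists `dess-fid` and `dess_echo` with inconsistent
  separators; both are registered verbatim, and the filename parser
  matches suffixes longest-first before entity tokenization so an
  underscore inside a registered suffix survives. Whether the
  inconsistency is intentional upstream is unknown; preserving it is the
  conservative reading.
- DESS acquisitions are listed as 3D, so the FID-like and echo-like
  images are emitted as separate 3D volumes per suffix rather than one
  4D stack.
- Sessions are supported at both folder and filename level but never
  invented: the converter writes a session only when the caller supplies
  one.
- The patient/extra sidecar filenames (`_patient.json`, `_extra.json`)
  keep all three headers adjacent to the image under one basename.
- Validation treats unknown extra keys in a main sidecar as warnings
  (errors under `strict = TRUE`), absent extra sidecars as compliant,
  and reserved suffixes (`vel`, `diff`, `seg`, `us`) as parse-valid but
  "reserved, not yet specified" warnings; `derivatives/` trees are
  checked for grammar only, since derived content is user-defined.

## Problem sizes and verification

All tests and the acceptance script run on fixtures of 32×32 in-plane
matrices with 3–6 slices and 3–5 echoes — generously above the
structural edge cases they probe and small enough to keep the full suite
fast. The affine is verified against a brute-force oracle that maps
every frame corner through the raw DICOM formula (agreement better than
10⁻⁶ mm over six orientations including oblique ones); the DICOM
round trip is verified pixel-for-pixel and tag-for-tag; the low-level
Part-10 codec is cross-checked against pydicom in both directions; and
the T2* of the gradient-echo phantom is re-estimated from the converted
4D volume by a log-linear fit across echoes, landing within a few
percent of the generating value — a guard against silent echo-axis
corruption.
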