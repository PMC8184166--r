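---
title: "Sealing DICOM series with encrypted DRR blocks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sealing DICOM series with encrypted DRR blocks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A radiology study is transmitted as a *series* of single-frame DICOM files —
often hundreds per patient. Per-image protections (checksums, watermarks,
per-file encryption) authenticate individual files but say nothing about the
*set*: an adversary on the network can insert a slice from another patient,
duplicate an existing slice, delete one, or nudge pixel values, and every
surviving file still checks out. `drrseal` protects the dataset as a whole.

The idea is that a digitally reconstructed radiograph (DRR) — a synthetic
X-ray obtained by averaging the Hounsfield-unit (HU) volume along one patient
axis — is a deterministic functional of *every* slice. The sender computes
the DRR, splits it into a grid of blocks, traverses them in zig-zag order,
and AES-encrypts each block into a JSON sidecar (the *sealed manifest*). The
receiver regenerates the DRR from the files it actually received and compares
it, block by block, with the decrypted original. Any insertion, deletion, or
pixel modification along the projection axis changes some projection mean,
so the regenerated DRR no longer matches.

```{r, eval = FALSE}
library(drrseal)

series <- tempfile("series-")
generate_phantom(phantom_spec(seed = 1), series)

manifest <- seal_series(series, passphrase = "shared-secret")
report <- verify_series(series, manifest, passphrase = "shared-secret")
glance(report)
```

## Pipeline and assumptions

Both ends run the identical pipeline: read the Part-10 files, validate
attributes, sort by Slice Location (tag 0020,1041; Instance Number and SOP
Instance UID break ties), convert stored values to HU with the rescale
slope/intercept, stack into a `[z, y, x]` volume resampled along z to the
in-plane pixel spacing, and average along the chosen axis. Determinism is the
load-bearing assumption: all arithmetic is double precision with a fixed
accumulation order, block serialization is a frozen dialect (little-endian
`uint32` dimensions, row-major `f64` pixels) recorded in the manifest, and
AES-CBC decryption restores plaintext bit for bit. An unchanged series
therefore reproduces the DRR *exactly*, which is why the PASS criterion can
demand RMSE equal to zero rather than "small".

The scheme assumes a shared passphrase (key transport is out of scope), and
it protects image content only: it deliberately ignores header-only edits
(checksum schemes already cover those), and it cannot notice wholesale
replacement of *both* the dataset and its sidecar — the verifier has no
root of trust beyond the passphrase.

## Parameters that matter

* **Projection direction** (`coronal` default, `sagittal`, `axial`): the
  coronal view is the conventional choice for visual plausibility; all three
  are supported and the manifest records which one was sealed. Direction
  affects which tampers are most visible: a modification inside slice *k*
  lands in one row of a coronal/sagittal DRR but is spread across the whole
  axial image.
* **Block grid** (`4x4` default, 16 blocks; `8x8` supported): finer grids
  localize tampering better at the cost of more ciphertext entries. A
  512x512 DRR gives 128x128 blocks; 256x256 gives 64x64.
* **Histogram range** (`-1024..+3072` HU): the CT HU scale. Histograms are
  built on integers (round half away from zero, clamp), so the range is only
  a binning choice; for non-CT intensities it is configurable via
  `hist_range` in `verify_series()`. What a sensible range for MRI
  intensities is remains open — intensities are scanner-relative — so the
  package does not guess one.
* **KDF iterations** (200,000, PBKDF2-HMAC-SHA256, 16-byte random salt):
  an ordinary interactive-use hardness setting; the salt and count travel in
  the manifest.
* **Tamper amplitude** (`+-10` HU default in `tamper_op()`): a perturbation
  near the limit of human grey-level discrimination, i.e. the interesting
  adversary. With 40 slices in a projection ray, a 10 HU change in one slice
  moves a coronal DRR pixel by 0.25 HU — which is why DRR pixels are kept at
  float precision and only quantized for histograms.

## Numerical choices

* **RMSE tolerance is exactly zero.** Identical pipelines on identical bytes
  produce identical doubles; any nonzero RMSE is evidence of change, not
  noise. Histogram comparison operates on quantized pixels; both criteria
  (all 16 block differences zero *and* RMSE zero) must hold for PASS — the
  conservative conjunction of the two reported criteria.
* **Block-level, not image-level, histograms.** Two different volumes can
  share a global histogram; sixteen local histograms are far harder to
  preserve while editing content.
* **Rounding half away from zero** before binning, rather than R's default
  round-half-to-even, so boundary pixels bin identically regardless of
  parity.
* **Tied slice locations.** Linear interpolation positions planes by their
  slice location, including non-uniform spacing. A *duplicated* slice makes
  that map ill-posed (two planes at one location) — and a piecewise-linear
  function through duplicated identical points would be unchanged, making a
  bit-identical duplicate invisible to any resampled projection. When sorted
  locations are not strictly increasing, `build_volume()` therefore assigns
  uniform index-based positions between the first and last location, matching
  the projection pseudo-view in which every received plane contributes to the
  stack average. A duplicated plane then shifts the reconstruction and is
  caught by RMSE, and the duplicate SOP Instance UID is independently
  reported by validation.
* **Degenerate inputs.** Non-divisible DRR dimensions are a hard error by
  default; opting into `pad = "air"` pads bottom/right with -1024 HU and
  records it in the manifest so the receiver pads identically. All-equal
  slice locations, mixed geometries, and unsortable series are errors at the
  volume stage; `verify_series()` converts every such failure into a FAIL
  report with a reason rather than raising.

## Cryptographic choices

AES-256 in CBC mode with PKCS#7 padding and a fresh random IV per block, via
OpenSSL. No authentication tag is attached: integrity is the job of the
content comparison itself (a MAC would authenticate the *sidecar*, not the
*dataset*), and a padding failure on decryption is surfaced as a wrong-key /
corruption error. The zig-zag transmission order means an adversary who
intercepts ciphertext blocks cannot trivially reassemble them in raster
order; it contributes obscurity of arrangement, not confidentiality, which
comes from AES.

## What the phantom emulates — and what it does not

`generate_phantom()` writes deterministic CT-like series: ellipsoids of
distinct HU (soft tissue 40, bone 700, near-air cavity -950) on an air
background, unsigned 16-bit stored pixels with slope 1 / intercept -1024,
unique SOP Instance UIDs, ascending slice locations, optional seeded Gaussian
noise, and optional attribute defects for validation tests. The default desk
scale is 64x64x40 at 1 mm isotropic spacing, so a full
generate-seal-tamper-verify cycle runs in seconds; tests use 32x32x12 where
geometry suffices. These sizes are the package's study conditions, not
limits of the method.

What passing tests on phantoms demonstrate is the *mechanism*: exact
round-trip zeros, and nonzero metrics under every simulated attack. What
they do not demonstrate is performance on real anatomy — real CT has texture,
scanner noise, non-integer rescale slopes, and gantry-tilt geometry the
phantom does not model, and the RMSE magnitudes reported on clinical data are
not reproducible from synthetic ellipsoids (nor does the bench claim them).

## Known limitations

* **Cancellation within a ray.** Opposite-sign modifications inside the same
  projection ray (e.g. +10 and -10 HU in one coronal column) can cancel in
  the mean. The histogram criterion catches many such cases but not all;
  `tamper_op(all_positive = TRUE)` exists so soundness tests stay outside the
  cancellation class. Projecting a second direction would shrink the class
  further.
* **Dataset replacement.** If the adversary replaces the series *and* the
  sealed manifest consistently (knowing the passphrase), verification
  passes; this is inherent to any scheme whose root of trust is the shared
  secret.
* **Scope.** Single-frame, uncompressed, little-endian DICOM image objects
  only: no multi-frame objects, RT objects, compressed transfer syntaxes, or
  DICOM networking. Validation rules default to a minimal set (one type-1c
  rule) and are user-extensible from JSON, since a complete conformance rule
  list is modality-specific.
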