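---
title: "Temporal-delta compression of dynamic CT perfusion data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-delta compression of dynamic CT perfusion data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicopp)
```

## The model

A dynamic CT perfusion (CTP) acquisition is a 4D array `I(x, t)` of 16-bit
signed intensities: `n` time steps (typically 24) of a `Z × Y × X` volume.
The codec rests on one empirical property of such data: the *temporal range*
`max V_x − min V_x` of a voxel's time series `V_x` is small for almost all
voxels. Brain tissue barely enhances; only vessels (and voxels swept by head
motion) span wide ranges; air and bone are essentially constant up to noise.

Compression therefore stores, per voxel,

* the temporal minimum `C(x) = min V_x` (16 bits), and
* the `n` deltas `Δ(x, t) = I(x, t) − C(x)`, each at the fixed width
  `B(x) = ⌈log₂(max V_x − min V_x + 1)⌉` bits.

Any base value between the minimum and maximum would make the deltas
non-negative; the minimum is used, which keeps every delta in
`0 .. 2^B − 1` and makes the decoding rule a single unsigned add. The width
formula is evaluated in exact integer arithmetic (bit-length of the range),
never via a floating-point logarithm, so boundary ranges such as 255 vs 256
can never round the wrong way.

Because each voxel is encoded purely from its own series, compression is
embarrassingly parallel and — more importantly for a reference
implementation — *deterministic*: any traversal order or chunking of the
voxel set produces bit-identical output. The test suite checks this by
compressing single-voxel sub-images and comparing their records with the
full image's.

## Storage layout and constant-time access

Variable-width records cannot live in one fixed-stride array, so the deltas
are packed contiguously into a stream `D` of 32-bit words: stream bit `b`
lives in word `⌊b/32⌋` at bit position `b mod 32`, values LSB-first. The bit
order within words is a representation choice the on-disk format must pin
down; LSB-first was chosen because a field is then extracted with one shift
and one mask (two when it straddles a word boundary). Since `B ≤ 16 < 32`,
every field spans at most two words — the suite verifies this behaviourally
by corrupting all *other* words and observing unchanged reads.

Voxels are linearised `j = (z·Y + y)·X + x` (x fastest, 0-based), and the
offset array `O` is the exclusive prefix sum of `n·B`. Reading `I(x, t)` is
then

```
C[j] + read_bits(D, O[j] + t·B[j], B[j])
```

— one offset computation, one bounded bit read, one addition, independent of
image size. Offsets are derivable from `B` by a single traversal, so the
container format omits them by default; in memory they are always
materialised for O(1) access. They are held as 64-bit quantities (doubles on
the R side, exact far beyond any realistic stream length): at full clinical
scale, `m ≈ 84·10⁶` voxels times up to `24 × 16` bits per voxel exceeds the
32-bit offset range, so 32-bit offsets would be a correctness bug even though
they remain the convention used for quoting comparable compression ratios
(`compression_stats(..., offset_bits = 32)`, the default).

Two further representation decisions: temporally constant voxels get
`B = 0` and occupy no delta bits at all (the formula's own value for a
range of one, and the best case for the ratio), and intensities are treated
as 16-bit *signed* so Hounsfield values below zero (air is about −1000 HU)
are first-class; the deltas themselves are always unsigned.

## Compressed-domain masking

The first stage of a common CTP noise-reduction filter is the double
threshold 0–15 HU. `threshold_mask()` evaluates `lo ≤ I(x, t) ≤ hi`
(inclusive on both ends — the convention had to be fixed and is documented
here) either per time step or reduced over time with all/any folds. On
compressed input it never materialises the 4D array: the per-voxel bound
`C ≤ I ≤ C + 2^B − 1` resolves any voxel whose interval lies entirely
inside or outside the band without touching a single delta bit; only
straddling voxels decode their `n` samples. The mask is *exactly* equal to
the uncompressed reference by construction, and the suite asserts this over
seeded phantoms tuned so that many voxels straddle the band. The achieved
pruning fraction is reported (as an attribute and in the CLI log) but never
asserted against a threshold — it is a property of the data, not of the
code.

Thresholds are interpreted in stored intensity units. DICOM rescale
slope/intercept are recorded as provenance when a series is loaded but never
applied: losslessness is defined on stored bits.

## The phantom generator

All tests run without patient data. The generator emulates the *statistical*
structure the codec exploits, not anatomy: a concentric head (background
air at −1000 HU, a dense skull ring, brain tissue, four embedded vessel
discs), each class following

```
intensity(t) = baseline + gamma_variate(t; t0, α, β, A) + N(0, σ²)
```

rounded and clipped to the signed 16-bit range. The gamma-variate is the
standard first-pass bolus model, parameterised so its peak is exactly `A` at
`t = t0 + αβ`. Defaults (tissue: baseline 35 HU, A = 15 HU, broad; vessel:
baseline 45 HU, A = 145 HU, sharp; noise σ = 5 HU) were chosen once so that
tissue voxels span a few tens of HU (≈6-bit widths) and vessel voxels
roughly 145 HU (≈8 bits), the regime clinical brain CTP occupies, where the
large majority of voxels need at most eight bits. That qualitative regime is
reported, not numerically asserted: the phantom is a statistical stand-in,
and its exact width histogram has no claim to clinical fidelity. Features of
real data the phantom does not reproduce — streak and beam-hardening
artifacts, spatially correlated noise, sub-voxel motion, anatomy — mean that
passing tests demonstrate the codec's correctness contracts, not clinical
compression ratios.

The acquisition schedule follows the standard protocol wording — scans every
2.5 s during the first 35 s, every 5 s until 60 s, then five late scans at a
30 s interval. That wording admits several 24-point readings; the one
implemented is `{0, 2.5, …, 32.5} ∪ {37.5, …, 57.5} ∪ {87.5, …, 207.5}`
(14 + 5 + 5 points, consecutive gaps 13×2.5 s, 5×5 s, 5×30 s). The codec
never uses the times numerically, so the choice only affects phantom
realism. Motion, when enabled, applies integer in-plane shifts at chosen
time steps — interpolation is deliberately avoided because it would break
16-bit integer semantics.

Phantom generation saves and restores the global RNG state and is
bit-reproducible from its seed.

## Container format and I/O

`write_container()` serialises the arrays little-endian with an 8-byte magic
tag, version, flags, geometry, optional acquisition times, declared payload
lengths, and a CRC-32 over the payload; truncation, tag/version mismatches
and checksum failures raise distinct typed conditions. Writing is
byte-stable, and `read_container()` reconstructs `O` from `B` when it was
not persisted (the default; a flag stores the 64-bit offsets for
direct-mapped use at 8 bytes/voxel).

Input adapters load 4D volumes from NIfTI (via RNifti), from a minimal raw
headered array format used by the CLI and phantom tools, and from DICOM
series. No R DICOM reader is available in this toolchain, so the package
carries a small purpose-built reader for uncompressed Explicit-VR
little-endian single-frame series; slices are grouped into time steps by
Temporal Position Identifier, else Acquisition Time, else instance-number
blocks, and sorted by slice location — the preference order is overridable
because vendors differ. The companion writer emits deliberately minimal
*synthetic* series for fixture generation only.

## Numerical and testing choices

Degenerate inputs are part of the contract: `n = 1` (every voxel constant,
zero delta bits), width-0 reads (defined as 0), full-range voxels (width 16,
compression ratio below 1 because the 56-bit per-voxel overhead then exceeds
the savings), and the extreme intensities ±32767/−32768 are all covered by
the property tests. Losslessness is asserted over hundreds of randomized
arrays with shapes up to 8×32×32 and `n ∈ {1, 2, 24}`; random access is
checked exhaustively on small images and on 10⁴ sampled positions of a
24×32×128×128 phantom — sizes chosen so the whole suite stays in tens of
seconds while still crossing every word-boundary and width case. The bit
packer is validated against an independent boolean-array oracle built on
base R's `intToBits`/`packBits` rather than against itself.

## Known limitations

* The ratio is bounded by per-voxel overhead: 56 bits under the 32-bit
  offset convention (88 with 64-bit offsets persisted), so images with many
  wide-range voxels can expand; the codec trades ratio for speed and random
  access by design.
* No spatial prediction, entropy coding, or motion compensation — explicit
  non-goals inherited from the design.
* The DICOM reader handles the uncompressed Explicit-VR little-endian subset
  only (no sequences with undefined length, no compressed transfer
  syntaxes).
* Thresholding is the only compressed-domain operation shipped; the bound
  `[C, C + 2^B − 1]` is exposed, and other range-decidable filters could be
  built on it.
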