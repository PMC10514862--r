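---
title: "Synthetic MR contrasts from quantitative maps: models, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic MR contrasts from quantitative maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrisynth)
```

## The model

Synthetic MRI replaces the acquisition of each contrast-weighted sequence by a
single quantitative acquisition that estimates tissue parameters per voxel —
longitudinal relaxation time T1 (ms), transverse relaxation time T2 (ms) and
proton density PD (arbitrary units) — followed by pixelwise evaluation of the
steady-state signal equation of the target sequence. The generic
inversion-recovery form combining the three classical weighting mechanisms is

$$ S \;=\; \bigl|\, \mathrm{PD}\cdot(1 - 2e^{-\mathrm{TI}/T_1})\cdot(1 - e^{-\mathrm{TR}/T_1})\cdot e^{-\mathrm{TE}/T_2} \,\bigr| $$

with the simulated scanner parameters repetition time TR, echo time TE and
inversion time TI, all in milliseconds (every time constant in this package is
in ms; no seconds appear anywhere). The factors are the inversion-recovery
term (sign-sensitive, hence the enclosing absolute value), T1 saturation, and
T2 decay. Each preset keeps the factors it needs:

```{r presets}
presets_table()[, c("model", "equation", "parameter", "default")]
```

Modelling assumptions worth stating explicitly:

* The equations are **steady-state magnitude models**, not Bloch simulations:
  no k-space, no B1 transmit field, no noise physics, no partial-volume
  mixing. Users who need those effects can add input maps (e.g. a B1 map) and
  write them into a custom equation; the engine is agnostic about map
  semantics.
* The absolute value wraps the **entire product** in the inversion-recovery
  models. For pure magnitude images this is the conventional choice, and it
  is what makes the MP2RAGE-like uniform image and FLAIR behave correctly
  around their zero crossings; it is applied exactly as written in each
  preset's equation string, never implicitly.
* Models without `abs` (the gradient-echo and spin-echo presets) cannot go
  negative for physically valid maps (positive T1/T2/PD and non-negative
  parameters), so their output is deliberately left unclipped.

### Parameter nulls

The inversion term vanishes when $T_1 = \mathrm{TI}/\ln 2$: a tissue at that
relaxation time is suppressed. This single fact drives FLAIR (one inversion
tuned to cerebrospinal fluid) and double inversion recovery (two inversions,
two suppressed tissues; its nulls are the roots of
$1 - 2e^{-\mathrm{TI2}/T_1} + 2e^{-(\mathrm{TI1}+\mathrm{TI2})/T_1} - e^{-\mathrm{TR}/T_1}$).
The test suite locates the double-inversion roots with a generic 1-D root
finder and verifies the engine returns zero signal there — an analytic oracle
independent of the evaluation path.

### The GenericIR preset

The generic model ships as its own preset so users can explore all three
weighting mechanisms at once. It has no canonical parameterization of its
own; we give it the tissue-border-enhancement values (TR = 5020, TE = 1,
TI = 795 ms) because that contrast *is* the generic model used directly, which
makes the preset immediately useful rather than a blank template. With
TI → ∞ the inversion factor tends to 1 and the model reduces exactly to the
spin-echo equation — a limit the tests check at TI = 10⁹ ms, where the
exponential underflows to 0 and the agreement is exact.

## The equation language

Equations arrive from JSON configuration files, i.e. from untrusted text, so
they are parsed by a small recursive-descent parser rather than evaluated as R
code. The language is: decimal constants, identifiers, binary `+ - * /`,
unary minus, parentheses, and exactly two functions, `exp` and `abs`. Any
other function name is rejected at parse time with the offending character
position, and string literals are recognized only to be rejected — a
configuration file can never call into R. The AST serializes back to an
equivalent infix string (`deparse_equation()`), and parse ∘ deparse is the
identity on ASTs, which is what makes canonical configuration round-trips
possible. A power operator is not needed by any shipped model and is left as
a documented extension point.

### Invalid voxels

Quantitative maps contain background and air where T1/T2/PD are zero, negative
fit failures, or NaN. Evaluating `-TR/T1` there would produce divisions by
zero and infinities, so the engine defines: **any voxel where a required map
is non-positive or non-finite yields S = 0**. Zero renders as background and
propagates cleanly through windowing and export. Any residual non-finite value
(from a pathological user map) is also forced to 0, so synthetic volumes are
finite by construction.

## Numerical choices

* Volumes are held as R double arrays in memory; evaluation is vectorized
  over the whole volume in one pass and is exactly the IEEE-754 double
  computation of the scalar formula per voxel (the tests compare against a
  per-voxel oracle at 10⁻⁶ relative tolerance; observed agreement is exact).
* NIfTI export stores 32-bit floats (the conventional storage for synthetic
  contrast, halving file size at ~7 significant digits, far below tissue
  contrast differences); the grid affine is written as the sform and is
  authoritative on read.
* DICOM export stores 16-bit signed integers with a per-volume rescale slope
  `max(|S|)/32767` (intercept 0), so the round-trip error is bounded by half
  a quantization step — a bound the tests verify empirically.
* Grid equality (for co-registration checks between maps) uses a 10⁻⁶
  absolute tolerance on spacing and affine entries.
* Window/level maps `[center − width/2, center + width/2]` linearly onto
  0–255 with half-up rounding; the exported default window covers the 1st–99th
  percentile of the signal, which is robust to the long zero tail of
  background voxels.

## Configuration format

The JSON schema is:

```json
{
  "accepted_maps": { "T1": {"units": "ms"}, "T2": {"units": "ms"}, "PD": {"units": "arbitrary"} },
  "presets": {
    "3T": {
      "models": {
        "GRE": {
          "title": "T1w gradient-recalled echo",
          "equation": "PD*(1-exp(-TR/T1))",
          "maps": ["PD", "T1"],
          "parameters": { "TR": {"default": 113, "min": 0, "max": 1130} }
        }
      }
    }
  }
}
```

Presets group models with parameter defaults appropriate to one input dataset
(typically one field strength). The validator (`validate_config()`) returns a
tibble of issues rather than raising: semantic violations (duplicate names,
defaults outside bounds, equation symbols not declared as map or parameter,
maps missing from `accepted_maps`) are errors; unknown keys and unused
accepted maps are warnings, for forward compatibility. Every issue carries a
JSON path. `reload_config()` supports live editing: an invalid edit returns
the previous configuration unchanged, with the report attached.

Serialization is canonical — UTF-8, two-space indent, keys sorted in the C
locale, numbers printed without trailing zeros — so `save → load → save` is
byte-identical, and the shipped `config.json` is itself a fixed point of that
cycle. Parameter bounds default to `[0, 10 × default]` when a file gives only
a default; all bounds are advisory ranges for interactive sliders, and
programmatic evaluation accepts any finite non-negative value.

## DICOM design notes

No R DICOM library covers series writing, so the package carries a minimal,
self-contained Explicit VR Little Endian implementation of MR Image Storage:
one file per slice, a code-generated template holding the static tags (no
patient data), and per-export updates of the mutable slots — TR (0018,0080),
TE (0018,0081), TI (0018,0082), window center/width (0028,1050/1051), series
description (0008,103E), and fresh Study/Series/SOP instance UIDs on every
export (UIDs are never reused). Two non-standard parameters need a home:
TSAT and the double-inversion pair TI1/TI2 have no standard tag, so TI1 is
written to InversionTime and the complete parameter set is serialized as JSON
into both a private element (0011,1001) and ImageComments, from which it is
fully recoverable. Slices are ordered by the projection of
ImagePositionPatient on the slice normal; geometry converts between the
internal RAS affine and DICOM's LPS convention without ever resampling.
Viewer compatibility of the minimal tag set is best-effort; enhanced
multi-frame DICOM and PACS networking are out of scope.

## Plane naming and reslicing

Volumes are index-addressed; anatomical plane names are labels over
*canonicalized* axes. Canonicalization reads the affine, assigns each voxel
axis to the world axis that dominates its direction column, and flips axes so
they increase rightward/anteriorly/superiorly; sagittal/coronal/axial then
mean world-x/y/z slices. This fails loudly for strongly oblique acquisitions
(no dominant axis), and `canonical = FALSE` addresses raw voxel axes instead.
Reslicing is exact extraction — display interpolation and zoom are
presentation concerns outside the package.

## The phantom

`generate_phantom()` builds nested axis-aligned ellipsoids — background, a
CSF shell, a grey-matter shell, a white-matter core — with piecewise-constant
T1/T2/PD and an integer label volume as ground truth. Defaults per field
strength are literature-style representative values (e.g. at 3T: WM
850/70 ms, GM 1350/100 ms, CSF 4200/1800 ms, PD 0.65/0.8/1.0), shipped as
clearly synthetic testing defaults, not measurements. Optional Gaussian noise
is added per map, inside tissue only, from a generator seeded by the spec (the
session RNG stream is saved and restored, so phantom generation never
perturbs user code).

What the phantom emulates: co-registered, positive, piecewise-homogeneous
maps on a shared grid — enough to exercise every pipeline stage with exact
expectations (each tissue's synthetic signal equals the scalar equation at
its parameters). What it does not emulate: partial-volume mixing at
interfaces, B1 bias, flow and motion artifacts, or the fit noise structure of
real multiparametric acquisitions. Passing tests on the phantom therefore
validate the *computational pipeline*, not the radiological quality of any
particular acquisition's maps.

## Batch processing

Batch runs are sequential by design: deterministic logs and bit-identical
NIfTI outputs for identical inputs (DICOM outputs differ only in UIDs).
Subjects are immediate subdirectories of a root; map files match per-symbol
filename patterns (default: the symbol bounded by non-alphanumerics, so `T1`
does not match `TI` or `T12`; override per symbol with a regular expression).
A subject missing any required map is skipped and recorded — one bad subject
never aborts a run — and `written + skipped + failed` always equals
subjects × models. A JSON report is written alongside the outputs; exit code
0 from the CLI means zero failures.

## Problem sizes and test design

The test suite evaluates oracle equivalence on 8³ random plausible maps
(T1 ∈ [200, 5000] ms, T2 ∈ [20, 2000] ms, PD ∈ [0.1, 1]), noise calibration on
a 64³ phantom (≥10⁴ voxels per tissue for tight sd estimates), and the full
batch reproduction on 210 subjects of 32×32×16 voxels — small enough that the
whole suite runs in well under a minute while every claim is still measured,
not assumed. `scripts/acceptance.R` recomputes the same quantities from
scratch under a caller-supplied seed.

## Known limitations

* Only 3D volumes: 4D inputs are rejected rather than silently split.
* Implicit VR and compressed DICOM transfer syntaxes are not read; the
  reader targets the writer's Explicit VR Little Endian output and similar
  single-series directories.
* The equation language has no power operator, no conditionals and no
  user-defined functions — by design; extend the whitelist in code if a new
  model genuinely needs more.
* Anatomical plane labels assume a not-too-oblique affine; oblique volumes
  must be addressed by raw voxel axes.
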