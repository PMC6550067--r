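---
title: "Models and methods behind myelometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myelometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

The g-ratio of a myelinated nerve fibre — the ratio of the inner (axon)
diameter *d* to the outer (axon + myelin) fibre diameter *D* — is a
sensitive index of myelin maturity and health.  Theory places its optimum
near 0.60–0.62, and empirical values for healthy peripheral fibres span
roughly 0.55–0.68.  Correlative light and electron microscopy (CLEM) of
myelinating cultures lets the same fibre be measured in both modalities,
which raises three questions this package makes computable:

1. How well do the three common estimators of g agree —
   per-scan diameters (`d/D`), cross-sectional areas
   (`sqrt(ca/CA)`), and compartment volumes (`sqrt(V_axon/V_fibre)`)?
2. How much does the light-microscope point-spread function bias
   diameter-based g?
3. How accurately are the LM and EM datasets registered, measured as
   per-landmark shifts between thickness-matched projections?

Because no public CLEM dataset of this kind exists, the package is built
around a *ground-truthed synthetic world*: phantoms of myelinated fibres,
nodes of Ranvier and somatic fiducials, rendered as EM-like and LM-like
stacks whose every parameter is known.  Every analysis routine is then
validated against that ground truth, against closed-form oracles, or
against brute-force reimplementations.

## The phantom model

**Rasterization.**  A voxel belongs to a material iff its *center* lies
inside the analytic region (voxel-center convention).  This makes
voxel-count volumes asymptotically unbiased: a straight cylinder with at
least 20 voxels per diameter recovers its analytic volume within 1%.
A fibre is a flat-ended tube around a polyline centerline — a voxel is
axon if its perpendicular distance to some segment (foot inside the
segment) is at most `d/2`, myelin within `(d/2, D/2]` — plus joint
spheres restricted to the *wedge* between adjacent segments (past the
end of one, before the start of the next) so bent fibres have no gaps.
Restricting the spheres to the wedge matters as much as the flat ends:
unconditional joint spheres protrude axially past the caps of a
densely-sampled polyline, and spherical caps on a 20 µm fibre would
inflate its volume by ~4%, visibly corrupting the volume-based g.

**Node of Ranvier.**  The node is a gap (default order 1 µm) centred on
the arc-length midpoint.  Each flanking paranode replaces compact myelin
with `n` concentric loop-labelled shells spaced radially by the lamellar
period, each shell half a period thick so neighbouring lamellae remain
resolvable.  The lamellae terminate sequentially toward the node with
the innermost reaching closest — the geometry of a myelin spiral ending
in paranodal loops.  The period defaults to 0.016 µm (the order of the
compact-myelin major dense line spacing); phantoms that must resolve
individual lamellae at practical voxel sizes pass a larger period
explicitly, since the imaging model, not the biology, sets what is
countable.  This concentric-shell reading is one plausible model of the
paranode; real loops spiral and touch the axolemma, which the counting
analysis does not need.

**Fiducials.**  Somata (semi-axes 2–4 µm) and nuclei (1–2 µm) are random
ellipsoids placed by bounded rejection sampling (≤ 1000 retries), never
overlapping existing labels, with centers at least their semi-axes from
the walls.  All placements derive from one explicit seed.

**EM render.**  Nearest-neighbour resampling of the labels onto the EM
grid (default 13.8 × 13.8 nm pixels, 80 nm sections — the fine SBF-SEM
acquisition settings), then per-material mean grey levels (myelin 30 <
axon 150 < background 200 on a 0–255 scale, enforcing the
darkest-myelin contrast of osmium staining) plus i.i.d. Gaussian
detector noise, clipped to range.

**LM render.**  Two dye channels — myelin (myelin + loop labels) and
nuclei — each a binary source convolved with a separable anisotropic
Gaussian PSF on the label grid, trilinearly resampled to the LM grid
(default 0.068 × 0.068 × 0.3 µm), with optional Poisson shot noise and
Gaussian read noise.  PSF defaults: confocal 0.25/0.6 µm
lateral/axial FWHM, Airyscan-style 0.14/0.35 µm.  The instruments this
emulates are real; the FWHM values are configurable stand-ins, not
measured calibrations.

**Misregistration.**  A `modality_transform` (translation, rotation
about the plane normal, per-axis scale) models residual processing
distortions such as anisotropic shrinkage; it is exactly invertible and
all landmark simulations flow through it.

## Measurement conventions

**Line-scan diameters.**  A pixel-density scan across the whole fibre
shows two myelin extrema (troughs in EM, peaks in LM).  The fibre
diameter D is the distance between the *outer* half-level crossings of
the two extrema, the axon diameter d between the *inner* crossings;
half levels sit midway between each extremum and the adjacent plateau
(outer background, or the axoplasm between the extrema), and crossings
are localized by linear sub-sample interpolation — the standard FWHM
convention, deterministic and exact on trapezoidal test profiles.
Scans whose extrema or crossings cannot be found raise a typed
measurement error and are *skipped and counted, never imputed* — the
same bookkeeping a microscopist applies when out-of-focus light defeats
a confocal scan.  Noisy EM scans are lightly smoothed (5-sample moving
average) before feature detection; noiseless tests use no smoothing.
Candidate extrema must additionally clear a 4σ noise floor, with σ
estimated from robust lagged differences of the raw profile (lag at
least the smoothing window, so oversampled, interpolation-correlated
samples do not hide the pixel noise) — without this gate a scan through
pure background noise returns a random (d, D) instead of a reported
failure.

On blurred bright-myelin profiles the 1-D convolution argument says the
outer half-max moves outward and the inner one inward, so g falls as
the PSF widens.  In the full 2-D render the convex outer boundary adds
a curvature correction (≈ σ²κ) that cancels much of the outer
broadening; the inward pull on d survives, so the *net* bias on g is
still downward and monotone in the FWHM — which is what the acceptance
suite asserts.

**Three estimators, one quantity.**  Area- and volume-based g take
square roots (`sqrt(ca/CA)`, `sqrt(V_a/V_f)`) so all three estimate the
same d/D: for circular geometry they agree identically, and without the
square root a healthy fibre would report ≈ 0.36, inconsistent with any
reported range.  The convention is recorded in the output metadata.
Volume-based g must compare volumes over a *common axial extent*; the
pipeline restricts both compartments to sections where both were
segmented.

**Lamella counting** is plateau-aware local-extremum counting with a
prominence threshold expressed as a fraction (default 0.2) of the
profile dynamic range, so shallow ripples riding on deep troughs are
ignored and a flat profile counts zero.

**Why volume g is tightest.**  The estimator-tightness property
(across-fibre SD: volume ≤ area ≤ diameter) is driven by how much each
method averages before taking the ratio.  On perfectly concentric
circular phantoms a diameter scan through the exact fibre center is
*immune* to obliquity — tilt scales d and D identically — so the
mechanism the volume method is claimed to average out ("local
structural deviations along the fibre axis") only appears when the
section wanders across the scan line.  The tightness cohort therefore
bends its fibres and scans transverse to the bend plane: each scan then
measures an offset chord, whose error the per-section areas (exact
under displacement) and the integrated volumes do not share.

**Group comparison** is fixed-effects one-way ANOVA computed from group
sums of squares, cross-checked in the tests against `anova(lm(...))`
and the two-group `t² = F` identity, and calibrated under the null
(type-I error 0.05 ± 0.02 over 1000 seeded repetitions).

## Segmentation: the blow tool, formalized

The interactive "blow" gesture grows a polygon from a seed until
contrast stops it.  Here that is a two-threshold region grower: a pixel
joins the region iff its intensity is within `intensity_tolerance` of
the reference intensity *and* its central-difference gradient magnitude
is below `gradient_threshold`, connected 4- (default) or 8-wise.  The
result is by construction the connected component of the acceptance set
containing the seed — independent of visitation order, hence testable
against a brute-force flood-fill oracle, which the suite does on a
family of piecewise-constant fixtures.  Growth is confined to a
physical `max_radius` around the seed; a region that would continue
past it is returned flagged `capped` rather than erroring, mirroring
the interactive tool where the user re-seeds.

When a segmentation is propagated through serial sections, three
deliberate robustness choices depart from the naive
"re-seed at the centroid" recipe.  (1) The tolerance band is centred on
the *previous section's mean mask intensity*, not on whatever pixel now
lies under the seed — otherwise the propagation re-seeds on axoplasm
when the myelin ends at a nodal gap instead of stopping there, which is
the behaviour the node phantom test pins down.  (2) The seed is the
most *interior* mask pixel (the deepest erosion shell, nearest the
centroid): for a disk that is the centroid, but for an annulus the
in-mask pixel nearest the centroid is a knife-edge inner-boundary
pixel, and one voxel of boundary drift between sections aborts the
propagation.  (3) Growth starts from the acceptable pixels in a 5×5
window around the seed, so a single noisy pixel (≈0.5% per section at
5% detector noise) cannot fake a gap; a genuinely material-free section
has no acceptable pixel in the window and yields the empty mask that
stops the propagation.

Defaults (`gradient_threshold` 40, `intensity_tolerance` 35 grey
levels, `max_radius` 3 µm) are set against the default EM contrast map:
the tolerance must stay below the 50-level axon/background step or the
grower floods the resin.

## Digital re-sectioning

Multiplanar reslicing samples the volume by trilinear interpolation on
an arbitrary plane; out-of-volume samples take a declared fill value
and are masked, and the operation is exactly linear in the volume.
Centerline-orthogonal sections use central-difference tangents and a
parallel-transported (minimal-twist) in-plane frame, so a helical tube
shows a constant cross-section diameter instead of frame-flip
artefacts.  Projections reduce a window of `n` sections by mean
(default; max provided) and report their physical thickness `n · t`.
Thickness matching across modalities uses `floor(t_ref/t_other)` — the
largest count *not exceeding* the reference thickness.  This dialect is
deliberate: matching a 2.7 µm optical projection (9 × 300 nm) with
80 nm EM sections gives 33 sections (2.64 µm), whereas nearest-count
rounding would give 34 (2.72 µm).

## Shift analysis

Landmarks marked in both thickness-matched projections are re-centred
on a shared origin landmark — explicitly chosen, never auto-detected —
by subtracting the *midpoint of its two marked positions* from both
sets.  This preserves a genuine inter-modality offset (a pure 0.3/0.4
µm translation reports 0.5 µm everywhere) while any rigid translation
common to both modalities cancels exactly.  Per landmark the analysis
reports (dx, dy) = EM − LM, the shift distance, the distance from
origin r (measured at the mean of the two centred positions — the
convention is recorded in the output), the direction both as
`asin(dy/shift)` (the convention used when scoring by eye) and as
full-quadrant `atan2(dy, dx)`, and a concentric-ring index
`ceil(r/spacing)` with a closed outer boundary (default spacing
6.5 µm).  Trends of shift against r and against angle use Pearson
correlation with two-sided t-based p-values; the verdict is
"isotropic" when both p > 0.05, "anisotropic" when either is
significant, and "indeterminate" when a correlation is undefined
(zero variance, as under a pure translation).  Under seeded isotropic
jitter of sd σ the mean shift converges to the Rayleigh mean σ√(π/2).

Finder-grid relocation is plain anchor arithmetic: numbers step along
one axis, letters along the other, at a configurable pitch (default
500 µm — a typical gridded-dish pitch, not a measured value).  Letters
are a single A–Z run; no wraparound is defined, so multi-letter labels
are rejected.

## What the synthetic world does and does not establish

The phantoms emulate geometry (diameters 1–2 µm, g near 0.6, nodes with
~10 lamellae per side, somatic fiducials), the two acquisition grids,
modality contrast polarity, detector noise, PSF blur, and affine
misregistration.  They do **not** emulate SBF-SEM charging or knife
artefacts, staining heterogeneity, non-circular axon cross-sections,
deconvolution, or depth-dependent PSF variation.  A green suite
therefore establishes that the *measurement machinery* is correct and
that the stated optical physics reproduces the qualitative findings
(EM > Airyscan > confocal diameter-g ordering; volume g tightest); it
does not re-derive the authors' instrument-specific numbers, which
depend on data that was never deposited.

## Numerical choices

- Flatness guards: profiles whose dynamic range is below 10⁻⁶ of their
  magnitude are flat (bilinear interpolation of a constant image
  produces 10⁻¹⁴-level jitter).
- Zero-variance correlations are reported as `NA` with a flag, using a
  relative 10⁻⁹ epsilon on the standard deviation.
- TIFF I/O is an in-package baseline codec (uncompressed grayscale,
  8/16-bit unsigned and 32-bit float, little-endian written, both byte
  orders read) because the R stack here ships no TIFF package; it is
  cross-validated against an independent reader in the test suite.
  Voxel sizes travel in an ImageDescription JSON payload with a
  `<path>.json` sidecar fallback; labels carry a material-table sidecar.
- All stochastic stages consume one explicit seed; reruns are
  byte-identical, which the pipeline test asserts on the emitted CSV
  and JSON artifacts.
- Scaled-down test configurations shorten fibres and reduce scan counts
  but never change pixel sizes, contrast, noise fractions or
  diameters — the physics of the stated world is fixed.

## Known limitations

- The blow tool's two-threshold formulation is one reading of "polygon
  expansion based on contrast gradient"; parameters are configurable
  because the original tool's are undocumented.
- The paranode model is concentric shells, not a spiral; only counts
  and termination order are asserted against it.
- Volume-based g from propagated segmentations inherits any systematic
  under/over-segmentation of both compartments; the cohort test shows
  the ratio is robust to it, not that absolute volumes are exact.
- LM diameter measurements use the inner-edge-of-myelin convention for
  d in both modalities, since an unlabeled axon provides no direct
  boundary.
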