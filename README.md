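# myelometry

Ground-truthed morphometry of myelinated axons imaged by correlative
light microscopy (LM) and serial block-face scanning electron microscopy
(SBF-SEM).

## Who this is for

Labs doing CLEM of myelinating cultures (DRG neuron–glia co-cultures and
similar systems) who want to quantify myelin maturity — and anyone who
needs to know *how much to trust* a g-ratio measured from a given
modality, estimator, or noise level before applying it to real data.
Because no public dataset of this kind is deposited, the package ships a
fully synthetic, ground-truthed pipeline: every analysis routine can be
exercised against phantoms whose true geometry is known exactly.

## The statistic at its core

For a myelinated fibre with axon diameter *d* and outer fibre diameter
*D*, the g-ratio is

    g = d / D          (theoretical optimum ~0.6; healthy range 0.55-0.68)

and the package implements its three standard estimators so that all
measure the same quantity:

- **diameter**: `g = d/D` per pixel-density line scan, with d and D from
  half-level edge crossings of the two myelin extrema;
- **cross-sectional area**: `g = sqrt(ca/CA)` per section;
- **volume**: `g = sqrt(V_axon/V_fibre)` per fibre, over a common axial
  extent.

Around that sit: a 3D phantom generator (fibres, nodes of Ranvier with
paranodal lamellae, soma/nucleus fiducials; EM-like and LM-like renders
with configurable PSF, noise and inter-modality misregistration); a
contrast-gradient-bounded region-growing ("blow") segmenter with
serial-section propagation; digital re-sectioning (multiplanar reslices,
centerline-orthogonal sections, thickness-matched projections); lamella
counting; one-way ANOVA group comparison; and a landmark shift analysis
for LM↔EM registration accuracy.

See `vignettes/myelometry-methods.Rmd` for the models, conventions and
design decisions.

## Worked example

Build a cylinder phantom with known g = 0.6, render it at SBF-SEM
resolution with 5% detector noise, and measure:

```r
library(myelometry)

grid   <- grid_spec(shape = c(150, 150, 300), voxel_size = rep(0.02, 3))
fibre  <- straight_fibre(grid, d = 1.2, D = 2.0, length = 5)   # um
phantom <- build_fibre_phantom(fibre, grid)
phantom$truth$volumes_um3
#>    axon  myelin    loop    soma nucleus
#>   5.656  10.064   0.000   0.000   0.000

em    <- render_em(phantom$labels, noise_sd = 0.05 * 255, seed = 42)
scans <- scan_fibre_diameters(em, n_scans = 50, smooth_window = 5)
g_ratio_diameter(scans)
#> g-ratio (diameter method): 0.603 +/- 0.002 (sd), sem 0.000, n = 50

v <- phantom$truth$volumes_um3
g_ratio_volume(v[["axon"]], v[["axon"]] + v[["myelin"]])
#> g-ratio (volume method): 0.600 +/- NA (sd), sem NA, n = 1
```

The diameter estimate (0.603) sits within noise of the true 0.600; the
volume estimate recovers it to three decimals (the analytic axon volume
is pi * 0.6^2 * 5 = 5.655 um^3 against 5.656 measured).

Landmark shift analysis of a simulated 0.22 um misregistration plus
0.15 um isotropic jitter:

```r
set.seed(1)
pts <- matrix(runif(40, -20, 20), ncol = 2); pts[1, ] <- 0
em_pts <- apply_modality_transform(
  pts, modality_transform(translation = c(0.2, 0.1))) +
  matrix(rnorm(40, sd = 0.15), ncol = 2)
shifts <- compute_shifts(correspondence_set(pts, em_pts, origin_index = 1))
shifts
#> <shift_result> n = 20, mean shift 0.277 um (+/- 0.089 um sd)
shift_trend(shifts)$verdict
#> [1] "isotropic"
```

A full end-to-end experiment (simulate → segment → measure → g-ratio →
shift → report) runs from one JSON config:

```sh
Rscript inst/cli/myelometry.R all --seed 42 --outdir out \
    phantom.fibre.length_um=2.5 morphometry.n_scans=25
```

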