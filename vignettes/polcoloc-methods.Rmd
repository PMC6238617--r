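---
title: "Quantifying compartment polarisation and colocalisation in single cells"
author: "polcoloc developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying compartment polarisation and colocalisation in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polcoloc)
```

## The measurement problem

Activated lymphocytes reorganise their interior: lysosomes (LAMP1⁺
vesicles), internalised antigen and cytoskeletal networks that are spread
uniformly in resting cells collapse towards one pole of the cell — the
nascent immunological synapse. polcoloc quantifies this on single-cell
fluorescence crops with a small set of per-cell statistics:

* **cluster count** — number of segmented puncta in a compartment channel;
* **asymmetry** (μm) — distance between the intensity-weighted centroid of
  the channel and the cell centre;
* **cluster half-width** (μm) — intensity-weighted SD of the cluster pixel
  positions, computed separately in x and y and averaged; a compactness
  measure;
* **area coverage** — in-cell fraction of pixels above the channel's Otsu
  threshold;
* **mean spot intensity / area** — per-cluster features familiar from
  high-content screening readouts;
* **colocalisation** — Pearson correlation and Manders M1/M2 between two
  compartment channels at automatically chosen (Costes-style) thresholds.

One cell per image crop is the unit of analysis; whole-field segmentation
is out of scope.

## The analysis chain

For each compartment channel of a crop (maximum-intensity projected if a
z-stack):

1. **Bandpass** — difference of Gaussians between physical scales 0.13 μm
   and 0.9 μm. Scales map to kernel sigmas as `scale / 2` pixels (a
   full-width convention, `scale / 2.355`, is selectable). The image is
   centred on its first pixel value before filtering: a difference of two
   unit-sum kernels annihilates constants in exact arithmetic, and the
   centring makes the all-constant case exactly zero in floating point
   as well, without a special-cased branch.
2. **Otsu threshold** on the filtered image (256 bins). Class means are
   accumulated from exact per-bin intensity sums, not bin centres, so the
   binned maximiser coincides with the exhaustive between-class-variance
   search whenever distinct values do not share a bin. Ties break towards
   the lower threshold.
3. **Connected-component labeling** under 8-connectivity; components
   smaller than 4 px are discarded as single-pixel noise (both
   configurable). Cluster count, half-width and spot features are read off
   the label map; half-width weights are raw channel intensities by
   default.
4. **Centroid branch** (independent of segmentation): a local background
   estimated over a 2.6 μm disk is subtracted and the intensity-weighted
   centroid is computed over the in-cell pixels; asymmetry is its
   Euclidean distance to the cell centre in μm, unnormalised (dividing by
   the cell radius is optional and off by default).

The cell centre comes from the nucleus channel (Otsu mask → unweighted
centroid → equal-area-circle radius) or from a user-supplied circle. The
reference procedure placed that circle manually; automation is required
for batch testing, and a manual override is kept. Because a
nucleus-derived circle understates the cell outline, nucleus-derived radii
are inflated by `cell_mask_scale` (default 1.25, a typical lymphocyte
cytoplasmic allowance) before being used as masks or crop bounds; manual
circles are taken literally.

### Why the centroid branch uses a median background with signed weights

A rolling-ball-style background (greyscale opening by a flat disk) is
bounded by the local *minimum*; on a background that carries shot and read
noise it therefore sits several noise SDs below the true level. After
subtraction and clipping at zero, every background pixel keeps a small
positive residual. Those residuals are centred on the cell, and their sum
over a ~3.5 μm cell competes with the total spot intensity, dragging the
centroid inward and shrinking asymmetry by tens of percent — we measured
20–60% on synthetic cells with planted offsets. Two changes remove the
bias, and both are defaults of the centroid path only:

* the background is estimated as the **local median** over the same disk
  (unbiased under symmetric noise; implemented as a Huang
  sliding-histogram filter with 2048 quantisation bins), and
* the subtracted weights are left **signed** rather than clipped, so the
  remaining zero-mean residuals cancel instead of accumulating.

`subtract_local_background()` itself keeps the clipped opening as its
default, and both choices can be reverted per run
(`centroid_background = "opening"`, `centroid_clip_weights = TRUE`).

### Colocalisation

Crops are reduced to the cell circle (plus a small padding), the
inter-channel regression is fitted by total least squares (orthogonal
regression, as in the original automatic-threshold method; OLS is
selectable), and the channel-A threshold is walked down from the maximum
along the regression line until the Pearson correlation of the
jointly-below-threshold pixels first drops to ≤ 0. Candidates are the
sorted unique channel-A intensities, evenly subsampled to at most 512
levels — a scale-free rule, so doubling both channels exactly doubles both
thresholds and leaves M1/M2 unchanged. Three degenerate regimes are
handled explicitly:

* perfectly proportional channels never decorrelate below any cut: the
  minimum intensity is returned with a `degenerate` flag;
* anti-correlated channels have no meaningful Costes threshold:
  `costes_thresholds()` errors, and `colocalise_cell()` substitutes each
  channel's own Otsu threshold with a `costes_failed_otsu_fallback` flag
  (this keeps overlap-free cell pairs analysable in batches);
* constant channels yield `NA` with a reason, never a silent zero.

Pearson is reported both over all in-cell pixels (the headline value) and
restricted to pixels above both thresholds. Manders M1/M2 use the Costes
thresholds; no separate Manders thresholds are defined, and the report
flags that assumption. Note that M1/M2 are computed from raw intensities,
so a large additive background deflates them even at complete spot
overlap; the synthetic full-overlap benchmark therefore uses a low
background when asserting M ≥ 0.9.

## The synthetic-cell generator

Real accession data are not available for this kind of study, so
validation rests on simulated crops with planted ground truth. A scene is
a circular cell (default radius 3.5 μm) with a nucleus (radius 2.8 μm —
lymphocytes have a high nuclear-to-cytoplasmic ratio) centred in a
128 × 128 px frame at 0.08 μm/px. The pixel size is a stand-in for typical
63×/1.4 NA confocal sampling; the source imaging protocol states no
acquisition pixel size, and every μm↔px conversion goes through this one
number.

Each compartment channel places `n_puncta` spots by rejection sampling
from an isotropic Gaussian (SD `placement_spread`) whose centre sits
`polarisation_offset` μm from the cell centre: offset 0 gives the uniform
"cage-like" phenotype, large offsets the collapsed/polarised one. The
validity constraint `offset + spread ≤ cell_radius` keeps the distribution
inside the cell. An optional `min_separation` plants well-separated,
countable puncta. Spots are rendered as analytic Gaussians of SD
`puncta_sigma` (0.12 μm, a diffraction-limited PSF width) and amplitude
150 over a background of 20 counts; Poisson shot noise is applied to the
expected intensities, Gaussian read noise (SD 2) is added last, and the
result is clipped at zero. Channel overlap for colocalisation benchmarks
reuses a fraction of the first channel's spot centres in the second
channel; the realised fraction is recorded as ground truth.

Defaults were chosen once as realistic for confocal crops of primary
B cells and are not tuned per test. What the generator does **not**
emulate: 3D PSFs, spectral bleed-through, camera-specific noise
calibration, non-circular or touching cells, autofluorescence texture.
A green synthetic-recovery test therefore establishes that the estimators
are unbiased and monotone under the stated forward model — not that they
reproduce any particular biological effect size.

Two benchmark conventions follow directly from the stated world rather
than from tuning:

* asymmetry-recovery sweeps that include a 3 μm offset must use
  `placement_spread = 0.5` μm, the largest spread valid at every level
  under the `offset + spread ≤ cell_radius` invariant;
* cluster-count benchmarks use `min_separation = 1` μm, just above the
  0.9 μm upper bandpass scale, so that "well-separated" spots cannot be
  merged by the filter itself.

## Determinism and numerical choices

* All randomness flows through explicit integer seeds; population seeds
  are derived deterministically from one master seed, and identical specs
  plus seed give identical pixel arrays and byte-identical result CSVs
  (result files carry a parameter-echo header and no timestamps).
* TIFF export writes 64-bit float samples by default, so a write/read
  round trip reproduces R doubles exactly; 32-bit float and 16-bit
  unsigned are available, with quantisation applied only at export.
* Undefined metrics (no clusters, constant channels, zero Manders
  denominators) are `NA` with a `reason` attribute — never 0, because 0 is
  a meaningful value for asymmetry and correlation.
* The reference description of the centroid ("mean for x and y calculated
  independently and then averaged") is ambiguous for a 2D quantity; it is
  implemented as the standard 2D vector mean with Euclidean distance, and
  no alternative reading is guessed.
* Whether the 2.6 μm background subtraction also precedes segmentation is
  unstated in the reference chain; it is attached to the centroid only by
  default, with `background_before_segmentation = TRUE` as the switch.

## Known limitations

* The polarised/cage-like classifier is a strict threshold on asymmetry
  supplied by the user; it is a convenience surrogate and makes no claim
  to reproduce manual scoring of reorganisation phenotypes.
* Costes significance testing by pixel scrambling, object-based
  colocalisation and 3D segmentation are out of scope.
* The TIFF codec covers the uncompressed greyscale baseline subset it
  writes (plus either byte order and 8/16/32-bit unsigned or 32/64-bit
  float samples); compressed or tiled files from other software must be
  re-exported uncompressed.
```{r session}
sessionInfo()
```
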