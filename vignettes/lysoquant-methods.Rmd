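---
title: "Quantifying lysosome spatial organization and motility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lysosome spatial organization and motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysoquant)
```

## The measurement problem

Lysosomes in cultured cells appear in fluorescence time-lapse imaging as
hundreds of punctate spots per cell. Their positioning — clustered around
the nucleus versus scattered to the periphery — and their motion — caged,
freely diffusive, or motor-driven — are readouts of the positioning
machinery (kinesin/dynein adaptors, small GTPase effectors). lysoquant
turns a calibrated time-lapse stack into four quantitative summaries:

1. **Counts and sizes** of segmented puncta, per frame and per subcellular
   region.
2. **Ripley's K function** of the punctum point pattern, against the
   complete-spatial-randomness (CSR) baseline.
3. **Region-resolved diffusion exponents** from trajectory linking and
   ensemble mean-squared displacement (EMSD).
4. **Intensity distribution metrics**: the perinuclear index and corrected
   total cell fluorescence (CTCF).

A synthetic-data generator produces ground-truthed scenes for every one of
these measurements, so the whole chain is validated against known truth
without microscopy data.

## Detection

Frames are reduced to 8-bit grayscale (RGB by the 0.299/0.587/0.114
luminance weights; 16-bit by full-range division by 257 — the conversion
the source data format leaves unspecified, so it is a documented choice).
Foreground is a global intensity threshold, default 100 on the 8-bit
scale, applied *strictly* (`> 100`); puncta are 8-connected components of
the foreground, the convention of contour-based segmentation. Centroids
are unweighted binary moments (mean member-pixel coordinates), because the
moments are computed on the binarized objects; intensity weighting is
deliberately not used. Both choices are pinned by an explicit flood-fill
oracle in the test suite. No size filter is applied by default
(`min_area = 1`).

Coordinates are 0-based with x = column and y = row, so thresholds and
band widths stated in pixels translate directly to array operations.

## Cell geometry from the puncta themselves

The outermost lysosomes of the first frame serve as a proxy for the cell
outline. Centroids are Delaunay-triangulated and triangles with
circumradius above `1/alpha` are discarded; the default `alpha = 0.02`
keeps circumradii below 50 px. The union of kept triangles is the
alpha-shape footprint and its outer boundary is the cell polygon — a
concave hull that follows invaginations a convex hull would bridge.
Because "alpha" conventions differ between libraries (radius, inverse
radius, area), the inverse-radius convention used here is explicit and
`alpha` is a configuration knob. If no triangle survives, or the kept
triangles fall into disconnected islands, the convex hull is used instead
and a warning names the fallback; points in no kept triangle are reported.

Two bands partition the cytoplasm:

* **peripheral rim** — cell-mask pixels within 60 px (7.8 µm at the
  default 0.13 µm/px) of the cell exterior;
* **perinuclear annulus** — pixels within 40 px (5.2 µm) outside the
  manually annotated nucleus, clipped to the cell mask.

Bands are built with the Euclidean distance transform rather than
iterative 3×3 dilation: iterated square structuring elements grow
Chebyshev (square) neighborhoods, so a "60 px" band would be 60 px along
the axes but 85 px along diagonals. The Euclidean band has the stated
physical thickness in every direction. A `method = "dilate"`
compatibility mode reproduces the iterative-morphology behavior.
Whether the annulus should be clipped to the cell mask is left open by
the method description; clipping defaults on, since unclipped annuli can
leak outside the cell. Brute-force per-pixel distance computations pin
both bands exactly on small rasters.

## Ripley's K

For each frame with at least two detections,

$$\hat K(r) = \frac{A}{n(n-1)}\,\#\{(i,j): i \neq j,\ d_{ij} \le r\}$$

over ordered pairs, with radii 1–250 px. No edge correction is applied:
the estimator is the literal area-normalized pair count, which is biased
downward as r approaches the window size. That bias is acceptable here
because groups are compared under identical analysis, and it is what the
plain pair-count definition computes; an edge-corrected variant would
change absolute values near the boundary, not the clustered/dispersed
ordering. The normalizing area A defaults to the alpha-shape cell-mask
pixel count (the full image rectangle is available as an option); the
method description does not say which area was used, and the choice
rescales K multiplicatively.

Per-frame curves are averaged over the (default 50) analyzed frames to
give a per-video curve; video curves are averaged across videos with a
normal-approximation 95% band, mean ± 1.96·SD/√n. Frames with fewer than
two detections are skipped and counted. The estimator is pinned exactly
against an O(n²) double loop, and its sign behavior (clustered above CSR
above hard-core) is verified on generated patterns.

## Tracking and diffusion

Linking is Crocker–Grier-style optimal assignment: per frame, candidate
links are (track, detection) pairs within 9 px of the track's last known
position; connected subnetworks of the candidate graph are solved as
linear assignment problems minimizing total squared displacement, with
cost 81 px² (= search range²) for leaving either side unmatched. Tracks
missing a detection persist for up to 5 frames ("memory") and remain
linkable against their last known position; longer absences start new
tracks. Track length counts detections, not frames spanned, and the
minimum retained length is 20, inclusive. The contract — not the
internals — is what the published parameters pin down, so the tests
enforce exact ground-truth recovery on separable scenes and the exact
memory boundary (gap of 3 joined, gap of 6 split).

The ensemble MSD pools every displacement pair across tracks and start
times with equal weight per pair (a per-track-averaged variant is
available); gap frames contribute no pairs. The power law

$$\mathrm{EMSD}(\tau) = 4 D \tau^{\alpha}$$

is fitted by ordinary least squares of ln EMSD on ln τ; the slope is the
diffusion exponent α and `exp(intercept)/4` the apparent diffusion
coefficient D. Natural logarithms are used; the base cancels in the
slope. The default fit range is lags 1 to min(20, max_lag/2), because
long-lag EMSD rests on few pairs and is noisy; the range used is recorded
in the fit object. Motion is classified subdiffusive / Brownian /
superdiffusive with a band δ = 0.1 around α = 1 — the source method draws
no numeric boundary, so the band is a package default, configurable.
Region-resolved analysis partitions detections by band membership before
linking, so trajectories never straddle region definitions.

## Intensity metrics

The perinuclear index uses a Euclidean distance-from-nucleus field inside
the cell: I<5 is the intensity fraction within 0–5 µm of the nuclear
boundary, I>10 the fraction beyond 10 µm, and the index is
(I<5 − I>10) × 100 ∈ [−100, 100]. The 5–10 µm zone is computed and
reported but never enters the index. The whole-cell total includes the
nuclear interior (configurable), matching normalization by total cell
intensity. Band edges are compared against the continuous distance field,
not rounded to integer pixels. CTCF is
`integrated density − area × mean background` over user-supplied cell and
background ROIs, passed through even when negative.

## The synthetic generator

The generator emulates the imaging conditions the defaults assume:
HeLa-like footprints of
500–1400 µm² (disk or Fourier-perturbed blob, realized mask area within
2% of request), 0.13 µm/px, 50-frame videos, punctate spots. Point
patterns come in three regimes — fixed-n or Poisson-count CSR, a
Thomas-type parent–offspring cluster process, and sequential hard-core
inhibition — and trajectories in three — Brownian (per-axis increments
N(0, 2DΔt)), Brownian reflected in a circular corral, and constant drift
plus Brownian noise. Rectangular windows reflect trajectories specularly
(wrapping would hand the linker spurious jumps); polygon windows redraw
boundary-crossing steps. Rendering places Gaussian spots (default
σ = 1.5 px, peak 200, background 20, noise SD 5 — implementer defaults,
documented as such, since the source states no noise model) and
quantizes to 8-bit.

What the generator does *not* emulate: optics (no PSF beyond the Gaussian
spot, no 3D defocus), photobleaching, detector noise statistics, or
density-dependent motion. Passing tests therefore demonstrate estimator
correctness under the stated statistical models, not robustness to every
imaging artifact of real microscopy.

All randomness flows from one seed per generator call, and the caller's
RNG state is restored afterwards; identical parameters and seed give
bit-identical scenes, stacks, and pipeline outputs.

## Numerical choices and degenerate inputs

* Delaunay triangulation uses a sweep-hull implementation that tolerates
  cocircular inputs (points sampled on arcs); the RNG is pinned around the
  call so any internal jitter is deterministic.
* Exactly collinear or < 3 points are an error for the alpha shape;
  empty frames yield zero detections, not errors; K requires n ≥ 2 and
  frames below that are skipped.
* Fewer than two positive EMSD values, or non-positive values inside the
  fit range, abort the fit with the offending lags listed.
* Hard-core packings that cannot be realized error out after bounded
  retries rather than looping forever.
* Assignment ties in linking are broken deterministically (track id, then
  raster order of detections).

## Problem sizes

The validation suite simulates at desk scale chosen to hold Monte-Carlo
error well below the asserted tolerances: 500 trajectories × 100 frames
for exponent calibration, 20 replicates for regime-bound checks, 25–60
pattern replicates for K envelopes, and ≤ 128² rasters for the per-pixel
oracles. At these sizes the whole suite runs in well under a minute per
module on a single core.

## Known limitations

* No watershed splitting: touching puncta merge into one object, so
  counts are conservative in dense regions (visible as a few percent
  undercount in the rendered-scene tests).
* The uncorrected K estimator is biased near the window scale; compare
  curves only across identically analyzed groups.
* The alpha-shape footprint follows the outermost puncta and therefore
  underestimates the true membrane outline when the periphery is sparsely
  populated.
* Linking assumes near-constant appearance; it uses no motion model, so
  crossing particles closer than the search range can swap identities.
* All analysis is 2D; axial motion projects into apparent lateral motion.
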