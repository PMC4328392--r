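---
title: "Quantifying laminar fiber innervation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying laminar fiber innervation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fiberlayer)
```

## The measurement problem

Anterograde tracing and immunostaining label axonal fibers whose laminar
termination pattern is the scientific question: in the olfactory bulb, do
serotonergic afferents from a given raphe nucleus terminate in the glomerular
layer (GL), the external plexiform layer (EPL), or the granule cell layer
(GCL)? The raw data are large stitched confocal mosaics of coronal sections —
a sparse, thin, bright fiber signal on a smooth, spatially varying background,
with per-pixel sensor noise and occasional hot pixels. Comparing "how much
label is in each layer" across animals requires a pipeline in which every
choice (where to sample, how to remove background, what counts as signal) is
explicit, reproducible, and blind to the thing being measured.

fiberlayer implements that pipeline: layer-stratified sampling from an
anatomical mask, despeckle + rolling-ball preprocessing, per-animal global
thresholding, layer-resolved density estimation with across-layer statistics,
shift-correlation colocalization against a rotated-image null, proximity-based
marker colocalization, and the association between injection-site infection
composition and laminar projection composition. A synthetic-section generator
with exact ground truth makes every stage testable without microscopy data.

## Sampling design

Ten square samples of 120 × 120 µm are taken per layer. Placement uses only
the layer mask (derived from the nuclei channel in real data), never the
signal channel — the function signature enforces this blindness. The centroid
of the layer's pixels defines an angular origin (0° at "3 o'clock",
counter-clockwise; the convention is arbitrary but must be fixed for
reproducibility), and each 36° sector contributes at most one sample so that
all mediolateral and dorsoventral positions are covered evenly.

Within a sector the sample centre is drawn uniformly from every pixel whose
full square footprint lies inside the layer. We enumerate that candidate set
exactly — a binary erosion of the layer mask by the square footprint, computed
with two separable sliding-window passes — rather than rejection-sampling
candidate centres. The draw distribution is identical, but a sector fails only
when it genuinely admits no placement, and the failure is reported
explicitly rather than after an attempt cap. Samples in adjacent sectors of a
small layer may overlap; overlapping area is then counted in both samples
(numerator and denominator alike), which leaves the density estimator
unbiased under uniform fiber placement but adds variance in small layers.

The sample side in pixels is rounded to the nearest *even* integer
(120 µm × 7 px/µm = 840 px) so that the 90° rotation used by the
colocalization control is an exact pixel permutation of the square, with no
resampling.

## Preprocessing

Each sample is despeckled and background-subtracted before any statistics are
computed.

*Despeckle* is the 3×3 median filter — the operation that name denotes in the
standard image-processing toolchain. It removes isolated single-pixel
impulses exactly and is non-expansive. The window (default 3) and the border
policy are configuration-exposed; borders use edge replication, because
zero padding would create dark halos that bias samples near the layer edge.

*Background subtraction* is the rolling-ball estimate: the grayscale opening
of the image with a non-flat, spherical-cap structuring element of radius
30 µm (210 px at 7 px/µm), subtracted from the image and clipped at zero.
Structures much narrower than the ball — fibers are well under 1 µm wide —
pass through nearly unattenuated, while smooth illumination gradients are
removed. For radii above 32 px the opening is computed on a grid downsampled
by block minimum (factor chosen so the shrunk ball is ~16 px) with bilinear
upsampling of the background, the standard fast rolling-ball construction;
the test suite bounds this approximation against the exact opening. Both
filters run in floating point regardless of storage depth.

The composition order is fixed — despeckle, then subtract background — and is
recorded in a provenance attribute on every preprocessed sample.

## Signal detection and density

The detection threshold is global per animal: the mean and standard deviation
of pixel values pooled across *all* of that animal's samples (all layers), and
signal is any pixel strictly above mean + k·SD with k = 6. Pooling across
layers is what makes between-layer comparisons meaningful; a per-sample
threshold would adapt to — and therefore hide — exactly the laminar
differences being measured. We use the population (÷n) rather than sample
(÷(n−1)) SD; at ~10⁷ pooled pixels the difference is far below representation
error, and fixing the convention makes runs bit-reproducible. "Above" is
strict, matching the definition; ties have measure zero on real data. A
sensitivity sweep over k is available (`threshold_sensitivity()`) as a
robustness report.

Signal density is detected pixels over total pixels analysed, × 100. The
µm² conversion of numerator and denominator cancels, so the value is directly
in µm² of signal per 100 µm² of tissue; the px/µm calibration is still carried
in every record for traceability. Densities are compared across layers by
one-way ANOVA with the animal as the experimental unit (one density per
animal per layer) followed by Tukey HSD adjusted pairwise contrasts. When all
groups are identical both sums of squares vanish; we report F = 0, p = 1
for that degenerate case rather than 0/0.

## Colocalization

Two channels of the same field are compared by the van Steensel
shift-correlation diagnostic: Pearson's r between the two channels as channel
b is displaced horizontally by integer dx ∈ [−50, +50] px (~7 µm at the
working calibration; the range is a default, not a published constant).
Positive dx displaces b toward larger column indices, so a channel pair in
which b is a copy of a translated by +d px peaks at dx = −d; this sign
convention is fixed by a test. r is computed over the overlapping region
only — zero padding would damp r at large |dx| and fake a peak at 0. The
per-sample peak displacement is the integer argmax of r with ties broken
toward 0; fractional mean peak positions arise only by averaging integer
per-sample peaks across samples. Vertical displacement is equivalent by
symmetry and available behind the `axis` flag.

The null is the rotated control: the same statistic with one channel rotated
by 90°, which destroys spatial correspondence while preserving single-image
statistics. Colocalization is declared by a two-sided paired t-test of
per-sample test peak r against control peak r. If the per-sample differences
have zero variance the t statistic is undefined; the result is flagged
degenerate and p is reported as 1 (zero mean difference) or at the
machine-epsilon bound.

Point-marker colocalization pairs markers across channels one-to-one:
repeatedly match the globally closest unmatched cross-channel pair with
distance ≤ 12 µm. Greedy-by-global-minimum can in principle differ from the
optimal assignment in dense clusters; pairs whose endpoints had more than one
in-cutoff candidate are flagged ambiguous, and the test suite checks the
greedy count against a brute-force enumerated optimum on small sets. Manual
count replicates are aggregated as mean ± SD; a single replicate reports its
SD as absent.

## Infection–projection association

Per animal, the projection covariate is log₁₀((d_GL + ε_d)/(d_GCL + ε_d)) and
the infection covariate log₁₀((n_MRN + ε_c)/(n_DRN + ε_c)), correlated by
Pearson's r with the usual t-based two-sided p. Log base 10 and the
pseudocounts (ε_c = 1 cell, ε_d = 10⁻⁴ µm²/100 µm²) are package choices: the
underlying colour-scale formula states no base, and real cohorts contain
zeros in both counts and densities, so stabilization is unavoidable; both
values sit well below the scales of interest and are reported in the output.
The alternative fractional form n_MRN/(n_MRN + n_DRN) is available behind a
switch, since the exact functional form of "relative infection level" on the
published axis is not stated; neither form is asserted to be the original.
The colour encoding of the abundance ratio L (clipped to [0, 1]) is
RGB = (L, 0.8(1−L), 1−L).

The simulated mixed-injection cohort draws its group sizes and infected-cell
counts from the published cohort statistics (4 DRN-targeted animals with
303 ± 55 DRN / 11 ± 8 MRN cells; 3 MRN-targeted with 127 ± 26 MRN / 57 ± 39
DRN cells) and couples densities to composition as d_GL ∝ n_MRN^β,
d_GCL ∝ n_DRN^β with multiplicative lognormal noise (CV 0.1). On the log
scale this is y = βx + const + ε with sd(ε) = √2·CV/ln 10, so the expected
correlation is the attenuation form β·σₓ/√(β²σₓ² + σ_ε²) — a closed-form
oracle the tests compare the Monte-Carlo recovery against.

## The synthetic generator

The generator emulates what the pipeline consumes, with ground truth exact by
construction:

* **Geometry** — concentric GCL disc and EPL/GL annuli. Default outer radii
  250 / 450 / 650 µm at 7 px/µm: a deliberately compact section that keeps the
  layer topology and leaves each band ≥ 200 µm wide, the minimum at which an
  axis-aligned 120 µm square fits inside a curved band at every sector angle
  (the diagonal of the square, √2 × 120 ≈ 170 µm, plus curvature sagitta).
* **Fibers** — constant-width polyline strokes (no anti-aliasing), rasterized
  as every pixel within half-width of the path, clipped to their layer, so
  true signal area is an exact pixel count. Defaults: width 0.6 µm, two
  1.2 µm random-walk steps (heading SD 0.4 rad) — short bright fragments, as a
  punctate presynaptic-terminal label appears in a thin optical section. Whole
  fibers are added while each brings the rasterized area closer to the target
  density; the achieved (never the target) density is recorded as truth. At
  very sparse targets in small layers a single fiber is the closest
  attainable count and the quantization appears honestly in the truth table;
  only a target unreachable from below (packing limit) is an error.
* **Nuclei** — a DAPI-like channel of stamped discs, dense in GCL and GL and
  sparse in EPL. It motivates mask delineation; automatic segmentation of the
  mask from it is deliberately out of scope (masks are inputs).
* **Noise** — additive smooth quadratic background (peak 300 counts),
  Gaussian sensor noise (SD 50), and impulse "speckle" (rate 10⁻⁴, amplitude
  20000) constrained to strictly isolated single pixels so the despeckle
  stage's contract — exact removal — is testable. Intensities live on a
  16-bit count scale; fiber amplitude defaults to 12000. No published
  intensity statistics exist for the labeled material, so these amplitudes
  are free, realistic parameters, not fits.
* **Channel pairs and markers** — a stated fraction of fibers is rendered in
  both channels (second copy jittered by 0.25 µm, a sub-resolution
  registration error), the rest split alternately between channels; marker
  sets place true pairs with Gaussian offsets and keep all other points ≥ 3 ×
  cutoff apart, so truth colocalization is unambiguous for any cutoff near
  12 µm.

What the generator does **not** emulate — and what green tests therefore do
not establish about real data: optics (no PSF convolution, so no blur-limited
fiber width), photobleaching, 3-D structure (the pipeline operates on 2-D
rasters; whether the original per-"volume" correlations pooled z-planes or
used projections is unstated, a documented divergence), glomerular
substructure within the GL, and real anatomical irregularity of layer
boundaries. Detection performance on synthetic fibers with crisp edges is an
upper bound on real-tissue performance.

All randomness flows from one integer seed through deterministic sub-seed
derivation per stage and channel; identical (configuration, seed) reproduces
every raster and table bit-identically, including the on-disk pipeline
(provenance files record configuration, version and seed, and no
timestamps).

## Numerical conventions

* All µm→px conversions go through one utility (`um_to_px()`), rounding half
  to even; ROI sides round to the nearest even pixel count.
* Raster coordinates are (row, column), origin top-left; ROI bounds are
  stored as 1-based top-left corner plus side.
* Images are processed as doubles; outputs of preprocessing are clipped below
  at 0 and detection thresholds are applied with strict inequality.
* 16-bit TIFF I/O quantizes intensities to the 0–65535 grid; generation,
  being integer-amplitude, round-trips exactly.

## Problem sizes used by the tests

The suite exercises the full working calibration where the science demands it
and compact configurations where only the logic is under test: the density
recovery check runs a 3-animal cohort at 7 px/µm on the default geometry
(≈ 9200² px per section, the published density profile 0.014 / 0.0007 /
0.0008 µm²/100 µm² as generator targets, full noise model); colocalization
uses 60 µm fields (420² px) with 20 positive samples and 20 six-sample null
cohorts; the association check runs 100 seven-animal cohorts; end-to-end
determinism runs a 2-animal cohort at a coarse 2 px/µm calibration (with a
proportionally wider 2 µm synthetic fiber so the strokes remain more than one
pixel wide) through all four pipeline stages twice.

## Known limitations

* The density estimate samples ~20–30% of a layer's area; for layers holding
  only tens of discrete fiber fragments the estimate carries sampling
  variance of order 15–20% per animal. This is a property of the sampling
  design itself, visible in the acceptance measurements.
* Greedy marker matching is exact on unambiguous material (enforced in the
  generator, flagged in real data), but is not a full optimal-assignment
  solver.
* The shift-correlation is horizontal-only by default; vertical is available
  but no 2-D displacement surface is computed.
* The sensitivity sweep over the threshold multiplier k reports densities
  over a user-chosen grid; no published sweep range exists to compare
  against.
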