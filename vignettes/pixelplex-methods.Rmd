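---
title: "Pixel-level co-expression analysis of cyclic multiplexed immunofluorescence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-level co-expression analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Cyclic multiplexed immunofluorescence images a tissue section over many
staining rounds (cycles): in each cycle a few antibodies are applied,
imaged at their emission wavelengths, and eluted before the next round.
The result is a stack of tens to hundreds of marker channels over the same
field of view (FOV), acquired at subcellular pixel sizes. `pixelplex`
analyses such experiments at the *pixel* level: instead of segmenting
cells first, it clusters the multichannel intensity vectors of individual
pixels into protein co-expression patterns ("clusters"), quantifies their
abundance and spatial adjacency, tests them between conditions, and only
then optionally aggregates them into cell-level metaclusters around
externally segmented nuclei.

# Pipeline stages and their models

## Registration

Each cycle's reference channel (a nuclear stain or a pan-protein label
such as an amine-reactive NHS-ester) is conditioned by percentile clipping
(defaults 1 / 99.9), z-scoring, min–max scaling to [0, 1], a Gaussian blur
of sigma 1 px, histogram matching to the first-cycle reference, and
zeroing of everything below the 70th percentile of the blurred image —
sharpening the stained-structure/background contrast that drives
alignment. Shifts are then detected by phase cross-correlation with local
discrete-Fourier upsampling (default factor 5, i.e. 0.2 px resolution).
Optionally a projective refinement follows: Harris-corner keypoints on the
reference are matched at subpixel precision by Hann-windowed local phase
correlation (a second pass re-centres each moving patch on the integer
part of the first estimate, removing the shrinkage bias a spatial window
induces on off-centre content), and a homography is fitted with a
random-consensus estimator (reprojection tolerance 3 px, fixed seed). All
channels of a cycle receive the same transform; fractional shifts use
bilinear interpolation with zero fill.

Alignment quality is graded by the structural similarity index (SSIM)
before and after registration, with four review flags: the SSIM decreased;
the SSIM after registration is below 0.3; any shift component exceeds 300
px; or the SSIM after registration is below 0.8 while the improvement is
below 0.05. Flagged cycles are reported for manual review, not discarded —
automatic rejection would silently bias abundance estimates. Finally all
cycles are cropped to a common window, either by removing the ceiling of
the largest absolute offset from all four sides (equal-size frames) or by
intersecting the shifted fields.

## Masking and signal correction

Tissue foreground is the Otsu binarization of the minimum projection of
the per-cycle reference images: any area that lifted in at least one cycle
drops out of the projection and hence out of the analysis. Erythrocytes
(strongly autofluorescent) are masked from an erythrocyte marker channel:
clip to the 90th–99.5th percentiles, Otsu, removal of connected components
below 72 px (8-connectivity), two dilations with a 3×3 cross, and hole
filling. The analysis mask is `foreground & !rbc`.

Tissue autofluorescence is estimated per wavelength from secondary-only
cycles (staining rounds with secondary antibodies but no new primary):
for each primary cycle the two nearest secondary-only images at the same
wavelength are interpolated linearly in cycle index (constant
extrapolation at the ends) and subtracted with clipping at zero. The same
secondary-only cycles drive elution quality control: a primary channel
whose 50th or 99.95th intensity percentile is equal to or lower than the
corresponding percentile-wise maximum over matched secondary-only images
(same wavelength, same host species) is flagged for manual review — either
elution failed or the marker is genuinely sparse.

## Subsampling and normalization

Clustering is fitted on a weighted stratified subsample of pixel
positions: per imaging plate, the requested total is split equally over
conditions, within a condition equally over samples, and within a sample
equally over FOVs, using largest-remainder rounding with a lexicographic
tie-break; within a FOV, positions are drawn uniformly without replacement
from the analysis mask. This prevents large samples or heavily imaged
conditions from dominating the fitted clusters. Per-channel histogram
clipping (defaults: 50th and 99.7th percentiles of the pooled subsample;
absolute bounds supported) and affine normalization to [0, 1] are fitted
on the subsample and applied to every image.

## SOM + graph clustering

A batch self-organizing map (SOM) compresses the subsample to a lattice of
prototype vectors (nodes). Each iteration assigns every point to its
best-matching node (Euclidean, cosine, or Pearson = 1 − r on mean-centred
vectors) and replaces each node by the Gaussian-lattice-kernel-weighted
mean of the assigned points; the kernel sigma decays exponentially from
`grid_side / 2` to 1e-3 over 50 iterations. We use the classic Kohonen
batch update (full replacement): in the batch formulation the annealed
neighbourhood plays the role the learning rate plays online, and a damped
schedule that decays to ~1e-4 freezes the lattice before the neighbourhood
collapses, leaving nodes measurably short of their local means (they fail
a planted-signature recovery that full replacement passes). An optional
learning-rate schedule below 1 is retained for users who want damped
updates, and the full-scale presets record the historical final value 1e-4
alongside the other preset parameters.

SOM nodes are then connected in a k-nearest-neighbour graph (union
symmetrization, ties to the lowest index). Multi-plate experiments use a
batch-balanced variant: every node receives `k` nearest neighbours within
*each* plate, forcing cross-plate connectivity so plate effects cannot
split clusters. Communities are found by Leiden with the modularity
objective at a given resolution, deterministically seeded; every pixel of
every image then inherits the cluster of its best-matching node, with
masked pixels labelled −1. Clusters occupying ≤ 0.1% of foreground pixels
are flagged for expert review rather than deleted.

Desk-scale defaults (32×32 grid, 100k subsample, k = 15, resolution 1) are
sized so a complete synthetic study runs in minutes on one core; presets
`cgn`, `dkd` and `early-t2d` carry the full-scale parameterizations
(500²/400² grids, 5–10 M subsamples, k = 40/50, resolutions 1 / 2.5 / 2).

## Statistics

Cluster abundance is the fraction of counted pixels per cluster per FOV
(rows sum to 1); patient-level tables average a sample's FOVs. Differential
abundance uses a two-sided Welch t-test per cluster with
Benjamini–Hochberg (step-up FDR) or Holm–Šidák (step-down FWER)
correction. The log2 fold change is stabilized by ε = half the smallest
positive abundance in the table, engaged *only when a group mean is zero*
— always adding ε would bias every reported fold change, whereas the
conditional form only affects ratios that are otherwise undefined. Marker
contributors per cluster compare in-cluster versus out-of-cluster mean
normalized intensity (Welch test, corrected across markers within the
cluster); a marker is a *high contributor* when its mean normalized
intensity is ≥ 0.2, its adjusted p is < 0.05 and its log2 fold change is
≥ 1, and markers are ranked by mean × log2 fold change. Contributor tests
default to SOM node weights as observations (each node summarizes many
pixels; using raw pixels makes p-values arbitrarily small with pixel
count), with the subsample as the configurable alternative.

## Spatial adjacency

Join counts tally, for every unmasked pixel, the cluster labels of its up
to eight in-bounds unmasked neighbours (first-order queen neighbourhood;
no wraparound or padding, masked pixels skipped entirely). Per-condition
sums discard self-connections and are normalized to [0, 1] by the global
off-diagonal maximum; the display graph keeps directed edges whose
row-relative neighbourhood share is at least 7.5%. Both matrices (global
normalization and row shares) are exported because "normalized to 0–1" is
ambiguous between them; the display threshold is phrased as a
neighbourhood share and therefore uses the row-relative matrix.

## Cell-level metaclustering

Nucleus centroids are supplied externally (segmentation is not a pipeline
stage). All nuclei of a FOV share one disc radius: the smaller of 5 µm and
half the shortest Delaunay-triangulation edge — which equals half the
minimum pairwise centroid distance, since the closest pair of points is
always a Delaunay edge; the implementation therefore needs no
triangulation and the radius rule is exact. A per-FOV radius (rather than
per-nucleus) keeps cell areas comparable within a field; the per-nucleus
alternative would require the full triangulation. Pixels belong to a disc
if their centre is within the radius (inclusive). Each cell's feature
vector is the fraction of in-disc unmasked pixels per cluster; cells are
grouped by a kNN graph (default k = 50) plus Leiden (resolution 1), and
metacluster abundances — averaged per image and then per patient — are
compared between conditions with a two-sided Mann–Whitney U-test,
Bonferroni-corrected across metaclusters.

# The synthetic-data generator

`synthetic_config()` / `generate_experiment()` emulate a complete
experiment with known ground truth: K planted co-expression signatures
(each with two defining markers ≥ 0.7 and off-markers ≤ 0.08, defining
pairs unique and usage-balanced across the panel, pairwise cosine < 0.95)
laid out as non-overlapping discs over empty background; per-FOV tissue
coverage varying lognormally (default CV 0.2); per-cycle integer shifts
(default up to ±5 px) and optional small rotations; additive
autofluorescence shared across cycles within a wavelength group (three
markers per group, so members sit in different cycles and the
interpolation across secondary-only cycles — emitted as the first and last
cycle — is genuinely exercised), with a smooth spatial field and a linear
amplitude drift across cycles; occasional erythrocyte-like blobs bright in
all channels plus a dedicated erythrocyte marker channel; a pan-protein
reference channel with fixed speckle texture in every cycle; and Gaussian
noise (default s.d. 5% of the signature intensity scale). Intensities are
written as 16-bit TIFFs with a YAML manifest; everything is deterministic
given the seed.

The default study has 2 conditions × 3 samples × 4 FOVs of 256² px with 8
markers and 6 signatures, and the second condition doubles pattern 1's
expected blob count. What the generator does *not* emulate: optical
point-spread functions, shot noise, chromatic aberration, lens distortion,
antibody cross-reactivity, or any real biological texture — passing tests
therefore demonstrate algorithmic correctness under the stated noise
model, not performance on real microscopy data.

## Design of the differential-abundance recovery study

Cluster abundances are compositions (rows sum to 1), so a planted 2-fold
increase in one pattern necessarily depletes the relative share of every
other cluster by log2(K/(K+1)); no generator can remove this closure. The
recovery study is therefore designed for a large pattern count (K = 24,
closure ≈ −0.06 log2 per other cluster) against per-pattern count noise of
CV ≈ 0.29 (12 blobs per pattern, 224² FOVs so the blobs place without
crowding), tested over 12 vs 12 FOVs, where the planted effect (~+0.9
log2 in shares) is detected at high power while the closure depletion
stays well below the detection threshold. A residual ~10% chance per run
that some null cluster crosses the Benjamini–Hochberg threshold is
intrinsic to FDR control at α = 0.05 with one strong discovery, and
Leiden occasionally merges the planted pattern with a neighbour, diluting
its fold change; the recovery check therefore requires 4 of 5 seeded
replicates to flag exactly the planted cluster rather than all 5.

# Numerical conventions

* Coordinates are (row, col), 0-based in transform matrices, 1-based in R
  raster indexing; shifts are (d_row, d_col), positive = down/right.
* `detect_shift(reference, moving)` returns the offset of *moving*
  relative to *reference*; the registration orchestrator stores the
  correction (its negation), which `apply_transform()` applies directly.
* Percentiles interpolate linearly between order statistics
  (`quantile` type 7) everywhere.
* Z-scores use the population standard deviation; constant inputs return
  zeros with a warning instead of NaN.
* Integer TIFFs are read at native values — no implicit /65535 rescale;
  the only intensity transforms are the explicit clip/normalize steps.
* Label images store −1 for masked pixels; on disk they are offset by +1
  into a 16-bit raster, which round-trips losslessly.
* kNN ties break to the lowest node index; Leiden is seeded and labels are
  compacted to 0..K−1.
* Welch's unequal-variance t-test is used wherever a "two-sided t-test" is
  called for; zero-variance groups degrade to p = 1 (equal means) or p = 0
  (different means) instead of erroring.

# Known limitations

* Rigid shift + projective refinement only: no nonrigid or iterative
  multi-resolution registration, no lens-distortion correction (input is
  assumed pre-corrected).
* The corner-based projective refinement assumes the residual transform
  after shift correction is small (a few pixels); large rotations or scale
  changes are out of scope.
* Elution QC percentiles default to the full frame unless a mask is
  supplied; sparse markers can be flagged spuriously and are meant for
  manual review.
* Differential abundance treats FOVs (or patients) as independent
  observations; no hierarchical or compositional (log-ratio) modelling.
* The SOM lattice size bounds the number of distinguishable clusters;
  desk-scale grids are for method validation, not full-scale studies.
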