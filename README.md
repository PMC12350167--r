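# pixelplex

Pixel-level protein co-expression analysis for cyclic multiplexed
immunofluorescence experiments.

Cyclic multiplexed immunofluorescence repeatedly stains, images and elutes
antibodies on the same tissue section, building up tens to hundreds of
marker channels per field of view (FOV) at subcellular resolution.
`pixelplex` analyses such experiments without segmenting cells first: it
treats every pixel's multichannel intensity vector as an observation and
discovers *protein co-expression clusters* jointly across all images of an
experiment, then quantifies them statistically and spatially.

The pipeline, in order:

1. **Registration** — every cycle's reference channel (nuclear stain or
   pan-protein label) is aligned to the first cycle by subpixel phase
   cross-correlation, optionally refined by a keypoint-based projective
   fit; alignments are graded by SSIM with four review flags, and all
   cycles are cropped to a common window.
2. **Masking & correction** — tissue foreground from the minimum
   projection of the reference channels (Otsu), erythrocyte masking from
   an RBC marker, per-wavelength autofluorescence interpolated between
   secondary-only cycles and subtracted, and elution quality control
   against the secondary-only baseline (50th / 99.95th percentiles).
3. **Clustering** — a weighted stratified pixel subsample (equal weight
   per condition, sample and FOV) is clip/range-normalized per channel,
   compressed by a batch self-organizing map, connected in a
   (batch-balanced) k-nearest-neighbour graph and partitioned by Leiden
   community detection; every pixel of every image inherits its node's
   cluster.
4. **Statistics** — per-FOV cluster abundances (fractions summing to 1),
   patient-level aggregation, two-sided Welch t-tests with
   Benjamini–Hochberg or Holm–Šidák correction, and per-cluster marker
   contributor statistics with the high-contributor gates
   (mean normalized intensity ≥ 0.2, adjusted p < 0.05, log2 fold change ≥ 1).
5. **Spatial analysis** — first-order queen-neighbourhood join counts
   between clusters, aggregated per condition into normalized vicinity
   graphs (7.5% neighbourhood-share display threshold).
6. **Metaclustering** — pixel-cluster composition inside discs around
   externally segmented nucleus centroids (radius = min(5 µm, half the
   closest centroid distance)), grouped by kNN + Leiden and tested between
   conditions with Mann–Whitney U / Bonferroni.

A fully synthetic experiment generator (`synthetic_config()`,
`generate_experiment()`) emulates planted co-expression signatures in
spatial blobs, per-cycle rigid shifts, shared autofluorescence with
secondary-only cycles, erythrocyte-like blobs and sensor noise — with
complete ground truth, so every stage is testable end to end without any
external data. See the methods vignette
(`vignettes/pixelplex-methods.Rmd`) for the models, parameter choices and
limitations.

## Worked example

```r
library(pixelplex)

# generate a synthetic two-condition experiment (8 markers, 6 planted
# signatures, 2 conditions x 3 samples x 4 FOVs of 256x256 px)
gen <- generate_experiment(synthetic_config(seed = 1), "synth_data")

# run the full pipeline at desk scale (32x32 SOM, 100k subsample, k = 15)
res <- run_pipeline(gen$manifest,
                    run_config(rbc_channel = "GYPA"),
                    out_dir = "results")

res$model$n_clusters
#> [1] 6

# score the recovered clusters against the planted ground truth
means <- cluster_mean_profiles(res$node_weights, res$model$node_labels)
rep <- score_against_truth(res$cluster_images, gen$truth,
                           cluster_means = means,
                           detected_shifts = res$shifts)
rep$shift_rmse; rep$min_cosine; rep$pixel_ari
#> [1] 1.832175e-16
#> [1] 0.9966662
#> [1] 1
```

The run recovers exactly the six planted signatures: each matched cluster
mean has cosine similarity > 0.996 to its planted co-expression vector,
and the pixel labels agree with the planted blob map up to permutation
(adjusted Rand index 1). Every planted per-cycle shift was recovered
exactly (RMSE ~ 0). `results/` contains the registration QC
table, abundance and differential-abundance tables (volcano-ready),
contributor statistics, cluster label TIFFs and per-condition vicinity
graphs (CSV + GraphML).

A thin command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/pixelplex.R", package="pixelplex"))') \
    synth --out data/ --seed 1
Rscript .../pixelplex.R run --manifest data/manifest.yaml --out results/ \
    --rbc-channel GYPA --seed 7
```

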