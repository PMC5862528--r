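---
title: "Quantifying clonal tumor growth in imaginal discs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clonal tumor growth in imaginal discs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`discquant` packages the quantitative workflow of a clonal tumor study in
*Drosophila* eye-antennal imaginal discs: mutant clones of an epigenetic
regulator (a PRC1 member) are induced mitotically, GFP-labelled, imaged as
confocal z-stacks, and quantified as the fraction of the tissue volume they
occupy; proliferation is scored by counting phospho-histone H3 (pH3)
positive nuclei inside and outside the clones; and the tumor's
transcription-factor signature is examined by hierarchical clustering of
expression profiles. This vignette documents the models, the defaults and
the reasoning behind the design choices. Everything below is computed by
the package's test suite or its acceptance script; no result is quoted
that the code does not reproduce.

## The measurement model

For one disc the central quantity is the **tumor volume percent**

$$
V_\% \;=\; 100 \times
\frac{\sum_k \text{vol}(\text{clone}_k)}{\text{vol}(\text{tissue})},
$$

with the tissue defined by the DAPI (nuclear) channel and clones by the
segmented GFP signal. Volumes are voxel counts times the physical voxel
volume; clones are connected components of the clone mask under
26-connectivity (voxels sharing a face, edge or corner), the convention of
typical 3D surface tools. Conditions are summarised as mean ± SD of the
per-disc percentages (mean of ratios). Whether the original analysis used
mean-of-ratios or ratio-of-means is not documented; mean-of-ratios matches
the reporting of per-disc dots in the figures and weights every disc
equally, so it is the package's choice.

pH3 counts are partitioned by the clone mask — a detected spot is *inside*
iff its centroid voxel lies in a clone — and normalised per mm³ of the
respective reference volume: whole tissue, GFP⁺ volume, or GFP⁻ volume
(1 mm³ = 10⁹ µm³). When a disc has no clones the inside density is
undefined and is reported as `NA`, to be excluded from group summaries
rather than silently zeroed.

## Supervised voxel classification

The study's segmentation was a supervised pixel classifier trained
interactively on five tumor discs; the exact features and labels are
unpublished. `discquant` re-implements the idea reproducibly:

* **Features** (per voxel, on the GFP channel): raw intensity, and for
  each smoothing scale (defaults 1 µm and 3 µm) the Gaussian-smoothed
  intensity, its gradient magnitude and its Laplacian. Scales are
  physical; the per-axis sigma is `scale_um / voxel_size_um[axis]`, so
  anisotropic sampling (z spacing ≈ 1 µm vs 0.5 µm laterally) is corrected
  in microns, not voxels.
* **Classifier**: a random forest (100 trees) on labelled voxels
  (1 = clone, 2 = not-clone, 0 = unlabelled), subsampled to at most
  20 000 voxels per class under a fixed seed, with a 20% held-out split
  whose accuracy is stored in the model's metadata.
* **Mask**: clone probability ≥ 0.5, intersected with the tissue mask,
  minus connected objects smaller than 50 µm³. The probability volume is
  kept for audit. Raising the threshold can only shrink the mask
  (monotonicity), which the tests assert.

The tissue mask is a reproducible stand-in for the proprietary surface
tool used originally: sub-voxel Gaussian smoothing (0.4 µm) of DAPI, a
global Otsu threshold, boundary regularisation by thresholding the
smoothed binary mask at 0.5 (a majority vote that removes
texture-induced boundary noise without biasing the volume), filling of
interior holes, and removal of components below 500 µm³. Disjoint lobes —
the eye and antennal lobes can pinch apart in a section — are retained.
The sub-voxel smoothing scale matters: smoothing DAPI at several microns
flattens the tissue edge so much that nuclear texture moves the threshold
crossing by 1–2 voxels, which costs several percent of overlap accuracy
on a small disc.

## pH3 spot detection

Spots are detected with a single-scale Laplacian-of-Gaussian filter tuned
to a nuclear radius of 2.5 µm (sigma = radius/√3, where the 3D LoG
response of a ball of that radius peaks). Local maxima over the
26-neighbourhood are kept if they exceed a robust noise floor — six times
the MAD of the response, which is exactly zero on an empty channel and
scales with the noise on a real one — then maxima closer than one radius
are merged keeping the stronger, and detections outside the tissue mask
are discarded. The original study counted pH3⁺ cells with a semi-automated
commercial tool whose parameters are not stated; the LoG detector is a
declared stand-in, validated against the phantom ground truth (precision
and recall ≥ 0.9 in the tests; unbiased counts over 100 seeds in the
acceptance suite).

## The synthetic phantom

The generator emulates the study's imaging conditions at a reduced scale
so that the full pipeline can be exercised in seconds:

* **Geometry**: 24 × 56 × 80 voxels at 1.0 × 0.5 × 0.5 µm (z, y, x). The
  z spacing mirrors the ~1 µm z-stacks of the study; the lateral sampling
  is typical 20×/40× confocal pixel size. The tissue is the union of two
  overlapping ellipsoids (eye and antennal lobes) with ±4% random jitter
  in position and radii.
* **Clones**: Gaussian bumps (6 µm length scale) seeded at 3–8 random
  tissue voxels plus a smoothed noise field, thresholded at the tissue
  quantile that yields the target voxel count. Lowering the threshold
  accretes voxels, so this finds the accretion endpoint in one step and
  the realised clone fraction equals the target to within one voxel —
  well inside the ±0.01 tolerance the generator promises.
* **Channels**: DAPI is the tissue with 30% nuclear-scale multiplicative
  texture; GFP is the clone support at fixed amplitude; pH3 is a sum of
  Gaussian spots (sigma = 2.5 µm/√3). All channels pass through a 0.5 µm
  optical blur, Poisson shot noise and Gaussian read noise set by the
  signal-to-noise ratio (default 10).
* **pH3 ground truth**: per-compartment counts are Poisson with mean
  density × compartment volume in mm³; centers follow a hard-core process
  (minimum separation twice the nuclear radius, enforced across the clone
  boundary too) because nuclei cannot overlap — this also means the
  detector's merge rule cannot systematically lose spots. The density
  defaults (3 × 10⁶ mm⁻³ inside clones, 1 × 10⁶ mm⁻³ outside) are scaled
  up from per-disc figures because the phantom is a miniature: they give
  a few tens of mitotic figures per phantom, the per-disc scale of the
  real data.
* **Presets**: `make_condition_preset()` registers the reported mean
  tumor-volume fraction per genotype (46% baseline, 7% rescue, 14/13/5/14%
  for the cad/drm/kni/bgcn knock-downs, 14% for the independent second kni
  RNAi line, 6% with apoptosis blocked, 3% for atonal overexpression). The
  neutral-clone control preset (25%) is a stand-in — no control fraction
  is reported — and is flagged as such in its documentation.

Every generator is a pure function of `(params, seed)`: identical inputs
give bit-identical stacks, and the caller's RNG stream is saved and
restored.

**What the phantom does not model**: optical point-spread anisotropy and
spectral bleed-through, intensity attenuation with depth, nuclear packing
in DAPI beyond a texture field, clone shapes driven by tissue mechanics
(real neoplastic clones are lobulated; the phantom's blobs are smooth),
and any biology of eclosion or transplantation beyond binomial survival.
Passing the recovery tests therefore shows the pipeline is unbiased under
realistic noise and geometry, not that it would match a human expert on
real discs.

## Synthetic expression data

Counts are negative binomial, `NB(mean = q_g · ℓ_j · 2^{s_{gj}}, dispersion α)`
with gene baselines `q_g` log-normal (meanlog log 100, sdlog 1.2), library
factors `ℓ_j` uniform on [0.7, 1.3] and α = 0.1 — values typical of bulk
RNA-seq at moderate depth. The signal `s_{gj}` encodes the study's
signature logic: an *embryonic-TF module* (60 genes) up-shifted by
log2FC = +3 in both tumor and embryo samples, and a *neural module*
(64 genes; the module sizes sum to the 124-gene TF signature of the study)
expressed at baseline in disc-like tissues and down-shifted by −3 in tumor
and embryo samples — embryos have not yet activated the neural
differentiation program, which is what makes the tumor profiles cluster
with embryos rather than with their tissue of origin. The default design
(10 embryos, 10 eye discs, 7 tumors, 4 controls, 8 other samples) echoes
the study's 7 + 4 own samples inside a broader public compendium.

The DE stand-in normalises by median-of-ratios size factors, estimates a
per-gene NB dispersion by method of moments and moderates it by the
across-genes median — with a handful of samples per group the moment
estimate frequently collapses to zero, which would make the Wald statistic
explode; raising those estimates to the median is the minimal shrinkage
that restores calibration (0 false calls in the null tests at padj ≤ 0.01)
while keeping power ≥ 0.9 on the module genes. It is explicitly not a
reimplementation of a full DE framework; its role is to select signature
genes on synthetic counts.

## Clustering

Samples are clustered on 1 − Pearson correlation over the signature genes
(so any positively affine-rescaled profile is at distance zero), genes on
Euclidean distance — the study's stated distance pair. The study does not
state its linkage or the exact variance-stabilising transform, so both are
configuration points: average (UPGMA) linkage by default, and
`log2(count/size factor + 1)` as a monotone, variance-flattening VST
surrogate. Agglomeration is `stats::hclust`, whose deterministic
tie-handling (ordered merge indices) is inherited. "Tumor samples cluster
with embryos" is quantified by `co_cluster_purity()`: cut the dendrogram
into k flat clusters, find the cluster holding the majority of embryo
samples (a tie is an error, not a guess), and report the fraction of tumor
samples inside it.

## Cohort statistics

Eclosion rate is `100 × adults/larvae`. The methods text of the study
words the ratio the other way round, but every printed rate (99% control,
97% rescue, 12% baseline) is only consistent with adults over larvae, so
that is what the package computes. Condition summaries are mean ± SD
(sample SD, n − 1).

Group comparisons mirror the study's tests: Kruskal–Wallis (tie-corrected,
chi-square reference, via `stats::kruskal.test`) with Dunn's post hoc for
rank-scale measures, and one-way ANOVA with Dunnett's comparisons to
control for volume-scale measures. Dunn's z uses the tie-corrected
pooled-rank variance and Bonferroni adjustment over the chosen comparison
family — the convention of the commercial statistics package used in the
study; both all-pairs and vs-control families are provided because the
study does not say which was used. Dunnett's family-wise adjustment is
computed by seeded Monte-Carlo of the null max-|t| distribution with the
design's exact (possibly unbalanced) correlation structure, default 10⁵
draws; this handles any group sizes uniformly, reduces to the pooled
t-test with two groups, and agrees with the multivariate-t implementation
in `multcomp` to two decimals in the tests. Adjusted p-values are clamped
to be at least the raw ones. All tests are two-sided.

## Numerical choices and degenerate inputs

* Gaussian smoothing is separable with row-normalised discrete kernels
  truncated at 3σ (a replicate-boundary approximation); gradients are
  central differences and Laplacians second differences, both in physical
  units.
* Connected components are found by building the voxel adjacency graph
  and labelling its components; labels are deterministic (first-occurrence
  order).
* Otsu's threshold refuses (near-)constant input instead of returning an
  arbitrary cut; `measure_disc` tags every stage's errors with the stage
  name.
* All-identical data: Kruskal–Wallis reports H = 0, p = 1 with a
  `degenerate` flag; the ANOVA/Dunnett path does the same instead of
  dividing by a zero variance.
* Clone-free discs report 0%, zero clones, and an `NA` inside-density.

## Problem sizes

The recovery suites use 30 phantoms per condition with a classifier
trained on 5 separate phantoms, 100 phantoms for the pH3 density
calibration, 20 seeded runs for the clustering property, 5000 null
simulations for the type-I-error and family-wise-error checks, and 2000
binomial replicates for eclosion — sizes at which the Monte-Carlo error
of each check is several times smaller than the tolerance it is compared
against.

## Known limitations

The classifier is trained and evaluated on phantoms from the same
generator, so its measured accuracy does not transfer to real microscopy;
the declared defaults (threshold 0.5, 50 µm³ floor, 2.5 µm nuclear
radius) are starting points to be re-examined on real data. The simplified
VST and the DE stand-in are deliberately minimal. The clone-count
statistic depends on the generator's blob geometry and is not compared to
printed values, which exist only as figure dots. Transplantation
time-courses and survival modelling are out of scope.
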