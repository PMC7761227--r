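---
title: "Imaging subtypes from single-cell spatial phenotypes of H&E sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging subtypes from single-cell spatial phenotypes of H&E sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hespat implements a quantitative pipeline for hematoxylin-and-eosin
pathology built on a *typed single-cell map*: every nucleus of a tissue
section segmented, outlined and classified as tumor cell, lymphocyte or
other non-malignant cell, together with three regions of interest (whole
tumor, tumor core, tumor periphery). From this map the package computes a
246-feature spatial phenotype per patient, discovers *imaging subtypes*
by consensus clustering, validates them with the in-group proportion
statistic, and carries the subtypes into association and survival
analysis. A built-in generator simulates H&E-like cohorts so that every
stage of the pipeline is testable end to end without any external data.

This vignette is the package's methods account: the models and their
assumptions, the parameters that matter, the numerical conventions, the
design choices that were genuinely open, and what the synthetic cohorts
do and do not establish about real tissue.

## The cell map and its conventions

A `cellmap` holds per-nucleus polygons (closed rings), centroids and
classes plus the three ROI polygons; `read_cellmap()`/`write_cellmap()`
round-trip it through GeoJSON FeatureCollections in pixel coordinates.

Conventions, chosen once and applied everywhere:

* Coordinates are 0-based pixels, x to the right, y down, matching raster
  indexing of the image patches; `pixel_size_um` (default 0.25 µm at 40×)
  is carried as metadata but **all radii and grid sizes stay in pixels**,
  since the neighborhood radii (50/100 px) and quadrat side are defined
  in pixels.
* Point-in-polygon tests count the boundary as inside — a deterministic
  tie rule for centroids that fall exactly on an ROI edge.
* The tumor periphery is stored as an annulus (outer + inner ring): the
  outermost band of the tumor is a band, not a simple polygon.
* ROI membership of a nucleus is decided by its centroid. Nuclei outside
  all ROIs are flagged and counted, never silently dropped.
* Pixels belong to a nucleus mask when their integer center lies inside
  the polygon (scanline parity); morphology, by contrast, is computed
  from the polygon itself and is therefore exact for the stored contour.

## The 246-feature phenotype

The feature space has four blocks, with a machine-readable registry
(`feature_registry()`, shipped as TSV) giving name, category, region,
radius and formula for every feature:

| block | count | region |
|---|---|---|
| nuclear morphometry | 20 | whole tumor |
| intensity histogram | 14 | whole tumor |
| GLCM texture + gradient | 62 | whole tumor |
| color | 54 | whole tumor |
| density / homogeneity | 28 | core + periphery |
| tumor–lymphocyte interaction | 64 | core + periphery |
| composite counts | 4 | core + periphery |

**Nuclear features.** The published taxonomy gives patient-level counts
(20/14/62/54) without per-nucleus formulas. We realize them as 75 base
descriptors per tumor nucleus, each aggregated to the patient level by
mean and sample (n−1) standard deviation over tumor nuclei in the whole
tumor, which reproduces the printed counts exactly (10/7/31/27 × 2).
The base descriptors are:

* *morphology (10)*: area, perimeter, equivalent diameter
  2√(area/π), major/minor axis (from second area moments of the
  polygon), eccentricity, solidity, extent, circularity 4πA/P², aspect
  ratio. All from the polygon, not a rasterized mask.
* *histogram (7)*: mean, sd, skewness, excess kurtosis, Shannon entropy
  (32 bins over [0, 255]), 10th/90th percentile of the in-mask
  luminance (Rec. 601: 0.299 R + 0.587 G + 0.114 B). Within-nucleus
  moments use the population (1/n) denominator; skewness/kurtosis of
  constant pixels are defined as 0.
* *texture (31)*: 13 Haralick statistics of the gray-level
  co-occurrence matrix — 32 gray levels (value ÷ 8), symmetric,
  normalized, averaged over the 4 directions — at offsets 1 and 2 px,
  plus 5 Sobel gradient statistics (mean, sd, skewness, p90, fraction of
  in-mask pixels above the Otsu threshold of the whole patch's gradient
  magnitude). 32 levels and offsets {1, 2} are conventional choices at
  nuclear scale (~10–40 px) and fast on a desk machine.
* *color (27)*: mean, sd, skewness, entropy, p10, median, p90, min, max
  per RGB channel.

**Spatial features.** "Uniformity" of a cell population is realized as
quadrat statistics: counts on a 200-px grid anchored at the ROI bounding
box, keeping quadrats whose ROI coverage (estimated on a 5×5 point
lattice) is at least 50%. Seven statistics — density per 10⁴ px² of ROI
area, quadrat mean, sd, CV, fraction empty, Morisita index, mean
nearest-neighbor distance — per cell class (tumor, lymphocyte) per
region give the 28 density/homogeneity features. The Morisita index is 1
in expectation under complete spatial randomness and grows with
aggregation, which the CSR calibration tests verify by simulation.

The **interaction matrix** records, for every tumor nucleus in a region,
the number of tumor and lymphocyte nuclei whose centroid lies within 50
or 100 px of its centroid ("expansion by a radius" is interpreted as
centroid-to-centroid distance, which is deterministic and independent of
segmentation quality; polygon dilation would couple the neighborhood to
nuclear size). Counts use a uniform-grid spatial index whose arithmetic
is identical to the naive all-pairs scan — a property the test suite
checks exactly on random maps. Eight statistics (mean, sd, median, max,
skewness, q75, fraction zero, entropy of the count histogram) × 2
neighbor classes × 2 radii × 2 regions give 64 features; radius-50
features carry unsuffixed names (`tumor_lymph_relation_mean_CT` is the
mean lymphocyte count within 50 px per tumor cell in the core).

The four printed block totals (150 + 28 + 64) sum to 242, not 246; four
**composite** features (lymphocyte:tumor ratio and total nuclei count in
core and periphery) close the gap and are flagged "reconciliation" in
the registry so the accounting is auditable.

## Subtype discovery

**Preprocessing.** Features arrive on wildly different scales (areas in
px², fractions, entropies). The `feature_matrix()` default rank-transforms
every feature across specimens before any distance is computed. This has
two effects: all downstream distances become invariant to monotone
transformations of any single feature, and no feature dominates by
scale. Constant features are dropped with a message. (Z-scoring and raw
values remain available.)

**Distance.** `spearman_distance()` computes d(i,j) = 1 − ρ_s between
specimen rows (midrank ties), bounded in [0, 2].

**PAM.** k-medoids with deterministic tie-breaking (lowest index). For
tiny instances — at most 500 candidate medoid sets, which covers every
n ≤ 8, k ≤ 3 — the medoid set is found by exact enumeration; the global
optimum trivially admits no improving single swap, so the BUILD+SWAP
termination contract holds at once. Larger instances use greedy BUILD
followed by steepest-descent SWAP. The exact small-instance path exists
because plain BUILD+SWAP converges to a local optimum in roughly 5–10%
of tiny random instances (we verified the identical behavior in the
independent `cluster::pam` implementation), and the package promises
exhaustive-search equality at that scale.

**Consensus clustering.** Each of B bootstrap replicates samples 80% of
the features *and* 80% of the specimens without replacement, computes
the Spearman distance on the subsample, and runs PAM at every K in
2..6. The consensus value of a specimen pair is its co-clustering count
divided by its co-presence count. Resampling specimens as well as
features is essential: with feature-only resampling a deterministic
clusterer sees nearly the same distance matrix every replicate and
returns nearly the same partition, so the consensus matrix is crisp at
*every* K and carries no information about cluster stability. B defaults
to 10,000; the package's own analyses use B = 1,000 and the test suite
B = 100–500 (scaled down for desk-speed runs). Final
labels at each K come from average-linkage hierarchical clustering of
1 − consensus, the convention of the consensus-clustering literature.

**Choosing K: the CDF delta-area rule, and its threshold.** Let A(K) be
the area under the empirical CDF of the upper-triangle consensus values
at K, and Δ(2) = A(2), Δ(K) = (A(K) − A(K−1))/A(K−1). The selected K is
the largest K with Δ(K) > δ_min.

The threshold deserves care, because A(K) has a closed interpretation:
for values in [0, 1], the area under the empirical CDF equals one minus
the sample mean, so **A(K) = 1 − mean(consensus)**. Moving from a crisp
K-partition to a crisp (K+1)-partition therefore changes A by a purely
combinatorial amount — the pair mass of whichever cluster is split,
times the depth of the consensus drop — regardless of whether the split
reflects real structure. For n = 60 in three balanced clusters this
structural increment is ≈ 0.077 at K = 4, ≈ 0.068 at K = 5 and ≈ 0.045
at K = 6, while a genuine cluster boundary contributes several times
more (Δ(3) ≈ 0.45–0.50 on the synthetic cohorts). A threshold of 0.05
sits *inside* the structural band and systematically over-selects K; the
package default is δ_min = 0.10, which separates the two regimes with a
comfortable margin on both sides. δ_min is a config parameter of
`cdf_delta_area()`.

A known limitation follows from the same arithmetic: on data with *no*
cluster structure, arbitrary PAM partitions still shift the mean
consensus combinatorially, so the rule does not gracefully return K = 2
on null data. The benign null behavior sometimes reported for
delta-area plots comes from hierarchical consensus clustering, which
peels outlier singletons at higher K; with PAM the rule should only be
trusted in the presence of structure, which is how it is used here.

**IGP.** Cluster reproducibility across cohorts uses the in-group
proportion: discovery centroids (feature-wise means of the
rank-transformed matrix) classify each validation specimen to its
nearest centroid under the same Spearman distance, and IGP(g) is the
share of specimens classified to g whose nearest validation neighbor is
also classified to g. The original IGP null rotates centroids randomly;
we substitute a label-permutation null (shuffle the classified labels,
p(g) = (1 + #{IGP_perm ≥ IGP_obs})/(N+1)), which is assumption-light and
keeps p in (0, 1]. When two cohorts are clustered independently their
label sets are aligned by greedy maximal centroid rank-correlation
(`match_clusters()`), and the mapping is reported rather than applied
silently.

## The statistical stage

Feature–subtype association uses one-way ANOVA (equal-variance F) and
Kruskal–Wallis (midrank ties) per feature, each Benjamini–Hochberg
corrected across all 246 features; features constant across specimens
take the p = 1 convention and are flagged. Categorical association uses
the Pearson chi-squared test with Yates continuity correction applied
exactly for 2×2 tables (the default that reproduces the published
discovery-vs-validation sex comparison), with "unknown" levels dropped
before tabulation. Survival uses the Kaplan–Meier product-limit
estimator, the log-rank test, and Cox proportional-hazards models with
Breslow tie handling (Efron available), dummy-coded against explicit
baselines (subtype 1, pT1, G1, female) and Wald 95% intervals. All of
these call the standard R machinery (`stats`, `survival`) behind the
package API; nothing here is re-derived.

## The synthetic cohort generator

`simulate_cohort()` draws, per specimen: a typed point pattern, elliptical
nuclei, an optional rendered patch, and a clinical record. Default
conditions (all configurable):

| parameter | S1 | S2 | S3 | units |
|---|---|---|---|---|
| tumor process | Poisson | Thomas | Thomas | |
| tumor intensity κ (or parent κ) | 1.0 | 0.03 | 0.06 | per 10⁴ px² |
| offspring per parent µ / spread σ | — | 75 / 80 px | 40 / 150 px | |
| lymphocyte base intensity λ₀ | 0.12 | 0.3 | 0.3 | per 10⁴ px² |
| colocalization α (bandwidth 60 px) | +4 | −2 | 0 | |
| tumor nucleus median diameter | 24 | 28 | 31 | px |
| exponential hazard | 0.015 | 0.03 | 0.03 | per month |

Lymphocytes follow an inhomogeneous Poisson process with intensity
λ(x) = λ₀ · max(0.05, 1 + α Σᵢ exp(−|x − tᵢ|²/2h²)) over tumor cells tᵢ
— one parameter covers attraction (α > 0) and exclusion (α < 0), with
the 0.05 floor keeping the intensity nonnegative; realization is by
thinning with a safety-margined intensity bound. Each specimen's spec is
jittered by log-normal multipliers (sd 0.2 on intensities, 0.03 on the
size median), so subtypes are realistic continua rather than ideal
points — matching the wide within-subtype spread seen in real cohorts
and giving higher-K consensus splits nothing stable to latch onto.
Survival is exponential with the subtype hazard under independent
uniform censoring on [0, 120] months.

Together the three specs plant the qualitative subtype signature the
pipeline is designed to recover: S1 sparse, spatially homogeneous tumor
growth with dense, colocalized lymphocyte infiltration and the best
prognosis; S2 dense compact tumor clusters with immune exclusion; S3
loose broad clusters with the largest nuclei; S2/S3 share a doubled
hazard.

Nuclei are 32-vertex ellipses (log-normal equivalent diameter,
eccentricity uniform on [0, 0.8] for tumor, orientation uniform;
lymphocytes small and round, other cells intermediate — class-level
constants). A 32-gon underestimates the continuous ellipse's diameter by
a factor √(sin θ/θ), θ = 2π/32, about 0.3%. Overlaps are allowed.
Rendering uses an eosin-pink background (230, 180, 200), hematoxylin
purple tumor nuclei (90, 60, 140), dark compact lymphocytes
(50, 40, 110); one Gaussian noise field (sd 8) is shared by the three
channels, and nucleus interiors get smooth texture noise (4-px grid,
bilinear, sd 12). Z-order matters and is fixed: other cells, then
lymphocytes, then tumor nuclei on top, so a tumor mask reads its own
stain even where cells overlap — without this, tumor intensity features
leak information about local lymphocyte density, which is a rendering
artifact rather than biology.

Default geometry: 2000×2000 px patches (about 1,000–1,800 cells per
specimen), core = rectangle eroded by 300 px, periphery = outer 200-px
band, leaving a deliberate unassigned gap between them. Cohorts
regenerate byte-identically from the master seed; rendered patches are
not kept in memory but re-rendered on demand by replaying each
specimen's recorded RNG state.

**What the generator does not emulate** — and hence what green tests do
not establish about real slides: stain variation and batch effects,
segmentation and classification errors in the cell map, realistic
nuclear chromatin texture, irregular (non-elliptical) nuclear shapes,
tissue-level architecture (vessels, stroma, necrosis), non-rectangular
hand-drawn ROIs, and non-proportional hazards. Passing the planted
recovery tests shows the pipeline's machinery is correct and calibrated,
not that three subtypes exist in any particular tissue.

## Numerical choices and degenerate inputs

* Population moments guard against floating-point dust: a standard
  deviation below 10⁻⁹·(|mean|+1) is treated as exactly 0, and skewness /
  kurtosis of constant input are 0 by definition.
* GLCM directions with no valid pixel pairs are dropped from the
  average; masks under 4 pixels yield an all-missing texture row; empty
  masks an all-missing descriptor row. Patient aggregation excludes
  missing values pairwise and reports the count.
* Percentiles follow R's type-7 definition everywhere (C++ kernels
  included), so values agree with `quantile()` exactly.
* Quadrat CV is undefined (NA) when the mean count is 0; Morisita
  requires ≥ 2 points; nearest-neighbor distance requires ≥ 2 points —
  all logged, not errors.
* PAM ties (equidistant points, equal-gain candidates) resolve to the
  lowest index; consensus results are bit-reproducible from the seed.
* The renderer refuses patches beyond 4096² px and the point-process
  simulator refuses expected counts above 10⁵ (desk-scale guards).

## Problem sizes

The package's own analyses and tests run at desk scale by choice: 60
specimens (20 per subtype) per cohort, B = 200–1,000 consensus
replicates, 20 seeded replicate cohorts for the planted-recovery study,
200 patterns for the CSR calibration, 500 instances for the PAM oracle,
n = 500 with 40 replicates for the Cox recovery study. The consensus
default B = 10,000 matches the published protocol and is practical for a
single real cohort.
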