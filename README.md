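# hespat

Single-cell spatial phenotyping of hematoxylin-and-eosin (H&E) tissue
sections, and discovery of prognostic *imaging subtypes*.

Modern segmentation models can turn a whole-slide H&E image into a typed
single-cell map: every nucleus outlined and classified as tumor cell,
lymphocyte, or other non-malignant cell. hespat starts from that map
(plus three pathologist regions of interest: whole tumor, tumor core,
tumor periphery) and asks what the *spatial organization* of tumor and
immune cells says about a patient. It is aimed at computational
pathology and tumor-microenvironment researchers who want a transparent,
fully testable reference implementation of this analysis in R.

The pipeline:

1. **246-feature spatial phenotype per patient.** Nuclear morphometry
   (e.g. equivalent diameter 2√(A/π)), intensity histogram, gray-level
   co-occurrence (Haralick) texture and color descriptors of tumor
   nuclei, aggregated as mean and SD over the whole tumor (150
   features); quadrat-based density and spatial-heterogeneity statistics
   per cell class in core and periphery, including the Morisita index
   (28); a tumor–lymphocyte **spatial interaction matrix** — for each
   tumor nucleus, the number of tumor and lymphocyte nuclei within 50 or
   100 px — summarized by 8 statistics per class, radius and region
   (64); and 4 composite counts. Every feature is documented in a
   machine-readable registry.
2. **Subtype discovery by consensus clustering**: partition around
   medoids (PAM) on the Spearman distance d(i,j) = 1 − ρ_s of the
   rank-transformed feature matrix, under repeated resampling of 80% of
   features and specimens; the cluster number K is selected by the CDF
   delta-area rule and cluster reproducibility across cohorts is
   quantified with the in-group proportion (IGP) statistic.
3. **Association and survival stage**: per-feature ANOVA and
   Kruskal–Wallis tests with Benjamini–Hochberg correction, chi-squared
   tests against categorical labels, Kaplan–Meier / log-rank, and
   multivariable Cox regression (Breslow ties).
4. **A synthetic H&E cohort generator** that plants three subtypes with
   distinct tumor density, spatial clustering, lymphocyte infiltration /
   colocalization, nuclear size and survival hazard, rendered to
   H&E-like image patches — so the whole pipeline runs and is tested
   without any external data.

See `vignettes/imaging-subtypes.Rmd` for the full methods account, and
`analysis/01_simulate.R` … `analysis/05_survival.R` for the staged
analysis over a simulated cohort.

## A worked example

Simulate a small cohort (5 specimens per planted subtype), extract the
phenotype, and rediscover the subtypes:

```r
library(hespat)

co <- simulate_cohort(n_per_subtype = c(5, 5, 5), seed = 7)
X  <- extract_cohort(co$maps, co$image_of)   # 15 x 246 feature matrix

round(X[1:3, c("tumor_density_CT", "tumor_equivalent_diameter_mean",
               "tumor_lymph_relation_mean_CT")], 2)
#>       tumor_density_CT tumor_equivalent_diameter_mean tumor_lymph_relation_mean_CT
#> S1_01             1.06                          24.96                         1.18
#> S1_02             1.05                          24.30                         0.63
#> S1_03             0.99                          23.16                         0.83
```

`tumor_density_CT` is tumor cells per 10⁴ px² of the tumor core,
`tumor_equivalent_diameter_mean` the mean nuclear equivalent diameter in
px, and `tumor_lymph_relation_mean_CT` the mean number of lymphocytes
within 50 px of each tumor cell in the core — the single most
interpretable immune-infiltration feature.

```r
cc <- consensus_cluster(X, k_range = 2:5, B = 200, seed = 7)
cc
#> <consensus_result> n = 15  B = 200  p_feature = 0.8
#>   K: 2 3 4 5
#>   A(K): 0.481 0.714 0.775 0.827
#>   delta(K): 0.481 0.484 0.086 0.067
#>   optimal K: 3

table(recovered = cc$labels[["3"]], planted = co$truth$subtype)
#>          planted
#> recovered S1 S2 S3
#>         1  5  0  0
#>         2  0  5  0
#>         3  0  0  5
```

The relative CDF-area increments Δ(K) collapse after K = 3 (0.48 →
0.086), so the delta-area rule selects three clusters, and they
reproduce the planted subtypes exactly. The survival stage then attaches
the subtypes to the clinical table:

```r
cl <- co$clinical
cl$subtype <- as.character(cc$labels[["3"]])
km <- km_logrank(cl, cl$subtype)
sprintf("log-rank: chi2 = %.2f (df %d), p = %.3f", km$statistic, km$df, km$p)
#> "log-rank: chi2 = 4.18 (df 2), p = 0.124"
```

(With only 15 patients the planted hazard difference is visible but not
significant; the `analysis/` scripts run the full 60-specimen design.)

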