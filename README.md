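# eoatlas

Statistical toolkit for multi-donor, multi-condition single-cell RNA-seq
atlases of the esophageal mucosa in eosinophilic esophagitis (EoE) — and,
more generally, for any tissue atlas where biopsies from several donors and
disease states are profiled together and the questions are: *which cell
types shift in abundance, which genes shift within a cell type, which
ligand–receptor axes connect cell types, and how do labels transfer to new
data?*

Because the patient datasets these methods target are access-restricted,
the package is built around a fully specified generative simulator
(`generate_atlas()`) with known ground truth — planted composition shifts,
differential expression, per-sample ambient contamination,
chemistry-dependent mitochondrial load, and planted ligand–receptor axes —
so every estimator can be validated by recovery of planted structure.

## What's inside

| Analysis | Functions | Core model |
|---|---|---|
| Synthetic atlas with truth | `atlas_config()`, `generate_atlas()`, `write_atlas()`/`read_atlas()` | Dirichlet-multinomial composition, multinomial counts given log-normal depth, UMI-level ambient mixing |
| QC + normalization | `filter_cells()`, `lognorm()`, `pseudobulk_sum()`/`pseudobulk_mean()` | >500 UMIs, chemistry-specific mito ceiling (25% v2 / 40% v3); log TP10K |
| Differential abundance | `nb_abundance()` | per-type NB regression, `log mu = X beta + log N_s`, Wald + BH |
| Compositional geometry | `clr_transform()`, `composition_pca()` | centered log-ratio with half-count zero replacement |
| Rank-based abundance | `quantile_rank_regression()` | quantile-normalized proportions, OLS t-tests |
| Global composition test | `permanova_composition()` | PERMANOVA, Euclidean distance, sequential SS |
| Activity association | `activity_correlation()` | Spearman rho, `t = rho*sqrt((n-2)/(1-rho^2))` |
| Co-variation clusters | `proportion_correlation_clusters()` | Pearson r, WPGMA on `1 - r` |
| Subset-condition tests | `condition_proportion_fisher()` | exact two-tailed Fisher + BH |
| Composition feature selection | `lasso_fraction_predictor()` | L1 regression, exact LOOCV penalty choice |
| Differential expression | `de_logistic()`, `ambient_filter()`, `lfc_concordance()` | logistic LRT with covariates; majority-downregulation ambient filter |
| Cell–cell interactions | `subset_shares()`, `interaction_strength()`, `rank_partners()`, `per_condition_interactions()` | UMI-share scores, geometric-mean complex weights, top-k (=10) strength |
| Reference mapping | `fit_latent()`, `classify_knn()` | NCA to a latent space, kNN (k = 11) label transfer |
| Signatures & programs | `score_signature()`, `nmf_programs()`, `expressed_gene_screen()`, `risk_modules()` | binned-control scores; NMF; >=25% detection screen; Ward.D2 on sqrt pseudo-bulk |

Results come back as tibbles (or small classed objects with `tidy()`,
`glance()` and `autoplot()` methods), so everything chains with the pipe.
A 30-pair demo ligand–receptor catalog with multi-subunit complexes ships
in `inst/extdata/lr_demo_catalog.csv`.

## Worked example

```r
library(eoatlas)

sim   <- generate_atlas(atlas_config(seed = 1L))  # 22 donors, 37 biopsies
atlas <- filter_cells(sim$atlas)                  # chemistry-aware QC
atlas
#> <eoe_atlas> 11100 cells x 310 genes, 37 samples, 12 cell types
#>   conditions: active=14, healthy=12, remission=11

comp   <- composition_table(atlas)
shifts <- nb_abundance(comp)
dplyr::filter(shifts, contrast == "active_vs_healthy", fdr < 0.05)
#> # A tibble: 7 x 9
#>   cell_type      contrast estimate    se statistic  p.value theta model      fdr
#> 1 eosinophil     active_…    2.04  0.207      9.85 6.71e-23  6.89 nb    8.05e-22
#> 2 mac_folr2      active_…   -1.34  0.179     -7.45 9.28e-14 10.4  nb    5.57e-13
#> 3 apical         active_…   -1.01  0.150     -6.70 2.07e-11 12.9  nb    8.30e-11
#> 4 fibroblast_il… active_…    1.13  0.209      5.40 6.75e- 8  5.49 nb    2.03e- 7
#> ...
```

The `estimate` column is the natural-log fold change of the cell type's
expected count in active disease versus healthy, at fixed per-biopsy cell
totals (the offset): the planted eosinophil enrichment (`log 8 ≈ 2.08`) is
recovered at `2.04 ± 0.21`, the planted apical depletion (`-log 2 ≈
-0.69`) at `-1.01 ± 0.15`, each with its Wald test and BH FDR across the
12 cell types.

Ligand–receptor ranking on the same atlas finds the planted Th2 →
fibroblast axis:

```r
catalog <- lr_catalog(c("th2_fibro_axis", "mast_endo_axis"),
                      list("G0201", "G0204"),
                      list(c("G0202", "G0203"), "G0205"))
rank_partners(interaction_strength(subset_shares(atlas), catalog, k = 10),
              cell_type = "th2", top_n = 3)
#> # A tibble: 3 x 6
#>   cell_type partner     strength  rank      z degenerate_z
#> 1 th2       fibroblast    0.885      1  1.15  FALSE
#> 2 th2       endothelial   0.0108     2 -0.577 FALSE
#> 3 th2       cd8_t         0.0107     3 -0.578 FALSE
```

Strength is the sum of the top k = 10 directed pair scores, each the
product of the ligand complex's UMI share in the sender and the receptor
complex's (geometric-mean) share in the receiver — so 0.885 means the
planted axis is near the maximum attainable score of 1.

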