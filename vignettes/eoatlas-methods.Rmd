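---
title: "Models and methods behind eoatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eoatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eoatlas)
```

eoatlas packages the statistical machinery used to analyze a multi-donor
single-cell atlas of the esophageal mucosa in eosinophilic esophagitis
(EoE): which cell types change in abundance across disease states, which
genes change within each cell type, which ligand–receptor axes connect cell
types, how to transfer atlas labels onto new data, and how candidate risk
genes organize into modules. Because the patient data such methods are
usually applied to are access-restricted, the package ships a generative
simulator with known ground truth; every claim the test suite makes is a
claim about recovery of planted structure or about mathematical invariants,
not about any patient dataset.

## The synthetic atlas generator

`generate_atlas()` draws data from an explicit hierarchical model:

* **Design.** 22 donors contribute 37 biopsies (14 active, 11 remission, 12
  healthy), each donor one or two regions, with three 10x chemistry batches
  (7 donors v2, 9 v3, 6 v3-dual) interleaved across conditions so chemistry
  is correlated with, but not confounded with, disease. Clinical activity
  (eosinophils/HPF, EREFS) tracks condition.
* **Composition.** Each biopsy's cell-type composition is Dirichlet with
  concentration `base * exp(condition effects)`; cells are allocated
  multinomially. Per-sample spike-ins (`composition_overrides`) can enrich a
  single biopsy, emulating the strong patient-to-patient heterogeneity of
  granulocyte infiltration.
* **Expression.** Each cell type has a gamma-baseline mean profile with
  dedicated marker genes; planted differential expression multiplies a
  gene's rate in one (cell type, condition) stratum by `2^lfc`. Library
  sizes are log-normal, and gene counts are multinomial given the library
  size, so the total per cell is exactly its drawn depth — which makes
  library-size offsets and TP10K normalization downstream exactly correct
  rather than approximately so.
* **Ambient RNA.** Every UMI is switched, with probability
  `ambient_fraction`, to a draw from the *sample's own* soup — the
  composition-weighted average of the type profiles in that biopsy. Ambient
  contamination therefore varies across samples with composition, which is
  the phenomenon the ambient DE filter exploits; a dataset-global soup
  would make the filter untestable by construction.
* **Mitochondrial load.** `MT-` prefixed genes receive a chemistry-dependent
  share of each cell's profile (8% for v2, 16% for v3 by default), so QC
  operates on gene-name conventions exactly as real pipelines do.

The default dimensions (12 cell types, 300 genes, 300 cells per biopsy) are
the package's own desk-scale choice: large enough that every downstream
method has signal, small enough that hundreds of replicate atlases can be
simulated in test runs. The donor/biopsy/chemistry design is not scaled
down. What the simulator deliberately omits: doublets, cell-cycle
structure, batch effects beyond the mitochondrial load, and any
gene–gene correlation beyond cell-type identity. Passing recovery tests on
these data therefore demonstrates correctness of the estimators under the
stated model, not robustness to every artifact of real droplet data.

## Quality control and normalization

Cells are retained when total UMIs exceed 500 (strictly) and the
mitochondrial fraction is strictly below 25% (v2 chemistry) or 40% (v3
chemistries, which systematically run higher). Both thresholds are
parameters of `qc_thresholds()`. Normalization is log TP10K:
`ln(1 + 1e4 * count / total)`. Pseudo-bulk comes in the sum variant
(aggregate raw counts, then normalize the aggregate — used for profile
comparison) and the mean variant (per-gene mean of raw counts — used for
risk-gene modules); the mean variant can optionally average per-cell
normalized values instead, since the aggregation scale is genuinely
ambiguous for that analysis.

## Composition statistics

`nb_abundance()` fits, per cell type, a negative-binomial regression of the
per-biopsy cell count with `log(total analyzed cells)` as offset and
condition plus technical covariates as predictors, Wald tests on the
condition contrasts and BH FDR across cell types. Dispersion is estimated
by maximum likelihood (`MASS::glm.nb`); fits that fail fall back to Poisson
and are flagged. Two small-sample behaviors are worth knowing, and both are
quantified by the acceptance simulations rather than hidden: with ~30
biopsies the Wald interval under-covers mildly (the model standard error
underestimates the empirical spread by ~10% when the between-sample
composition noise is as skewed as a log-Gamma(1) random effect), and each
nuisance covariate added at this sample size inflates the Wald rejection
rate slightly because the reference distribution is normal rather than t.

The compositional view uses the centered log-ratio transform (zeros
replaced by 0.5 before closure — the half-count multiplicative replacement;
the pseudo-count is a parameter), followed by centered PCA with a
deterministic sign convention. The nonparametric companion
`quantile_rank_regression()` quantile-normalizes each cell type's
proportions across samples to the common distribution of mean order
statistics, then runs OLS with t-tests; it trades efficiency for robustness
and shows slightly lower power than the NB model in the planted-effect
simulations, consistent with its rank character. PERMANOVA
(`permanova_composition()`, via `vegan::adonis2`) partitions Euclidean
distances between quantile-normalized composition profiles with sequential
sums of squares; the default 10^4 permutations is a desk-scale choice and a
parameter. Note that the smallest attainable p-value is limited not only by
`1/(1+n_perm)` but by the chance of drawing a group-preserving permutation,
which is non-negligible below ~8 samples per group.

Association with clinical activity uses Spearman correlation with the
t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`; cell-type co-variation
uses Pearson correlation of proportions clustered with WPGMA (Mcquitty)
linkage on `1 - r`; subset-by-condition contingency tables get two-tailed
Fisher tests with BH adjustment, and tables with an empty margin are
flagged degenerate with p = 1 by convention. `lasso_fraction_predictor()`
selects composition features predicting a target fraction by L1-penalized
regression with the penalty chosen by exact leave-one-out cross-validation
(`cv.glmnet`, `nfolds = n`, ungrouped), reporting the nonzero coefficients
and a slope test of leave-one-out predictions against observations.

## Differential expression and the ambient filter

`de_logistic()` follows the logistic-regression formulation: for each gene,
group membership is modeled on the gene's normalized expression plus
covariates (log2 detected genes per cell, treatment, region, chemistry),
and compared by likelihood ratio against the covariate-only null. Fold
changes are ratios of group means of `expm1(lognorm)` with a `1e-9`
pseudo-count; both Bonferroni and BH adjustments are reported, and the
significance convention is adjusted p < 0.001 with fold change > 1.5.
Quasi-separated genes are refit with a small ridge penalty (`lambda = 1e-3`
on all but the intercept) applied to both null and alternative so the LRT
remains comparable; such genes are flagged.

The ambient filter addresses a specific artifact: a pooled, cell-weighted
test can call a gene upregulated when the signal comes from ambient
contamination in a minority of samples (typically one large, heavily
infiltrated biopsy), even though most focal samples individually show the
gene *down* relative to the comparison group. For each upregulated gene the
filter compares, in each of the M focal samples, the sample's mean
normalized expression within the cell type against the pooled
comparison-group mean, and removes the gene when strictly more than M/2
samples are negative. Ties at exactly M/2 retain the gene (conservative
reading of "most"); samples with no cells of the type are excluded from M
with a warning. The per-sample baseline is the pooled other-condition mean;
a per-sample-pair variant would require matched samples the design does not
guarantee.

## Ligand–receptor interaction scoring

The score is built from raw UMI shares: `s[g, subset]` is the fraction of
gene g's UMIs found in that subset, so shares sum to one over subsets and
abundant subsets naturally dominate — which is the intended behavior, since
signaling mass matters. A multi-subunit complex takes the geometric mean of
its subunits' shares (any absent subunit zeroes the complex), a directed
pair score is ligand weight in the sender times receptor weight in the
receiver, and the interaction strength of an ordered cell-type pair is the
sum of its top k = 10 pair scores, damping the long tail of background
pairs. Subsets under 10 cells are excluded from the share computation by
default. Scores are directed (sender, receiver); a symmetrized sum is
available. Autocrine pairs are included. Partner rankings break ties
lexicographically and report row z-scores using the sample standard
deviation (a single partner gets z = 0 and a degeneracy flag). Robustness
of the top-3 partners to k in {5, 10, 15} is assessed per cell type: each
cell type's top-3 set is compared across the three k values, and the
stability rate aggregates over cell types and replicate atlases.

## Reference mapping

`fit_latent()` learns a linear projection to a low-dimensional latent space
by neighborhood component analysis: starting from a PCA initialization on
standardized log-normalized expression of the top highly variable genes, it
maximizes the softmax-NCA objective (expected stochastic nearest-neighbor
label agreement) with L-BFGS for a bounded number of iterations. The
preprocessing recipe — gene set, per-gene reference mean and standard
deviation — is frozen into the model and applied unchanged to queries;
query genes absent from the model are imputed at the reference mean
(z = 0), and classification refuses to run below 50% gene overlap.
`classify_knn()` performs exact Euclidean k-nearest-neighbor voting
(k = 11) in the latent space with ties broken by summed inverse distance
and the vote fraction reported as confidence. On held-out synthetic cells
the NCA map at default settings classifies essentially perfectly and never
falls below the raw-PCA baseline at equal dimension.

## Signatures, programs and risk-gene modules

Signature scores use the binned-control scheme: genes are binned (25 bins)
by dataset-average expression, 100 control genes are drawn per signature
gene from its bin, and the score is the per-cell difference between
signature and control means — so a signature indistinguishable from its
expression-matched controls scores near zero, and adding a constant to all
normalized values cancels exactly. Gene programs come from non-negative
matrix factorization of the normalized expression of a cell family
(Lee–Seung multiplicative updates, Frobenius loss, seeded random
initialization); the reconstruction-error trace is monotone by
construction and exposed for rank selection, with the default rank 6 a
starting point rather than an estimate. The risk-gene analysis first
requires a gene to be detected in at least 25% of cells of some subset
(inclusive boundary), then clusters the square root of mean-variant
pseudo-bulk profiles across subsets with Ward.D2 linkage; the default tree
cut at half the maximum merge height is a convention and `k` can be forced.

## Numerical and reproducibility choices

All simulation entry points take one master seed; per-sample and per-cell
streams are derived by fixed integer hashing, so regenerating any one
sample is stable regardless of how many others are drawn. Serialization
writes counts as integer Matrix Market plus TSV/CSV sidecars and the truth
registry as JSON with 17 significant digits, which round-trips IEEE doubles
exactly. Problem sizes used by the acceptance checks: 50 oracle instances
(20 genes, 4 subsets, 10 pairs), 50 replicate atlases for k-robustness, 200
replicates for abundance recovery and for the PERMANOVA null, 100 for the
power comparison and for the ambient filter, one default atlas (37
biopsies, ~11,000 cells) for reference mapping. These sizes are the
package's own reporting choices and are stated here so the numbers in the
acceptance report can be read in context.

## Known limitations

The generator's independence assumptions make several real-data failure
modes invisible (doublets, cell-cycle, per-gene batch effects, UMI
saturation). The NB Wald intervals under-cover by a few percent at 30
samples, as quantified above; a parametric bootstrap would fix this but is
out of scope. The interaction score ranks, it does not test: no permutation
null is attached to interaction strengths, by design. NCA is optimized for
a bounded number of iterations with no convergence guarantee beyond the
flag it reports.
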