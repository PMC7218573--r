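# omixplain

How much of a dairy cow's milk protein yield (MPY, kg/day) can each omics
layer of her biology explain? `omixplain` answers that question for a
multi-omics cohort — rumen microbial species, microbial KEGG functions,
rumen metabolites, serum metabolites — and runs the cohort analyses that
surround it. It is aimed at researchers partitioning host-trait variance
over microbiome and metabolome layers ("microbiability" and its
generalization) and at anyone needing the accompanying screening machinery
on sample-by-feature tables.

## The model

For each omics layer separately, a single-random-effect linear mixed model
is fitted by REML:

    y = mu + parity_j + dim_k + u + e,
    u ~ N(0, A sigma2_a),   e ~ N(0, I sigma2_e),
    A = Z Z' / q

where `y` is MPY, `Z` the column-standardized `n x q` feature matrix of the
layer, and `A` its relationship matrix (the microbial **M**, functional
**K**, rumen-metabolome **R** or serum-metabolome **S** kernel). The layer's
**omics-explainability** is `sigma2_a / (sigma2_a + sigma2_e)`, and the
random effect is tested with a boundary-corrected likelihood-ratio test
(`0.5*chi2_0 + 0.5*chi2_1` null). The fit eigendecomposes `A` once and
maximizes the profiled restricted likelihood over the variance share in one
dimension.

Around that core the package provides: the feature-retention rules
(taxa > 0.1% relative abundance in ≥ 50% of animals per group; functions
cpm > 5; metabolite peaks by presence / RSD ≤ 30% / spectral similarity ≥
200), Bray-Curtis distances and PCoA, MPY-metabotype screening by Spearman
correlation with PERMANOVA-based microbiome-responsiveness calls under BH
FDR, Wilcoxon / LDA-effect-size / Welch-t + PLS-DA-VIP differential-feature
procedures, thresholded correlation networks, a deterministic
config-driven pipeline, and a synthetic multi-omics cohort generator with
planted ground truth.

## Worked example

Estimate the explainability of a taxa layer that truly accounts for 50% of
the phenotypic variance in a 300-animal synthetic cohort:

```r
library(omixplain)

cohort <- generate_cohort(seed = 1, n_animals = 300, n_hh = 150)
layer  <- generate_omics_layer(seed = 2, cohort, "taxa", n_features = 100)
z      <- zscore_standardize(layer)
pheno  <- generate_phenotype_from_layers(seed = 3, cohort, list(taxa = z),
                                         true_fractions = c(taxa = 0.5),
                                         scale_realized = TRUE)
fit <- reml_fit(pheno$mpy, pheno[, c("parity", "dim")],
                build_relationship_matrix(z))
fit
#> <VarianceComponentFit> layer=taxa n=300
#>   sigma2_a=0.3861 sigma2_e=0.568 explainability=40.47% LRT p=1.69e-12
```

The single-cohort estimate (40.5%) sits within the design's sampling noise
(sd ≈ 8 points) of the planted 50%, and the LRT rejects the no-effect null
decisively; across 25 replicate cohorts the mean estimate is 48.8%.

The full analysis over a 16-animal cohort — the emulated study's design
size — lives in `analysis/01…05`, each a short script that reads the
previous step's TSVs and prints what it found:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort: 16 animals | 7 HH / 9 LL
Rscript analysis/02_explainability.R    # per-layer REML report
Rscript analysis/03_metabotypes.R       # e.g. "rumen_metabolome: 16 MPY-associated metabotypes ..."
Rscript analysis/04_differential.R      # e.g. "function, LDA score > 2 & p < 0.05: 18 features"
Rscript analysis/05_ordination_networks.R
```

At n = 16 the variance-component estimates are essentially uninformative
(they often pin to 0% or 100% with LRT p near 1) — the scripts show this
honestly; see the vignette for why and for the cohort sizes at which the
estimator is calibrated.

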