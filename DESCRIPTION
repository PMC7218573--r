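Package: omixplain
Title: Omics-Explainability of Host Phenotypes from Multi-Omics Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the proportion of variance in a host phenotype (milk
    protein yield) explained by each omics layer of a multi-omics cohort
    (rumen microbial taxa, KEGG functions, rumen and serum metabolomes) via
    single-random-effect linear mixed models with omics-derived relationship
    matrices, fitted by restricted maximum likelihood through an
    eigendecomposition of the kernel. Also provides the surrounding cohort
    analyses: feature-retention filters, Bray-Curtis ordination,
    phenotype-associated metabotype screening with PERMANOVA-based
    microbiome-responsiveness calls, Wilcoxon, LDA-effect-size and t-test+VIP
    differential-feature procedures, thresholded Spearman correlation
    networks, and a synthetic multi-omics cohort generator with known planted
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
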