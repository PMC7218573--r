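#!/usr/bin/env Rscript
# Community ordination and cross-omics correlation networks: Bray-Curtis
# PCoA of the filtered taxa, and thresholded Spearman networks (|rho| > 0.5,
# p < 0.05) between taxa and each metabolome.

suppressPackageStartupMessages(library(omixplain))

cohort_dir <- "results/cohort"
pheno <- read_phenotype_table(file.path(cohort_dir, "phenotype.tsv"))
groups <- stats::setNames(pheno$group, pheno$sample_id)

taxa <- filter_prevalent_features(
  read_feature_table(file.path(cohort_dir, "taxa.tsv"), "taxa", "relative"),
  groups, 0.001, 0.5)
d <- bray_curtis(taxa)
ord <- pcoa(d, k = 2)
cat(sprintf("PCoA axes 1-2 explain %.1f%% and %.1f%% of the Bray-Curtis inertia\n",
            100 * ord$proportion_explained[1], 100 * ord$proportion_explained[2]))
utils::write.table(
  data.frame(sample_id = rownames(ord$coordinates), ord$coordinates,
             group = pheno$group),
  "results/pcoa_taxa.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

for (nm in c("rumen_metabolome", "serum_metabolome")) {
  met <- filter_metabolite_peaks(read_feature_table(
    file.path(cohort_dir, paste0(nm, ".tsv")), nm, "intensity",
    feature_meta = file.path(cohort_dir, paste0(nm, "_meta.tsv"))))
  net <- build_correlation_network(taxa, met, r_threshold = 0.5, alpha = 0.05)
  cat(sprintf("taxa x %s: %d edges kept (|rho| > 0.5, p < 0.05)\n",
              nm, nrow(net)))
  utils::write.table(net, paste0("results/network_taxa_", nm, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote results/pcoa_taxa.tsv and results/network_taxa_*.tsv\n")
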