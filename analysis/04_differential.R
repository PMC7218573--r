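#!/usr/bin/env Rscript
# Differential features between HH and LL cows, one procedure per layer as
# in the emulated workflow: Wilcoxon + BH FDR and the LDA-effect-size score
# for taxa, the LDA score for functions, Welch t + BH FDR + PLS-DA VIP for
# the two metabolomes.

suppressPackageStartupMessages(library(omixplain))

cohort_dir <- "results/cohort"
pheno <- read_phenotype_table(file.path(cohort_dir, "phenotype.tsv"))
groups <- stats::setNames(pheno$group, pheno$sample_id)

taxa <- filter_prevalent_features(
  read_feature_table(file.path(cohort_dir, "taxa.tsv"), "taxa", "relative"),
  groups, 0.001, 0.5)
fn <- filter_prevalent_features(
  read_feature_table(file.path(cohort_dir, "function.tsv"), "function", "cpm"),
  groups, 5, 0.5)

wil <- do.call(rbind, lapply(seq_len(ncol(taxa$values)), function(j) {
  sp <- split(taxa$values[, j], groups[rownames(taxa$values)])
  w <- wilcoxon_rank_sum(sp[[1]], sp[[2]])
  data.frame(feature_id = feature_ids(taxa)[j], rank_sum = w$rank_sum, p = w$p)
}))
wil$q_bh <- bh_fdr(wil$p)
cat("taxa, Wilcoxon + BH:", sum(wil$q_bh < 0.05), "of", nrow(wil),
    "species differential at FDR < 0.05\n")
utils::write.table(wil, "results/differential_taxa_wilcoxon.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (nm in c("taxa", "function")) {
  t1 <- if (nm == "taxa") taxa else fn
  lef <- lefse_style_score(t1, groups)
  cat(nm, ", LDA score > 2 & p < 0.05:", sum(lef$significant), "features (",
      sum(lef$significant & lef$effect_direction == "HH"), "HH-enriched )\n")
  utils::write.table(lef, paste0("results/differential_", nm, "_lefse.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

for (nm in c("rumen_metabolome", "serum_metabolome")) {
  met <- filter_metabolite_peaks(read_feature_table(
    file.path(cohort_dir, paste0(nm, ".tsv")), nm, "intensity",
    feature_meta = file.path(cohort_dir, paste0(nm, "_meta.tsv"))))
  res <- suppressWarnings(differential_metabolites(met, groups))
  cat(nm, ", t+FDR+VIP:", sum(res$significant), "differential metabolites\n")
  utils::write.table(res, paste0("results/differential_", nm, "_ttest_vip.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote results/differential_*.tsv\n")
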