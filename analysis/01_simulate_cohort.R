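#!/usr/bin/env Rscript
# Generate the synthetic 16-cow multi-omics cohort used by the downstream
# analysis scripts: 7 high-MPY (HH) and 9 low-MPY (LL) animals, a
# compositional rumen taxa table dominated by one genus block, a cpm
# function table, 263 rumen and 177 serum metabolite intensity tables, and
# an MPY phenotype assembled from the layers with the default planted
# variance fractions. Everything is written as plain TSV plus a truth JSON.

suppressPackageStartupMessages(library(omixplain))

seed <- 20260
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_multiomics(seed)

utils::write.table(as.data.frame(sim$phenotype),
                   file.path(out, "phenotype.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
for (nm in names(sim$layers)) {
  write_feature_table(sim$layers[[nm]], file.path(out, paste0(nm, ".tsv")))
  if (!is.null(sim$layers[[nm]]$feature_meta))
    utils::write.table(sim$layers[[nm]]$feature_meta,
                       file.path(out, paste0(nm, "_meta.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
}
jsonlite::write_json(sim$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("cohort:", nrow(sim$phenotype), "animals |",
    sum(sim$phenotype$group == "HH"), "HH /",
    sum(sim$phenotype$group == "LL"), "LL\n")
cat("MPY range:", paste(round(range(sim$phenotype$mpy), 2), collapse = " - "),
    "kg/day\n")
for (nm in names(sim$layers))
  cat(sprintf("%-17s %4d features (%s)\n", nm, ncol(sim$layers[[nm]]$values),
              sim$layers[[nm]]$value_kind))
cat("planted fractions:",
    paste(names(sim$truth$true_fractions),
          round(unlist(sim$truth$true_fractions), 3),
          sep = "=", collapse = "  "), "\n")
cat("wrote", out, "\n")
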