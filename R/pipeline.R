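#' Default analysis configuration
#'
#' All thresholds of the workflow in one place: taxa retained at relative
#' abundance > 0.1% in >= 50% of animals per group; functions at cpm > 5 in
#' >= 50% per group; metabolite peaks present in >= 50% of samples with
#' RSD <= 30% and spectral similarity >= 200; screening alpha 0.05;
#' responsiveness FDR 0.05; network |rho| > 0.5; LDA score > 2; VIP > 1;
#' 999 PERMANOVA permutations.
#'
#' @param seed global seed; per-stage seeds are derived by fixed offsets.
#' @param ... overrides for any config entry.
#' @return a named list.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    taxa_abundance_threshold = 0.001,
    prevalence_min_fraction = 0.5,
    cpm_threshold = 5,
    metabolite_min_presence = 0.5,
    metabolite_max_rsd = 30,
    metabolite_min_similarity = 200,
    alpha = 0.05,
    fdr = 0.05,
    r_threshold = 0.5,
    lda_threshold = 2,
    vip_threshold = 1,
    n_perm = 999,
    pls_components = 2,
    explainability_denominator = "model",
    group_rule = "every"  # prevalence criterion required in every group
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a YAML configuration
#'
#' @param path YAML file; entries override [default_config()].
#' @return a config list.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the full cross-omics analysis
#'
#' Stages, in order: feature retention per layer; standardization;
#' relationship matrices; per-layer REML explainability with LRT;
#' Bray-Curtis distance and PCoA of the filtered taxa; metabotype screening
#' with PERMANOVA responsiveness (both metabolomes); differential features
#' (Wilcoxon+FDR and LDA-score for taxa, LDA-score for functions, t-test+VIP
#' for metabolomes); taxa-metabolome correlation networks. Every output
#' table is written as TSV under `out_dir` together with a JSON manifest
#' holding the config, its hash, and the seed; re-running with identical
#' config and inputs is byte-identical.
#'
#' @param phenotype a `PhenotypeTable` with `group` labels.
#' @param layers named list of raw `FeatureTable`s with names `taxa`
#'   (relative), `function` (cpm), `rumen_metabolome`, `serum_metabolome`
#'   (intensity).
#' @param config list from [default_config()] / [read_config()].
#' @param out_dir output directory (created; default `NULL` = no files
#'   written, results only returned).
#' @return invisible list: `explainability`, `metabotypes` (per metabolome),
#'   `differential` (per layer), `networks`, `pcoa`, `filtered`, `manifest`.
#' @export
run_pipeline <- function(phenotype, layers, config = default_config(),
                         out_dir = NULL) {
  req <- c("taxa", "function", "rumen_metabolome", "serum_metabolome")
  if (!all(req %in% names(layers)))
    stop("layers must include: ", paste(req, collapse = ", "))
  for (nm in names(layers)) {
    ids <- rownames(layers[[nm]]$values)
    if (!setequal(ids, phenotype$sample_id))
      stop("sample-set mismatch in layer '", nm, "': ",
           paste(c(setdiff(ids, phenotype$sample_id),
                   setdiff(phenotype$sample_id, ids)), collapse = ", "))
    layers[[nm]]$values <- layers[[nm]]$values[phenotype$sample_id, , drop = FALSE]
  }
  if (is.null(phenotype$group)) stop("phenotype must carry group labels")
  groups <- stats::setNames(phenotype$group, phenotype$sample_id)
  cfg <- config

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  filtered <- list()
  filtered$taxa <- stage("filter_taxa", filter_prevalent_features(
    layers$taxa, groups, cfg$taxa_abundance_threshold,
    cfg$prevalence_min_fraction))
  filtered$`function` <- stage("filter_function", filter_prevalent_features(
    layers$`function`, groups, cfg$cpm_threshold, cfg$prevalence_min_fraction))
  for (nm in c("rumen_metabolome", "serum_metabolome"))
    filtered[[nm]] <- stage(paste0("filter_", nm), filter_metabolite_peaks(
      layers[[nm]], min_presence = cfg$metabolite_min_presence,
      max_rsd = cfg$metabolite_max_rsd,
      min_similarity = cfg$metabolite_min_similarity))

  z <- lapply(filtered, function(t) suppressWarnings(zscore_standardize(t)))
  kinship <- lapply(z, build_relationship_matrix)

  fits <- stage("explainability", lapply(names(kinship), function(nm)
    reml_fit(phenotype$mpy, phenotype[, c("parity", "dim")], kinship[[nm]],
             layer = nm, denominator = cfg$explainability_denominator)))
  names(fits) <- names(kinship)
  report <- explainability_report(fits)

  d_taxa <- stage("bray_curtis", bray_curtis(filtered$taxa))
  ord <- stage("pcoa", pcoa(d_taxa, k = 2))

  metabotypes <- list()
  for (i in seq_along(c("rumen_metabolome", "serum_metabolome"))) {
    nm <- c("rumen_metabolome", "serum_metabolome")[i]
    metabotypes[[nm]] <- stage(paste0("metabotypes_", nm), metabotype_analysis(
      filtered[[nm]], phenotype, d_taxa, alpha = cfg$alpha, fdr = cfg$fdr,
      n_perm = cfg$n_perm, seed = cfg$seed + 100 * i))
  }

  differential <- list()
  differential$taxa_wilcoxon <- stage("wilcoxon_taxa", {
    v <- filtered$taxa$values
    res <- lapply(seq_len(ncol(v)), function(j) {
      sp <- split(v[, j], groups[rownames(v)])
      w <- wilcoxon_rank_sum(sp[[1]], sp[[2]])
      data.frame(feature_id = colnames(v)[j], rank_sum = w$rank_sum, p = w$p)
    })
    res <- do.call(rbind, res)
    res$q_bh <- bh_fdr(res$p)
    res$significant <- res$q_bh < cfg$fdr
    res
  })
  differential$taxa_lefse <- stage("lefse_taxa", lefse_style_score(
    filtered$taxa, groups, kw_alpha = cfg$alpha,
    lda_threshold = cfg$lda_threshold))
  differential$function_lefse <- stage("lefse_function", lefse_style_score(
    filtered$`function`, groups, kw_alpha = cfg$alpha,
    lda_threshold = cfg$lda_threshold))
  for (nm in c("rumen_metabolome", "serum_metabolome"))
    differential[[paste0(nm, "_ttest_vip")]] <- stage(
      paste0("ttest_vip_", nm),
      suppressWarnings(differential_metabolites(
        filtered[[nm]], groups, alpha = cfg$fdr,
        vip_threshold = cfg$vip_threshold,
        n_components = cfg$pls_components)))

  networks <- list()
  for (nm in c("rumen_metabolome", "serum_metabolome"))
    networks[[paste0("taxa_", nm)]] <- stage(paste0("network_", nm),
      build_correlation_network(filtered$taxa, filtered[[nm]],
                                r_threshold = cfg$r_threshold,
                                alpha = cfg$alpha))

  manifest <- list(config = cfg, seed = cfg$seed,
                   n_samples = nrow(phenotype),
                   n_features_retained = vapply(filtered, function(t)
                     ncol(t$values), numeric(1)))

  res <- list(explainability = report, metabotypes = metabotypes,
              differential = differential, networks = networks,
              pcoa = ord, filtered = filtered, kinship = kinship,
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(report, "explainability.tsv")
    for (nm in names(metabotypes)) wt(metabotypes[[nm]],
                                      paste0("metabotypes_", nm, ".tsv"))
    for (nm in names(differential)) wt(differential[[nm]],
                                       paste0("differential_", nm, ".tsv"))
    for (nm in names(networks)) wt(cbind(networks[[nm]], kept = TRUE),
                                   paste0("network_", nm, ".tsv"))
    for (nm in names(kinship))
      write_square_matrix(kinship[[nm]],
                          file.path(out_dir, paste0("kinship_", nm, ".tsv")))
    write_square_matrix(d_taxa, file.path(out_dir, "bray_curtis_taxa.tsv"))
    utils::write.table(
      data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
      file.path(out_dir, "pcoa_taxa.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
    manifest$config_hash <- unname(tools::md5sum(cfg_path))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$manifest <- manifest
  }
  invisible(res)
}
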