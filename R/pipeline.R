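# Orchestration of the full dual-omics analysis.

#' Pipeline run configuration
#'
#' @param fdr_discovery discovery FDR level (default 0.2).
#' @param fdr_strict strict FDR level (default 0.05).
#' @param top_k top-abundance species universe for networks, balances and
#'   attribution (default 50).
#' @param rho_min,alpha co-occurrence edge thresholds.
#' @param boot_replicates,subsample network bootstrap design (default
#'   100 x 30).
#' @param balance_max_size,cv_folds,cv_repeats balance search settings.
#' @param n_trees,shap_permutations forest / Shapley settings.
#' @param max_shap_pathways cap on the number of flagged pathways carried
#'   into the attribution stage.
#' @param seed master seed; each stochastic stage derives its own stream.
#' @return list of class `run_config`.
#' @export
run_config <- function(fdr_discovery = 0.2, fdr_strict = 0.05, top_k = 50,
                       rho_min = 0.3, alpha = 0.05, boot_replicates = 100,
                       subsample = 30, balance_max_size = 8, cv_folds = 5,
                       cv_repeats = 10, n_trees = 500,
                       shap_permutations = 200, max_shap_pathways = 3,
                       seed = 1) {
  cfg <- list(fdr_discovery = fdr_discovery, fdr_strict = fdr_strict,
              top_k = top_k, rho_min = rho_min, alpha = alpha,
              boot_replicates = boot_replicates, subsample = subsample,
              balance_max_size = balance_max_size, cv_folds = cv_folds,
              cv_repeats = cv_repeats, n_trees = n_trees,
              shap_permutations = shap_permutations,
              max_shap_pathways = max_shap_pathways, seed = seed)
  assert_that(all(c(fdr_discovery, fdr_strict, alpha) > 0) &&
                all(c(fdr_discovery, fdr_strict, alpha) <= 1),
              "thresholds must lie in (0, 1]",
              class = "dualomics_parameter_error")
  structure(cfg, class = "run_config")
}

stage_msg <- function(stage, ...) {
  message(sprintf("[dualomics] %s: %s", stage, paste0(...)))
}

#' Run the full integrative analysis
#'
#' Aligns the three input tables on shared samples, then executes:
#' differential abundance (species, genus, metabolites, optional KO
#' pathways), diversity and ANOSIM, pathway activity scoring and
#' comparison, full-cohort and bootstrapped co-occurrence networks with
#' metric comparison, balance selection for GDM status and for OGTT
#' glucose at 0/1/2 h, sPLS of species against pathway scores, Spearman
#' heatmaps against clinical indices, and Shapley attribution of species
#' to each flagged pathway. Deterministic given the config seed.
#'
#' @param abundance an [abundance_table] (species level).
#' @param metabolites a [metabolite_table] with pathway map and sizes.
#' @param metadata data.frame with `sample_id`, `group` and clinical
#'   columns (see [read_metadata()]).
#' @param config a [run_config()].
#' @param ko_pathways optional samples x KO-pathway relative-abundance
#'   matrix; when absent the KO stage is skipped with a log entry.
#' @param out_dir optional directory; result tables are written as TSV and
#'   a JSON manifest recording parameters, seeds and row counts.
#' @return list of class `dualomics_run` with one element per stage plus
#'   `manifest`.
#' @export
run_all <- function(abundance, metabolites, metadata, config = run_config(),
                    ko_pathways = NULL, out_dir = NULL) {
  shared <- Reduce(intersect, list(rownames(values_of(abundance)),
                                   rownames(values_of(metabolites)),
                                   metadata$sample_id))
  assert_that(length(shared) >= 10, "fewer than 10 shared samples")
  stage_msg("align", length(shared), " shared samples")
  ab <- abundance; ab$values <- values_of(abundance)[shared, , drop = FALSE]
  mb <- metabolites; mb$values <- values_of(metabolites)[shared, , drop = FALSE]
  meta <- metadata[match(shared, metadata$sample_id), , drop = FALSE]
  groups <- meta$group

  res <- list()

  stage_msg("diffstats", "species/genus/metabolite tests")
  res$diff_species <- wilcoxon_bh(ab$values, groups)
  res$diff_genus <- wilcoxon_bh(collapse_to_genus(ab)$values, groups)
  res$diff_metabolites <- wilcoxon_bh(mb$values, groups)
  if (!is.null(ko_pathways)) {
    ko <- as.matrix(ko_pathways)[shared, , drop = FALSE]
    res$diff_ko_pathways <- wilcoxon_bh(ko, groups)
  } else {
    stage_msg("diffstats", "KO pathway table not provided; stage skipped")
  }
  res$diversity <- diversity_summary(ab, groups)
  res$diversity_tests <- list(
    richness = suppressWarnings(
      wilcox.test(richness ~ group, data = res$diversity)$p.value),
    shannon = suppressWarnings(
      wilcox.test(shannon ~ group, data = res$diversity)$p.value))
  res$anosim <- anosim_bray(ab, groups, n_permutations = 999,
                            seed = derive_seed(config$seed, 1L))

  stage_msg("papi", "pathway activity scores")
  norm <- suppressWarnings(normalize_metabolites(mb))
  res$pathway_scores <- pathway_activity(norm)
  res$diff_pathways <- compare_pathway_scores(res$pathway_scores, groups,
                                              fdr_flag = config$fdr_discovery)

  stage_msg("netboot", "co-occurrence networks")
  top <- select_top_taxa(ab, min(config$top_k, ncol(ab$values)))
  res$networks <- lapply(setNames(unique(groups), unique(groups)), function(g) {
    sub <- top; sub$values <- top$values[groups == g, , drop = FALSE]
    suppressWarnings(build_network(sub, rho_min = config$rho_min,
                                   alpha = config$fdr_strict,
                                   fdr_correct = TRUE, group = g))
  })
  res$core_species <- lapply(res$networks, core_species, top_n = 10)
  sub_n <- min(config$subsample, min(table(groups)))
  res$bootstrap <- bootstrap_networks(
    top, groups, subsample_size = sub_n,
    n_replicates = config$boot_replicates, rho_min = config$rho_min,
    alpha = config$alpha, seed = derive_seed(config$seed, 2L))
  res$network_comparison <- compare_metric_distributions(res$bootstrap)

  stage_msg("balance", "signature search (group + OGTT glucose)")
  pos <- replace_zeros(top)
  res$balance_group <- fit_balance(
    pos, groups, "binary", max_size = config$balance_max_size,
    cv_folds = config$cv_folds, cv_repeats = config$cv_repeats,
    seed = derive_seed(config$seed, 3L))
  res$balance_glucose <- list()
  for (gl in c("ogtt_glucose_0h", "ogtt_glucose_1h", "ogtt_glucose_2h")) {
    if (!gl %in% names(meta)) next
    res$balance_glucose[[gl]] <- fit_balance(
      pos, meta[[gl]], "continuous", max_size = config$balance_max_size,
      cv_folds = config$cv_folds, cv_repeats = config$cv_repeats,
      seed = derive_seed(config$seed, 4L))
  }

  stage_msg("integrate", "sPLS and Spearman heatmaps")
  res$spls <- spls_fit(log(pos$values),
                       res$pathway_scores$scores,
                       n_components = 2, keep_x = 10, keep_y = 5)
  res$spls_similarity <- spls_similarity(res$spls)
  clin <- c("ogtt_glucose_0h", "ogtt_glucose_1h", "ogtt_glucose_2h",
            "homa_ir", "hba1c", "bmi_prepregnancy", "neutrophil_count",
            "neutrophil_pct", "lymphocyte_pct", "tg")
  clin <- intersect(clin, names(meta))
  sig_sp <- apply_fdr_threshold(res$diff_species, config$fdr_discovery)$feature
  sig_sp <- intersect(sig_sp, colnames(top$values))
  if (length(sig_sp) >= 1 && length(clin) >= 1) {
    res$species_clinical <- spearman_heatmap(
      ab$values[, sig_sp, drop = FALSE],
      as.matrix(meta[, clin, drop = FALSE]))
  }
  sig_mb <- apply_fdr_threshold(res$diff_metabolites,
                                config$fdr_discovery)$feature
  if (length(sig_mb) >= 1 && length(clin) >= 1) {
    res$metabolite_clinical <- spearman_heatmap(
      mb$values[, sig_mb, drop = FALSE],
      as.matrix(meta[, clin, drop = FALSE]))
  }

  stage_msg("shap_attr", "forest + Shapley per flagged pathway")
  flagged <- apply_fdr_threshold(res$diff_pathways,
                                 config$fdr_discovery)$feature
  flagged <- head(flagged[order(res$diff_pathways$fdr_p[
    match(flagged, res$diff_pathways$feature)])], config$max_shap_pathways)
  res$shapley <- list()
  for (pw in flagged) {
    fm <- fit_forest(top$values, res$pathway_scores$scores[, pw],
                     n_trees = config$n_trees,
                     seed = derive_seed(config$seed, 5L))
    sv <- shapley_values(fm, n_permutations = config$shap_permutations,
                         seed = derive_seed(config$seed, 6L))
    res$shapley[[pw]] <- list(
      forest = fm, attributions = sv,
      by_group = compare_shapley_by_group(sv, groups,
                                          species_filter = sig_sp))
  }

  res$manifest <- list(
    n_samples = length(shared), n_taxa = ncol(ab$values),
    n_metabolites = ncol(mb$values),
    groups = as.list(table(groups)),
    parameters = unclass(config),
    stage_rows = list(diff_species = nrow(res$diff_species),
                      diff_metabolites = nrow(res$diff_metabolites),
                      pathways = ncol(res$pathway_scores$scores),
                      flagged_pathways = length(flagged)))
  class(res) <- "dualomics_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(res$diff_species, file.path(out_dir, "diff_species.tsv"))
    write_results(res$diff_genus, file.path(out_dir, "diff_genus.tsv"))
    write_results(res$diff_metabolites,
                  file.path(out_dir, "diff_metabolites.tsv"))
    write_results(res$diff_pathways, file.path(out_dir, "diff_pathways.tsv"))
    write_results(res$network_comparison,
                  file.path(out_dir, "network_comparison.tsv"))
    for (g in names(res$networks)) {
      write_results(res$networks[[g]]$edges,
                    file.path(out_dir, paste0("network_edges_", g, ".tsv")))
    }
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.dualomics_run <- function(x, ...) {
  m <- x$manifest
  cat("dualomics_run:", m$n_samples, "samples,", m$n_taxa, "taxa,",
      m$n_metabolites, "metabolites\n")
  cat("  flagged pathways:", m$stage_rows$flagged_pathways,
      "| species tested:", m$stage_rows$diff_species, "\n")
  invisible(x)
}
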