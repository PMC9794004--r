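# Pathway activity scoring from annotated metabolite abundances.
#
# A pathway's activity score for a sample is the sum of that sample's
# mean-normalized abundances over the measured metabolites mapped to the
# pathway, divided by the pathway's total compound count K_p
# (coverage-normalized summed relative abundance, "PAPi-style"). Unmeasured
# compounds contribute zero; they are not imputed.

#' Normalize metabolites to unit mean across samples
#'
#' Divides each metabolite by its mean across all samples, making
#' abundances comparable across metabolites with different instrument
#' response. Metabolites with zero mean are dropped with a warning.
#'
#' @param table a [metabolite_table].
#' @return a [metabolite_table] with per-metabolite mean 1.
#' @export
normalize_metabolites <- function(table) {
  m <- values_of(table)
  mu <- colMeans(m, na.rm = TRUE)
  assert_that(any(mu > 0), "all-zero metabolite table")
  drop <- mu == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " all-zero metabolite(s): ",
            paste(colnames(m)[drop], collapse = ", "))
    m <- m[, !drop, drop = FALSE]
    mu <- mu[!drop]
  }
  out <- table
  out$values <- sweep(m, 2, mu, "/")
  out
}

#' Pathway activity scores
#'
#' Computes `AS(s, p) = sum_i x_norm(s, i) / K_p` over measured metabolites
#' `i` mapped to pathway `p`, for every pathway with at least one measured
#' metabolite. `K_p` is the pathway's total compound count, so scores are
#' penalized for low pathway coverage.
#'
#' @param normalized a mean-normalized [metabolite_table] (see
#'   [normalize_metabolites()]) carrying `pathway_map` and `pathway_sizes`.
#' @return list of class `pathway_scores`: `scores` (samples x pathways),
#'   `k_detected`, `k_total` (named per pathway).
#' @export
pathway_activity <- function(normalized) {
  m <- values_of(normalized)
  pm <- normalized$pathway_map
  sizes <- normalized$pathway_sizes
  assert_that(!is.null(pm), "pathway_map required")
  assert_that(!is.null(sizes), "pathway_sizes required")
  pm <- pm[pm$metabolite %in% colnames(m), , drop = FALSE]
  paths <- unique(pm$pathway)
  assert_that(length(paths) > 0, "no pathway has a measured metabolite")
  missing_sz <- setdiff(paths, names(sizes))
  assert_that(length(missing_sz) == 0,
              "pathway size unknown for: ", paste(missing_sz, collapse = ", "))
  scores <- matrix(0, nrow(m), length(paths),
                   dimnames = list(rownames(m), paths))
  k_det <- setNames(integer(length(paths)), paths)
  for (p in paths) {
    mets <- pm$metabolite[pm$pathway == p]
    k_det[p] <- length(mets)
    scores[, p] <- rowSums(m[, mets, drop = FALSE]) / sizes[p]
  }
  structure(list(scores = scores, k_detected = k_det,
                 k_total = sizes[paths]),
            class = "pathway_scores")
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat("pathway_scores:", nrow(x$scores), "samples x", ncol(x$scores),
      "pathways\n")
  invisible(x)
}

#' Compare pathway activity scores between groups
#'
#' Wilcoxon rank-sum per pathway with BH adjustment across pathways
#' (delegates to [wilcoxon_bh()]); pathways passing the discovery FDR level
#' are flagged.
#'
#' @param scores a `pathway_scores` object (or samples x pathways matrix).
#' @param groups group labels per sample.
#' @param fdr_flag discovery FDR level used for the `flag_discovery` column.
#' @return a `diff_result` data.frame with an added `flag_discovery` column.
#' @export
compare_pathway_scores <- function(scores, groups, fdr_flag = 0.2) {
  m <- if (inherits(scores, "pathway_scores")) scores$scores else as.matrix(scores)
  res <- wilcoxon_bh(m, groups)
  res$flag_discovery <- res$fdr_p < fdr_flag
  res
}
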