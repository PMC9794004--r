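# Rank-based group comparisons, FDR control, diversity, ANOSIM, ratios.

#' Wilcoxon rank-sum tests with Benjamini-Hochberg correction
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test per feature, comparing the
#' case group (GDM) against the control group (NGT), followed by BH
#' adjustment across all tested features (one family per call). Exact
#' enumeration is used when both group sizes are at most 12 and the feature
#' has no ties; otherwise the normal approximation with tie and continuity
#' correction. The fold change convention is case over control
#' (`mean_a / mean_b` with group A = `group_a`).
#'
#' @param mat numeric matrix, samples x features (or features x samples with
#'   `features_as_rows = TRUE`).
#' @param groups factor/character vector of group labels per sample (two
#'   levels).
#' @param group_a label of the case group used as fold-change numerator;
#'   defaults to "GDM" when present, else the first level.
#' @param features_as_rows set TRUE if `mat` is features x samples.
#' @return data.frame of class `diff_result` with columns `feature`,
#'   `mean_a`, `mean_b`, `fold_change`, `p_value`, `fdr_p`, `flag_constant`.
#' @export
wilcoxon_bh <- function(mat, groups, group_a = NULL, features_as_rows = FALSE) {
  if (features_as_rows) mat <- t(mat)
  mat <- as.matrix(mat)
  groups <- as.character(groups)
  assert_that(length(groups) == nrow(mat),
              "groups must have one label per sample")
  lev <- unique(groups)
  assert_that(length(lev) == 2, "exactly two groups required")
  if (is.null(group_a)) group_a <- if ("GDM" %in% lev) "GDM" else lev[1]
  group_b <- setdiff(lev, group_a)
  ia <- groups == group_a
  ib <- groups == group_b
  assert_that(sum(ia) >= 2 && sum(ib) >= 2, "need >= 2 samples per group")
  feats <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
  p <- numeric(ncol(mat))
  flag <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    xa <- mat[ia, j]; xb <- mat[ib, j]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    vals <- c(xa, xb)
    if (length(unique(vals)) == 1L) {
      p[j] <- 1
      flag[j] <- TRUE
      next
    }
    exact <- length(xa) <= 12 && length(xb) <= 12 && !anyDuplicated(vals)
    p[j] <- suppressWarnings(
      wilcox.test(xa, xb, alternative = "two.sided", exact = exact,
                  correct = TRUE)$p.value)
  }
  if (any(flag)) warning(sum(flag), " constant feature(s): p set to 1")
  mean_a <- colMeans(mat[ia, , drop = FALSE], na.rm = TRUE)
  mean_b <- colMeans(mat[ib, , drop = FALSE], na.rm = TRUE)
  out <- data.frame(feature = feats,
                    mean_a = as.numeric(mean_a),
                    mean_b = as.numeric(mean_b),
                    fold_change = as.numeric(mean_a / mean_b),
                    p_value = p,
                    fdr_p = p.adjust(p, method = "BH"),
                    flag_constant = flag,
                    stringsAsFactors = FALSE)
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Filter a differential result at an FDR level
#'
#' Retains features with `fdr_p` strictly below the cutoff. The two working
#' levels of the analysis are 0.2 (discovery) and 0.05 (strict).
#'
#' @param results a `diff_result` data.frame.
#' @param cutoff FDR level in (0, 1].
#' @return the filtered subset.
#' @export
apply_fdr_threshold <- function(results, cutoff) {
  assert_that(is.numeric(cutoff) && length(cutoff) == 1 &&
                cutoff > 0 && cutoff <= 1,
              "cutoff must lie in (0, 1]", class = "dualomics_parameter_error")
  assert_that("fdr_p" %in% names(results), "fdr_p column missing")
  results[results$fdr_p < cutoff, , drop = FALSE]
}

#' Per-sample richness and Shannon diversity
#'
#' Richness counts taxa above the detection threshold; the Shannon index
#' (nats) is computed on the composition re-closed over detected taxa.
#'
#' @param table an [abundance_table].
#' @param groups optional group labels to carry along.
#' @param detection_threshold abundance strictly above this counts as
#'   detected (default 0).
#' @return data.frame with `sample_id`, `richness`, `shannon` (+ `group`).
#' @export
diversity_summary <- function(table, groups = NULL, detection_threshold = 0) {
  m <- values_of(table)
  rich <- integer(nrow(m)); shan <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    x <- x[x > detection_threshold]
    rich[i] <- length(x)
    if (length(x) == 0) {
      warning("sample ", rownames(m)[i], ": nothing detected; Shannon set to 0")
      shan[i] <- 0
    } else {
      q <- x / sum(x)
      shan[i] <- -sum(q * log(q))
    }
  }
  out <- data.frame(sample_id = rownames(m), richness = rich, shannon = shan,
                    stringsAsFactors = FALSE)
  if (!is.null(groups)) out$group <- as.character(groups)
  out
}

#' ANOSIM on Bray-Curtis dissimilarities
#'
#' Analysis of similarities comparing within- versus between-group rank
#' dissimilarities (Clarke's R), with a seeded permutation p-value
#' `(1 + #permuted R >= observed) / (1 + n_permutations)`. Dissimilarity
#' and test statistics are delegated to \pkg{vegan}.
#'
#' @param table an [abundance_table].
#' @param groups group labels per sample (>= 2 groups, >= 2 samples each).
#' @param n_permutations number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return list with `r_statistic`, `p_value`, `n_permutations`.
#' @export
anosim_bray <- function(table, groups, n_permutations = 999, seed = 1) {
  m <- values_of(table)
  groups <- as.factor(groups)
  assert_that(nlevels(droplevels(groups)) >= 2, "need >= 2 groups")
  assert_that(min(table(droplevels(groups))) >= 2,
              "singleton group not allowed")
  d <- vegan::vegdist(m, method = "bray")
  set.seed(seed)
  fit <- vegan::anosim(d, groups, permutations = n_permutations)
  list(r_statistic = unname(fit$statistic),
       p_value = fit$signif,
       n_permutations = n_permutations)
}

#' Per-sample abundance ratio of two taxa
#'
#' Ratio of two (typically genus-aggregate) taxa per sample, e.g.
#' Prevotella/Bacteroides. Zero denominators receive a pseudocount of half
#' the smallest positive value in the table and are flagged.
#'
#' @param table an [abundance_table].
#' @param numerator_taxon,denominator_taxon column names.
#' @param pseudocount replacement for zero denominators; default half the
#'   smallest positive table value.
#' @return data.frame `sample_id`, `ratio`, `flag_zero_denominator`.
#' @export
taxon_ratio <- function(table, numerator_taxon, denominator_taxon,
                        pseudocount = NULL) {
  m <- values_of(table)
  assert_that(numerator_taxon %in% colnames(m),
              "taxon absent: ", numerator_taxon)
  assert_that(denominator_taxon %in% colnames(m),
              "taxon absent: ", denominator_taxon)
  num <- m[, numerator_taxon]
  den <- m[, denominator_taxon]
  if (is.null(pseudocount)) {
    pos <- m[m > 0]
    pseudocount <- if (length(pos)) min(pos) / 2 else 1e-6
  }
  flag <- den == 0
  den[flag] <- pseudocount
  data.frame(sample_id = rownames(m), ratio = num / den,
             flag_zero_denominator = flag, stringsAsFactors = FALSE)
}
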