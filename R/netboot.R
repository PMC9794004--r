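# Subsample-bootstrap comparison of co-occurrence networks between groups.
#
# For each replicate a fixed-size subsample is drawn from each group
# (without replacement by default: with-replacement duplicates corrupt rank
# correlations), the network is rebuilt with identical thresholds, and all
# graph metrics plus every retained edge's rho are recorded. Edge
# significance inside replicates uses raw p-values by default (the
# full-cohort networks use BH-adjusted p-values).

#' Bootstrap co-occurrence networks per group
#'
#' @param table an [abundance_table] restricted to the taxa of interest
#'   (typically top 50).
#' @param groups group label per sample (two groups).
#' @param subsample_size samples drawn per group per replicate (default 30).
#' @param n_replicates number of replicates (default 100).
#' @param rho_min,alpha edge thresholds, as in [build_network()].
#' @param seed RNG seed; replicate draws are independent and deterministic.
#' @param fdr_correct BH-adjust edge p-values inside each replicate
#'   (default FALSE, raw p).
#' @param with_replacement draw subsamples with replacement (default FALSE).
#' @return object of class `network_bootstrap`: `global` (data.frame
#'   replicate, group, transitivity), `node` (replicate, group, node,
#'   degree, strength, closeness, eigenvector), `edge_rho` (list per group
#'   of n_replicates x n_pairs matrices of retained-edge rho, 0 when the
#'   edge is absent), `nodes`, parameters.
#' @export
bootstrap_networks <- function(table, groups, subsample_size = 30,
                               n_replicates = 100, rho_min = 0.3,
                               alpha = 0.05, seed = 1, fdr_correct = FALSE,
                               with_replacement = FALSE) {
  m <- values_of(table)
  groups <- as.character(groups)
  lev <- unique(groups)
  assert_that(length(lev) == 2, "exactly two groups required")
  for (g in lev) {
    assert_that(with_replacement || sum(groups == g) >= subsample_size,
                "subsample_size exceeds group size for ", g)
  }
  nodes <- colnames(m)
  pairs <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
  pair_names <- paste(nodes[pairs[, 1]], nodes[pairs[, 2]], sep = "||")
  global <- vector("list", 2 * n_replicates)
  node_rec <- vector("list", 2 * n_replicates)
  edge_rho <- lapply(lev, function(g)
    matrix(0, n_replicates, length(pair_names),
           dimnames = list(NULL, pair_names)))
  names(edge_rho) <- lev
  rec <- 0L
  for (gi in seq_along(lev)) {
    g <- lev[gi]
    rows <- which(groups == g)
    for (r in seq_len(n_replicates)) {
      set.seed(derive_seed(seed, gi * 100000L + r))
      take <- sample(rows, subsample_size, replace = with_replacement)
      sub <- list(values = m[take, , drop = FALSE])
      net <- suppressWarnings(
        build_network(sub, rho_min = rho_min, alpha = alpha,
                      fdr_correct = fdr_correct, group = g))
      gm <- suppressWarnings(graph_metrics(net))
      rec <- rec + 1L
      global[[rec]] <- data.frame(replicate = r, group = g,
                                  transitivity = gm$global_transitivity,
                                  stringsAsFactors = FALSE)
      nmx <- gm$node_metrics
      nmx$replicate <- r
      nmx$group <- g
      node_rec[[rec]] <- nmx
      if (nrow(net$edges)) {
        key <- paste(pmin(net$edges$u, net$edges$v),
                     pmax(net$edges$u, net$edges$v), sep = "||")
        edge_rho[[g]][r, key] <- net$edges$rho
      }
    }
  }
  structure(list(global = do.call(rbind, global),
                 node = do.call(rbind, node_rec),
                 edge_rho = edge_rho, nodes = nodes, groups = lev,
                 subsample_size = subsample_size,
                 n_replicates = n_replicates, rho_min = rho_min,
                 alpha = alpha, fdr_correct = fdr_correct, seed = seed),
            class = "network_bootstrap")
}

#' @export
print.network_bootstrap <- function(x, ...) {
  cat("network_bootstrap:", x$n_replicates, "replicates x", length(x$groups),
      "groups,", length(x$nodes), "nodes, subsample", x$subsample_size, "\n")
  invisible(x)
}

#' Compare bootstrap metric distributions between groups
#'
#' Two-sided Wilcoxon rank-sum tests on the replicate distributions of
#' global transitivity and on the node metrics (eigenvector centrality,
#' weighted degree, weighted closeness), BH-adjusted across the four
#' metrics. Node metrics are pooled over nodes x replicates by default;
#' `node_summary = "replicate_mean"` averages nodes within each replicate
#' first, and `node` restricts them to a single focal node's per-replicate
#' values.
#'
#' @param store a `network_bootstrap`.
#' @param node_summary "pooled" or "replicate_mean".
#' @param node optional focal node name.
#' @return a `diff_result`-style data.frame, one row per metric
#'   (`mean_a`/`mean_b` follow the store's group order: A = first group).
#' @export
compare_metric_distributions <- function(store, node_summary = "pooled",
                                         node = NULL) {
  ga <- store$groups[1]; gb <- store$groups[2]
  assert_that(store$n_replicates >= 2, "need >= 2 replicates per group")
  nd <- store$node
  if (!is.null(node)) {
    assert_that(node %in% store$nodes, "focal node absent: ", node)
    nd <- nd[nd$node == node, , drop = FALSE]
  } else if (node_summary == "replicate_mean") {
    nd <- do.call(rbind, lapply(split(nd, list(nd$group, nd$replicate)),
      function(d) data.frame(group = d$group[1], replicate = d$replicate[1],
                             strength = mean(d$strength),
                             closeness = mean(d$closeness),
                             eigenvector = mean(d$eigenvector))))
  }
  pull <- function(df, col) split(df[[col]], factor(df$group, levels = c(ga, gb)))
  sets <- list(
    global_transitivity = pull(store$global, "transitivity"),
    eigenvector_centrality = pull(nd, "eigenvector"),
    weighted_degree = pull(nd, "strength"),
    weighted_closeness = pull(nd, "closeness"))
  p <- vapply(sets, function(s) {
    if (length(unique(c(s[[1]], s[[2]]))) == 1L) return(1)
    suppressWarnings(wilcox.test(s[[1]], s[[2]], exact = FALSE,
                                 correct = TRUE)$p.value)
  }, numeric(1))
  out <- data.frame(feature = names(sets),
                    mean_a = vapply(sets, function(s) mean(s[[1]]), numeric(1)),
                    mean_b = vapply(sets, function(s) mean(s[[2]]), numeric(1)),
                    p_value = as.numeric(p),
                    fdr_p = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fold_change <- out$mean_a / out$mean_b
  attr(out, "group_a") <- ga
  attr(out, "group_b") <- gb
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Compare a focal species' edge-weight distributions between groups
#'
#' For every partner of the focal species, the per-replicate Spearman rho
#' supporting the focal-partner edge (0 when the edge is absent from a
#' replicate, or dropped with `absent = "drop"`) is compared between groups
#' by rank-sum test, BH-adjusted across partners with at least one
#' connection; partners never connected in either group are excluded.
#'
#' @param store a `network_bootstrap`.
#' @param focal_species node name.
#' @param top_n number of most significant partners to return (default 10).
#' @param absent "zero" (default) or "drop" for absent-edge replicates.
#' @return data.frame: partner, median rho per group, sign per group,
#'   p_value, fdr_p; ordered by significance.
#' @export
focal_edge_comparison <- function(store, focal_species, top_n = 10,
                                  absent = c("zero", "drop")) {
  absent <- match.arg(absent)
  assert_that(focal_species %in% store$nodes,
              "focal species absent: ", focal_species)
  ga <- store$groups[1]; gb <- store$groups[2]
  partners <- setdiff(store$nodes, focal_species)
  key <- paste(pmin(focal_species, partners), pmax(focal_species, partners),
               sep = "||")
  ra <- store$edge_rho[[ga]][, key, drop = FALSE]
  rb <- store$edge_rho[[gb]][, key, drop = FALSE]
  connected <- colSums(ra != 0) + colSums(rb != 0) > 0
  partners <- partners[connected]
  ra <- ra[, connected, drop = FALSE]; rb <- rb[, connected, drop = FALSE]
  if (length(partners) == 0) {
    return(data.frame(partner = character(0), median_rho_a = numeric(0),
                      median_rho_b = numeric(0), p_value = numeric(0),
                      fdr_p = numeric(0)))
  }
  p <- numeric(length(partners))
  for (j in seq_along(partners)) {
    xa <- ra[, j]; xb <- rb[, j]
    if (absent == "drop") { xa <- xa[xa != 0]; xb <- xb[xb != 0] }
    if (length(xa) == 0 || length(xb) == 0 ||
        length(unique(c(xa, xb))) == 1L) { p[j] <- 1; next }
    p[j] <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE,
                                         correct = TRUE)$p.value)
  }
  out <- data.frame(partner = partners,
                    median_rho_a = apply(ra, 2, median),
                    median_rho_b = apply(rb, 2, median),
                    p_value = p,
                    fdr_p = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$sign_a <- sign(out$median_rho_a)
  out$sign_b <- sign(out$median_rho_b)
  out <- out[order(out$fdr_p, out$p_value, out$partner), ]
  attr(out, "group_a") <- ga
  attr(out, "group_b") <- gb
  head(out, n = min(top_n, nrow(out)))
}
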