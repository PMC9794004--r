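# Spearman co-occurrence networks over the most abundant species and the
# graph metrics compared between groups.

# Spearman rho and asymptotic p (t approximation, as in cor.test with
# exact = FALSE) for all column pairs at once. Constant columns give NA.
spearman_all_pairs <- function(m) {
  n <- nrow(m)
  r <- apply(m, 2, rank)
  rho <- suppressWarnings(cor(r))
  diag(rho) <- NA
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(rho) & abs(rho) >= 1] <- 0
  list(rho = rho, p = p)
}

#' Build a co-occurrence network
#'
#' Spearman correlation of every taxon pair; edges are retained when the
#' (optionally BH-adjusted) p-value is below `alpha` and `|rho|` strictly
#' exceeds `rho_min`. The node set stays fixed to the input taxa even when
#' isolated. Constant taxa yield undefined correlations and contribute no
#' edges (warned).
#'
#' @param table an [abundance_table], typically the top-k most abundant
#'   species ([select_top_taxa()]).
#' @param rho_min minimum absolute Spearman coefficient (strict, default 0.3).
#' @param alpha significance level for edges (default 0.05).
#' @param fdr_correct apply BH across all C(k,2) pair tests before
#'   thresholding (the full-cohort convention); `FALSE` uses raw p-values
#'   (the bootstrap-replicate convention).
#' @param group optional group label stored on the network.
#' @return object of class `cooccurrence_network`: `nodes`, `edges`
#'   (data.frame u, v, rho, p, fdr_p), thresholds, `n_samples`.
#' @export
build_network <- function(table, rho_min = 0.3, alpha = 0.05,
                          fdr_correct = TRUE, group = NA_character_) {
  m <- values_of(table)
  assert_that(ncol(m) >= 3, "need at least 3 taxa")
  assert_that(nrow(m) >= 5, "need at least 5 samples")
  cst <- apply(m, 2, function(x) length(unique(x)) == 1L)
  if (any(cst)) warning(sum(cst), " constant taxon/taxa: pairs treated as no edge")
  sp <- spearman_all_pairs(m)
  idx <- which(upper.tri(sp$rho), arr.ind = TRUE)
  rho <- sp$rho[idx]; p <- sp$p[idx]
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- p.adjust(p[ok], method = "BH")
  crit <- if (fdr_correct) fdr else p
  keep <- ok & !is.na(rho) & crit < alpha & abs(rho) > rho_min
  edges <- data.frame(u = colnames(m)[idx[keep, 1]],
                      v = colnames(m)[idx[keep, 2]],
                      rho = rho[keep], p = p[keep], fdr_p = fdr[keep],
                      stringsAsFactors = FALSE)
  structure(list(nodes = colnames(m), edges = edges, group = group,
                 rho_min = rho_min, alpha = alpha,
                 fdr_correct = fdr_correct, n_samples = nrow(m)),
            class = "cooccurrence_network")
}

#' Assemble a co-occurrence network from an explicit edge list
#'
#' Useful for computing [graph_metrics()] on externally defined graphs.
#'
#' @param nodes character vector of node names.
#' @param edges data.frame with columns `u`, `v`, `rho` (optionally `p`,
#'   `fdr_p`).
#' @param group,rho_min,alpha metadata recorded on the object.
#' @return a `cooccurrence_network`.
#' @export
cooccurrence_network <- function(nodes, edges, group = NA_character_,
                                 rho_min = 0.3, alpha = 0.05) {
  assert_that(all(c("u", "v", "rho") %in% names(edges)),
              "edges needs columns u, v, rho")
  assert_that(all(c(edges$u, edges$v) %in% nodes),
              "edge endpoints must be in nodes")
  assert_that(all(edges$u != edges$v), "self-loops not allowed")
  assert_that(all(abs(edges$rho) <= 1), "|rho| must be <= 1")
  if (is.null(edges$p)) edges$p <- rep(NA_real_, nrow(edges))
  if (is.null(edges$fdr_p)) edges$fdr_p <- rep(NA_real_, nrow(edges))
  structure(list(nodes = nodes, edges = edges, group = group,
                 rho_min = rho_min, alpha = alpha, fdr_correct = NA,
                 n_samples = NA_integer_),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("cooccurrence_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (|rho| >", x$rho_min, ",",
      if (x$fdr_correct) "FDR" else "raw", "p <", x$alpha, ")\n")
  invisible(x)
}

net_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  igraph::E(g)$rho <- net$edges$rho
  igraph::E(g)$weight <- abs(net$edges$rho)
  g
}

#' Graph metrics of a co-occurrence network
#'
#' Global transitivity (fraction of closed triads, unweighted); per-node
#' strength (weighted degree, sum of incident `|rho|`); weighted closeness
#' `(number of reachable nodes) / (sum of shortest-path distances)` with
#' edge length `1 - |rho|` (0 for isolated nodes); eigenvector centrality as
#' the non-negative, L2-normalized principal eigenvector of the `|rho|`
#' adjacency matrix. Negative correlations enter all metrics through their
#' absolute value.
#'
#' @param net a `cooccurrence_network`.
#' @return list: `global_transitivity` scalar and data.frame `node_metrics`
#'   (node, degree, strength, closeness, eigenvector).
#' @export
graph_metrics <- function(net) {
  k <- length(net$nodes)
  if (nrow(net$edges) == 0) {
    warning("empty edge set: all metrics 0")
    z <- numeric(k)
    return(list(global_transitivity = 0,
                node_metrics = data.frame(node = net$nodes, degree = z,
                                          strength = z, closeness = z,
                                          eigenvector = z,
                                          stringsAsFactors = FALSE)))
  }
  g <- net_igraph(net)
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  deg <- igraph::degree(g)
  strength <- igraph::strength(g)
  d <- igraph::distances(g, weights = 1 - abs(igraph::E(g)$rho))
  closeness <- vapply(seq_len(k), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    if (!any(reach)) 0 else sum(reach) / sum(di[reach])
  }, numeric(1))
  A <- matrix(0, k, k, dimnames = list(net$nodes, net$nodes))
  A[cbind(net$edges$u, net$edges$v)] <- abs(net$edges$rho)
  A[cbind(net$edges$v, net$edges$u)] <- abs(net$edges$rho)
  ev <- eigen(A, symmetric = TRUE)$vectors[, 1]
  if (sum(ev) < 0) ev <- -ev
  ev[ev < 0] <- 0
  nrm <- sqrt(sum(ev^2))
  if (nrm > 0) ev <- ev / nrm
  list(global_transitivity = trans,
       node_metrics = data.frame(node = net$nodes,
                                 degree = as.numeric(deg),
                                 strength = as.numeric(strength),
                                 closeness = closeness,
                                 eigenvector = ev,
                                 stringsAsFactors = FALSE))
}

#' Core species of a network
#'
#' Nodes ranked by unweighted degree, ties broken by strength and then
#' taxon name; rankings by weighted degree (strength) and weighted
#' closeness are returned alongside.
#'
#' @param net a `cooccurrence_network`.
#' @param top_n number of rows to return per ranking (default all).
#' @return list of data.frames `by_degree`, `by_strength`, `by_closeness`.
#' @export
core_species <- function(net, top_n = Inf) {
  gm <- graph_metrics(net)
  nm <- gm$node_metrics
  take <- function(df) head(df, n = min(top_n, nrow(df)))
  list(by_degree = take(nm[order(-nm$degree, -nm$strength, nm$node), ]),
       by_strength = take(nm[order(-nm$strength, nm$node), ]),
       by_closeness = take(nm[order(-nm$closeness, nm$node), ]))
}
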