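# Independent brute-force oracles used to pin the statistical kernels.
# These deliberately avoid the code paths they check.

# Exact two-sided Wilcoxon rank-sum p by enumeration of all C(n, n1)
# assignments of the pooled ranks (valid when there are no ties).
oracle_wilcoxon_exact <- function(xa, xb) {
  n1 <- length(xa); n <- n1 + length(xb)
  r <- rank(c(xa, xb))
  obs <- sum(r[seq_len(n1)])
  sums <- combn(n, n1, FUN = sum)
  p <- min(1, 2 * min(mean(sums <= obs), mean(sums >= obs)))
  p
}

# Benjamini-Hochberg by the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  adj[o] <- rev(cummin(rev(sorted)))
  pmin(adj, 1)
}

# Spearman rho as Pearson correlation of ranks.
oracle_spearman <- function(x, y) cor(rank(x), rank(y))

# All-pairs network edges by per-pair cor.test (t approximation), raw or
# BH-adjusted p, strict thresholds.
oracle_network_edges <- function(m, rho_min, alpha, fdr_correct) {
  k <- ncol(m)
  pairs <- t(combn(k, 2))
  rho <- p <- numeric(nrow(pairs))
  for (e in seq_len(nrow(pairs))) {
    ct <- suppressWarnings(cor.test(m[, pairs[e, 1]], m[, pairs[e, 2]],
                                    method = "spearman", exact = FALSE))
    rho[e] <- unname(ct$estimate); p[e] <- ct$p.value
  }
  crit <- if (fdr_correct) p.adjust(p, "BH") else p
  keep <- crit < alpha & abs(rho) > rho_min
  data.frame(u = colnames(m)[pairs[keep, 1]], v = colnames(m)[pairs[keep, 2]],
             rho = rho[keep], stringsAsFactors = FALSE)
}

# AUC by trapezoidal integration of the empirical ROC curve.
oracle_auc_trapezoid <- function(s, y) {
  th <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(s[y == 1] >= t), 0), 1)
  fpr <- c(0, vapply(th, function(t) mean(s[y == 0] >= t), 0), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Exhaustive best single (numerator, denominator) pair balance search.
oracle_best_pair <- function(L, y, type) {
  k <- ncol(L)
  best <- list(crit = -Inf)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    s <- sqrt(0.5) * (L[, i] - L[, j])
    crit <- if (type == "binary") {
      r <- rank(s); n1 <- sum(y == 1); n0 <- sum(y == 0)
      (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    } else suppressWarnings(cor(s, y))^2
    if (is.na(crit)) crit <- 0
    if (crit > best$crit + 1e-12) {
      best <- list(num = colnames(L)[i], den = colnames(L)[j], crit = crit)
    }
  }
  best
}

# Dense PLS first component by power iteration on the cross-covariance.
oracle_pls_first <- function(X, Y, iters = 2000) {
  M <- crossprod(scale(X), scale(Y))
  v <- rep(1 / sqrt(ncol(Y)), ncol(Y))
  for (i in seq_len(iters)) {
    u <- as.numeric(M %*% v); u <- u / sqrt(sum(u^2))
    v <- as.numeric(crossprod(M, u)); v <- v / sqrt(sum(v^2))
  }
  if (u[which.max(abs(u))] < 0) { u <- -u; v <- -v }
  list(u = u, v = v)
}

# Exact Shapley values by subset enumeration for a prediction function,
# background-marginalized value function.
oracle_exact_shapley <- function(predfun, x, background, p) {
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  nb <- nrow(background)
  vals <- apply(subsets, 1, function(s) {
    comp <- background
    comp[, s] <- matrix(x[s], nb, sum(s), byrow = TRUE)
    mean(predfun(comp))
  })
  key <- apply(subsets, 1, function(s) paste0("k", paste(which(s), collapse = ",")))
  v <- setNames(vals, key)
  phi <- numeric(p)
  fact <- factorial(0:p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (r in 0:(p - 1)) {
      ss <- if (r == 0) list(integer(0)) else
        combn(others, r, simplify = FALSE)
      w <- fact[r + 1] * fact[p - r] / fact[p + 1]
      for (S in ss) {
        kS <- paste0("k", paste(S, collapse = ","))
        kSi <- paste0("k", paste(sort(c(S, i)), collapse = ","))
        phi[i] <- phi[i] + w * (v[[kSi]] - v[[kS]])
      }
    }
  }
  phi
}
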