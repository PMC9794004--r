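# Sparse partial least squares between omics blocks and Spearman
# association heatmaps against clinical indices.
#
# sPLS variant: regression mode; per component the dominant singular pair
# of the X-Y cross-covariance is sparsified by soft-thresholding to a
# fixed count of largest-magnitude entries per loading (the keepX idiom)
# and re-normalized; both blocks are deflated on the X scores.

soft_keep <- function(w, keep) {
  a <- abs(w)
  if (keep < length(w)) {
    lambda <- sort(a, decreasing = TRUE)[keep + 1]
    w <- sign(w) * pmax(a - lambda, 0)
  }
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) w / nrm else w
}

#' Fit a sparse PLS model between two blocks
#'
#' @param X,Y numeric matrices, samples x variables, aligned rows.
#' @param n_components number of latent components.
#' @param keep_x,keep_y retained-variable counts per component.
#' @param center,scale column-center / unit-variance-scale the blocks
#'   (default TRUE; zero-variance columns are an error).
#' @param max_iter,tol inner alternating-update control.
#' @return object of class `spls_model`: `x_loadings`, `y_loadings`
#'   (variables x components, unit L2 columns with at most keep_x/keep_y
#'   nonzeros), `scores` (X scores, samples x components), the processed
#'   blocks, and settings. Deterministic: SVD initialization with the sign
#'   fixed so the largest-magnitude X-loading entry is positive.
#' @export
spls_fit <- function(X, Y, n_components = 2, keep_x = 10, keep_y = 5,
                     center = TRUE, scale = TRUE, max_iter = 500,
                     tol = 1e-9) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  assert_that(nrow(X) == nrow(Y), "X and Y must have aligned samples")
  n <- nrow(X)
  assert_that(n_components <= min(ncol(X), ncol(Y), n - 1),
              "n_components exceeds min(p, q, n - 1)",
              class = "dualomics_parameter_error")
  if (scale) {
    sdx <- apply(X, 2, sd); sdy <- apply(Y, 2, sd)
    bad <- c(colnames(X)[sdx == 0], colnames(Y)[sdy == 0])
    assert_that(length(bad) == 0, "zero-variance column(s): ",
                paste(bad, collapse = ", "))
  }
  Xs <- base::scale(X, center = center, scale = scale)
  Ys <- base::scale(Y, center = center, scale = scale)
  keep_x <- min(keep_x, ncol(X)); keep_y <- min(keep_y, ncol(Y))
  p <- ncol(X); q <- ncol(Y)
  U <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  V <- matrix(0, q, n_components, dimnames = list(colnames(Y), NULL))
  Tm <- matrix(0, n, n_components, dimnames = list(rownames(X), NULL))
  Xh <- Xs; Yh <- Ys
  for (h in seq_len(n_components)) {
    M <- crossprod(Xh, Yh)
    sv <- svd(M, nu = 1, nv = 1)
    u <- soft_keep(sv$u[, 1], keep_x)
    v <- soft_keep(sv$v[, 1], keep_y)
    for (it in seq_len(max_iter)) {
      u_new <- soft_keep(as.numeric(M %*% v), keep_x)
      v_new <- soft_keep(as.numeric(crossprod(M, u_new)), keep_y)
      if (max(abs(u_new - u)) < tol && max(abs(v_new - v)) < tol) {
        u <- u_new; v <- v_new; break
      }
      u <- u_new; v <- v_new
    }
    if (u[which.max(abs(u))] < 0) { u <- -u; v <- -v }
    xi <- as.numeric(Xh %*% u)
    ss <- sum(xi^2)
    if (ss < .Machine$double.eps) break
    cx <- as.numeric(crossprod(Xh, xi)) / ss
    dy <- as.numeric(crossprod(Yh, xi)) / ss
    Xh <- Xh - tcrossprod(xi, cx)
    Yh <- Yh - tcrossprod(xi, dy)     # regression-mode deflation
    U[, h] <- u; V[, h] <- v; Tm[, h] <- xi
  }
  structure(list(x_loadings = U, y_loadings = V, scores = Tm,
                 X = Xs, Y = Ys, n_components = n_components,
                 keep_x = keep_x, keep_y = keep_y),
            class = "spls_model")
}

#' @export
print.spls_model <- function(x, ...) {
  cat("spls_model:", x$n_components, "components; keepX =", x$keep_x,
      ", keepY =", x$keep_y, "\n")
  invisible(x)
}

#' Variable-pair similarity surface of a fitted sPLS model
#'
#' `similarity(i, j) = sum_h cor(X_i, t_h) * cor(Y_j, t_h)` over the latent
#' X scores, clipped to `[-1, 1]`; this is the surface drawn in sPLS
#' association heatmaps.
#'
#' @param model an `spls_model`.
#' @return numeric matrix, X variables x Y variables.
#' @export
spls_similarity <- function(model) {
  assert_that(inherits(model, "spls_model"), "unfitted model")
  cx <- suppressWarnings(cor(model$X, model$scores))
  cy <- suppressWarnings(cor(model$Y, model$scores))
  cx[is.na(cx)] <- 0; cy[is.na(cy)] <- 0
  sim <- tcrossprod(cx, cy)
  pmin(pmax(sim, -1), 1)
}

#' Spearman cross-correlation heatmap between two feature blocks
#'
#' All cross-pairs' Spearman rho and p (t approximation), pairwise-complete
#' over missing values, BH-adjusted across the full matrix. Pairs with
#' fewer than 3 complete observations get missing rho and are flagged.
#'
#' @param A,B numeric matrices, samples x features, aligned rows.
#' @return list of class `association_matrix`: `rho`, `p`, `fdr_p`
#'   matrices (A features x B features) and `n_complete`.
#' @export
spearman_heatmap <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  assert_that(nrow(A) == nrow(B), "A and B must have aligned samples")
  pa <- ncol(A); pb <- ncol(B)
  rho <- p <- nc <- matrix(NA_real_, pa, pb,
                           dimnames = list(colnames(A), colnames(B)))
  for (i in seq_len(pa)) {
    for (j in seq_len(pb)) {
      ok <- stats::complete.cases(A[, i], B[, j])
      nc[i, j] <- sum(ok)
      if (nc[i, j] < 3) next
      ct <- suppressWarnings(cor.test(A[ok, i], B[ok, j],
                                      method = "spearman", exact = FALSE))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  fdr <- p
  ok <- !is.na(p)
  fdr[ok] <- p.adjust(p[ok], method = "BH")
  structure(list(rho = rho, p = p, fdr_p = fdr, n_complete = nc),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("association_matrix:", nrow(x$rho), "x", ncol(x$rho),
      "Spearman correlations;", sum(x$fdr_p < 0.05, na.rm = TRUE),
      "at FDR p < 0.05\n")
  invisible(x)
}
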