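rank1_blocks <- function(n = 80, p = 8, q = 5, seed = 2, noise = 0.05) {
  set.seed(seed)
  t_lat <- rnorm(n)
  w <- c(3, -2, 1.5, rep(0, p - 3))
  X <- outer(t_lat, w) + matrix(rnorm(n * p, 0, noise), n, p)
  cy <- c(2, -1, rep(0.5, q - 2))
  Y <- outer(t_lat, cy) + matrix(rnorm(n * q, 0, noise), n, q)
  colnames(X) <- paste0("x", 1:p); colnames(Y) <- paste0("y", 1:q)
  list(X = X, Y = Y, w = w)
}

test_that("sPLS recovers a planted latent direction with full keeps", {
  fx <- rank1_blocks()
  # centered, unscaled fit: loadings live on the raw planted direction
  fit <- spls_fit(fx$X, fx$Y, n_components = 1, keep_x = ncol(fx$X),
                  keep_y = ncol(fx$Y), scale = FALSE)
  w_unit <- fx$w / sqrt(sum(fx$w^2))
  cosine <- abs(sum(fit$x_loadings[, 1] * w_unit))
  expect_gte(cosine, 0.99)
})

test_that("dense sPLS equals power-iteration PLS on the cross-covariance", {
  set.seed(6)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("x", 1:6)))
  Y <- X[, 1:3] %*% matrix(rnorm(9), 3) + matrix(rnorm(40 * 3, 0, 0.3), 40, 3)
  colnames(Y) <- paste0("y", 1:3)
  fit <- spls_fit(X, Y, n_components = 1, keep_x = 6, keep_y = 3)
  ora <- oracle_pls_first(X, Y)
  expect_equal(abs(as.numeric(fit$x_loadings[, 1])), abs(ora$u),
               tolerance = 1e-6)
  expect_equal(abs(as.numeric(fit$y_loadings[, 1])), abs(ora$v),
               tolerance = 1e-6)
})

test_that("sparsity honours keep counts and scores stay orthogonal", {
  set.seed(3)
  X <- matrix(rnorm(60 * 10), 60, 10, dimnames = list(NULL, paste0("x", 1:10)))
  Y <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("y", 1:6)))
  fit <- spls_fit(X, Y, n_components = 3, keep_x = 4, keep_y = 2)
  expect_true(all(colSums(fit$x_loadings != 0) <= 4))
  expect_true(all(colSums(fit$y_loadings != 0) <= 2))
  expect_equal(sqrt(colSums(fit$x_loadings^2)), rep(1, 3), tolerance = 1e-8)
  cp <- crossprod(fit$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
  Xz <- X; Xz[, 2] <- 5
  expect_error(spls_fit(Xz, Y, 1), "x2")
})

test_that("similarity surface highlights planted pairs and flips signs", {
  fx <- rank1_blocks()
  fit <- spls_fit(fx$X, fx$Y, n_components = 1, keep_x = ncol(fx$X),
                  keep_y = ncol(fx$Y))
  sim <- spls_similarity(fit)
  expect_true(all(abs(sim) <= 1 + 1e-12))
  expect_gt(abs(sim["x1", "y1"]), 0.95)        # planted pair
  expect_gt(abs(sim["x1", "y1"]), abs(sim["x5", "y4"]))  # vs null pair
  # flipping one Y column flips its similarity column sign
  Y2 <- fx$Y; Y2[, 2] <- -Y2[, 2]
  sim2 <- spls_similarity(spls_fit(fx$X, Y2, 1, ncol(fx$X), ncol(fx$Y)))
  expect_equal(sim2[, 2], -sim[, 2], tolerance = 1e-6)
  # with near-noiseless blocks the best-coupled pair saturates toward 1
  fx3 <- rank1_blocks(noise = 0.003, seed = 5)
  sim3 <- spls_similarity(spls_fit(fx3$X, fx3$Y, 1, ncol(fx3$X), ncol(fx3$Y)))
  expect_gt(max(abs(sim3)), 0.99)
})

test_that("null blocks give uniformly weak similarities", {
  set.seed(10)
  Xn <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("x", 1:8)))
  Yn <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("y", 1:5)))
  sim_null <- spls_similarity(spls_fit(Xn, Yn, 1, 8, 5))
  fx <- rank1_blocks()
  sim_alt <- spls_similarity(spls_fit(fx$X, fx$Y, 1, ncol(fx$X), ncol(fx$Y)))
  expect_lt(quantile(abs(sim_null), 0.95), max(abs(sim_alt)))
})

test_that("spearman heatmap matches the rank formula and is symmetric", {
  A <- cbind(a1 = c(3, 1, 4, 1, 5, 9), a2 = c(2, 7, 1, 8, 2, 8))
  B <- cbind(b1 = exp(c(3, 1, 4, 1, 5, 9)), b2 = c(1, 2, 3, 4, 5, 6))
  am <- spearman_heatmap(A, B)
  expect_equal(unname(am$rho["a1", "b1"]), 1)   # monotone transform
  # hand d^2 formula on a tie-free 6-sample pair
  x <- c(3, 1, 4, 5, 9, 2); y <- c(1, 2, 3, 4, 6, 5)
  d2 <- sum((rank(x) - rank(y))^2)
  rho_hand <- 1 - 6 * d2 / (6 * (36 - 1))
  am2 <- spearman_heatmap(cbind(x = x), cbind(y = y))
  expect_equal(unname(am2$rho["x", "y"]), rho_hand)
  # transpose symmetry
  ab <- spearman_heatmap(A, B); ba <- spearman_heatmap(B, A)
  expect_equal(ab$rho, t(ba$rho))
  expect_equal(ab$fdr_p, t(ba$fdr_p))
})

test_that("heatmap handles missing values pairwise and flags short pairs", {
  A <- cbind(a = c(1, 2, 3, NA, 5, 6))
  B <- cbind(b = c(2, 4, 6, 8, NA, 12), c = c(NA, NA, NA, 1, 2, 3))
  am <- spearman_heatmap(A, B)
  expect_equal(unname(am$n_complete["a", "b"]), 4)
  expect_equal(unname(am$rho["a", "b"]), 1)
  expect_true(is.na(am$rho["a", "c"]))          # only 2 complete pairs
})

test_that("permuted-sample null keeps raw positive rate near alpha", {
  set.seed(12)
  hits <- 0; total <- 0
  for (s in 1:3) {
    A <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("a", 1:10)))
    B <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("b", 1:10)))
    am <- spearman_heatmap(A, B)
    hits <- hits + sum(am$p < 0.05); total <- total + length(am$p)
  }
  expect_lt(abs(hits / total - 0.05), 0.03)
})
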