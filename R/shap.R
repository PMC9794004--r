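# Random-forest regression of pathway scores on species abundances and
# Shapley attribution of species to the predicted pathway signal.
#
# The Shapley estimator is the model-agnostic permutation sampler: for each
# random feature ordering, features are switched one by one from a sampled
# background row to the explained sample's values and the marginal
# prediction changes are accumulated. Attributions are normalized post hoc
# so efficiency (sum phi = prediction - baseline) holds exactly, the
# residual being spread uniformly over features.

#' Fit a random-forest regression of a pathway score on species
#'
#' Standard regression forest (bootstrap per tree, variance-reduction
#' splits over `mtry` random features, minimum node size 5) via
#' \pkg{randomForest}; deterministic given `seed`. Out-of-bag R-squared is
#' reported.
#'
#' @param X numeric matrix, samples x species (no missing values, n >= 10).
#' @param y numeric response (e.g. a pathway activity score column).
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split (default floor(p / 3), min 1).
#' @param min_leaf minimum node size (default 5).
#' @param seed RNG seed.
#' @return object of class `forest_model`: `rf` (the fitted forest),
#'   `oob_r2`, training data, settings.
#' @export
fit_forest <- function(X, y, n_trees = 500, mtry = NULL, min_leaf = 5,
                       seed = 1) {
  X <- as.matrix(X)
  assert_that(nrow(X) >= 10, "need at least 10 samples")
  assert_that(!anyNA(X) && !anyNA(y), "missing values not allowed")
  assert_that(length(y) == nrow(X), "y not aligned to X")
  assert_that(sd(y) > 0, "constant response")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = as.numeric(y), ntree = n_trees,
                                   mtry = mtry, nodesize = min_leaf)
  oob_r2 <- 1 - rf$mse[n_trees] / mean((y - mean(y))^2)
  structure(list(rf = rf, oob_r2 = oob_r2, X = X, y = as.numeric(y),
                 n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                 seed = seed),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat("forest_model:", x$n_trees, "trees, mtry", x$mtry,
      sprintf("; OOB R2 = %.3f\n", x$oob_r2))
  invisible(x)
}

#' @export
predict.forest_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$X
  as.numeric(predict(object$rf, newdata = as.matrix(newdata)))
}

#' Monte-Carlo Shapley values for a fitted model
#'
#' Permutation-sampling estimator of the per-sample, per-feature Shapley
#' value of the model prediction relative to the mean prediction over the
#' background set. Each permutation draws one feature ordering and one
#' background row (shared across explained samples); phi is the average
#' marginal prediction change, then normalized so
#' `rowSums(phi) = prediction - baseline` exactly. Deterministic given
#' `seed`.
#'
#' @param model a `forest_model` (any object with a `predict` method over
#'   numeric matrices works).
#' @param X samples to explain (samples x features; defaults to training X).
#' @param background_X background set (defaults to training X).
#' @param n_permutations orderings per explanation (default 200).
#' @param seed RNG seed.
#' @return object of class `shapley_attribution`: `phi` (samples x
#'   features, in response units), `baseline`, `prediction`.
#' @export
shapley_values <- function(model, X = NULL, background_X = NULL,
                           n_permutations = 200, seed = 1) {
  assert_that(n_permutations >= 1, "n_permutations must be >= 1",
              class = "dualomics_parameter_error")
  if (is.null(X)) X <- model$X
  if (is.null(background_X)) background_X <- model$X
  X <- as.matrix(X); background_X <- as.matrix(background_X)
  assert_that(nrow(background_X) >= 1, "background set empty")
  n <- nrow(X); p <- ncol(X)
  phi <- matrix(0, n, p, dimnames = dimnames(X))
  set.seed(derive_seed(seed, 29L))
  bg_pred <- predict(model, background_X)
  baseline <- mean(bg_pred)
  for (t in seq_len(n_permutations)) {
    ord <- sample.int(p)
    b <- background_X[sample.int(nrow(background_X), 1), ]
    cur <- matrix(b, n, p, byrow = TRUE, dimnames = dimnames(X))
    prev <- predict(model, cur)
    for (j in ord) {
      cur[, j] <- X[, j]
      now <- predict(model, cur)
      phi[, j] <- phi[, j] + (now - prev)
      prev <- now
    }
  }
  phi <- phi / n_permutations
  pred <- predict(model, X)
  resid <- pred - baseline - rowSums(phi)
  phi <- phi + resid / p          # enforce efficiency exactly
  structure(list(phi = phi, baseline = baseline, prediction = pred,
                 n_permutations = n_permutations, seed = seed),
            class = "shapley_attribution")
}

#' @export
print.shapley_attribution <- function(x, ...) {
  cat("shapley_attribution:", nrow(x$phi), "samples x", ncol(x$phi),
      "features; baseline", signif(x$baseline, 4), "\n")
  invisible(x)
}

#' Compare per-sample Shapley values between groups
#'
#' Rank-sum test per species of the per-sample phi between GDM and NGT,
#' BH-adjusted across the tested species. Typically restricted (via
#' `species_filter`) to species already flagged as differentially abundant.
#'
#' @param attributions a `shapley_attribution`.
#' @param groups group labels per explained sample.
#' @param species_filter optional character vector of species to test.
#' @return a `diff_result` data.frame (fold change of mean phi; means can
#'   be negative, so interpret `fold_change` with care).
#' @export
compare_shapley_by_group <- function(attributions, groups,
                                     species_filter = NULL) {
  phi <- attributions$phi
  if (!is.null(species_filter)) {
    species_filter <- intersect(species_filter, colnames(phi))
    assert_that(length(species_filter) > 0,
                "species_filter matches no attributed species")
    phi <- phi[, species_filter, drop = FALSE]
  }
  wilcoxon_bh(phi, groups)
}
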