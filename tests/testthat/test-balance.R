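test_that("zero replacement is multiplicative and re-closes rows", {
  m <- rbind(S1 = c(0, 0.4, 0.6), S2 = c(0.1, 0.4, 0.5))
  colnames(m) <- c("A", "B", "C")
  tab <- abundance_table(m, closure = 1)
  rz <- replace_zeros(tab)
  # zero -> 0.05 (half of min positive 0.1), then re-closed
  expect_equal(unname(rz$values["S1", ]), c(0.05, 0.4, 0.6) / 1.05)
  expect_equal(rowSums(rz$values), c(S1 = 1, S2 = 1))
  pos <- random_table(3, 4, seed = 1)
  expect_equal(replace_zeros(pos)$values, pos$values, tolerance = 1e-12)
  m0 <- rbind(S1 = c(0, 0), S2 = c(1, 1))
  colnames(m0) <- c("A", "B")
  expect_error(replace_zeros(list(values = m0, closure = 1)), "all-zero")
})

test_that("balance scores match the closed-form and are scale invariant", {
  m <- rbind(S1 = c(A = 1, B = 4), S2 = c(A = 2, B = 2))
  tab <- list(values = close_rows <- m / rowSums(m), closure = 1)
  class(tab) <- "abundance_table"
  b <- balance_score(tab, "A", "B")
  expect_equal(unname(b["S1"]), sqrt(0.5) * (log(1) - log(4)))  # -0.9803...
  expect_equal(unname(b["S2"]), 0)
  # per-sample rescaling leaves the score unchanged
  tab10 <- tab; tab10$values <- tab$values * 10
  expect_equal(balance_score(tab10, "A", "B"), b)
  expect_error(balance_score(tab, c("A", "B"), "B"), "overlap")
  # compositional coherence on random tables
  for (s in 1:5) {
    tb <- random_table(6, 8, seed = s)
    num <- c("T01", "T03"); den <- c("T05", "T06", "T08")
    b1 <- balance_score(tb, num, den)
    scl <- tb; scl$values <- tb$values * runif(6, 0.5, 5)
    expect_equal(balance_score(scl, num, den), b1, tolerance = 1e-10)
  }
})

test_that("rank AUC equals trapezoidal ROC integration", {
  for (s in 1:20) {
    set.seed(s)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    sc <- rnorm(40) + y
    expect_equal(dualomics:::rank_auc(sc, y), oracle_auc_trapezoid(sc, y),
                 tolerance = 1e-12)
  }
})

test_that("greedy search at max_size 2 equals exhaustive pair search", {
  for (s in 1:6) {
    set.seed(s)
    n <- 40; k <- 15
    tab <- random_table(n, k, seed = 100 + s)
    L <- log(tab$values)
    y_bin <- as.integer(L[, 1] - L[, 2] + rnorm(n, 0, 0.5) > 0)
    if (length(unique(y_bin)) < 2) next
    got <- dualomics:::greedy_balance(L, y_bin, "binary", max_size = 2)
    ora <- oracle_best_pair(L, y_bin, "binary")
    expect_equal(got$criterion, ora$crit, tolerance = 1e-8)
    y_cont <- L[, 3] - L[, 4] + rnorm(n, 0, 0.5)
    got2 <- dualomics:::greedy_balance(L, y_cont, "continuous", max_size = 2)
    ora2 <- oracle_best_pair(L, y_cont, "continuous")
    expect_equal(got2$criterion, ora2$crit, tolerance = 1e-8)
    expect_setequal(c(got2$numerator, got2$denominator), c(ora2$num, ora2$den))
  }
})

test_that("a perfectly separating log-ratio reaches apparent AUC 1", {
  set.seed(8)
  tab <- random_table(30, 6, seed = 8)
  L <- log(tab$values)
  y <- ifelse(L[, 1] - L[, 2] > median(L[, 1] - L[, 2]), "GDM", "NGT")
  fit <- fit_balance(tab, y, "binary", max_size = 2, cv_repeats = 0)
  expect_equal(fit$apparent, 1.0)
  expect_error(balance_report(fit), "cross-validation")
  expect_error(fit_balance(tab, y, "binary", max_size = 1), "max_size")
  expect_error(fit_balance(tab, rep("GDM", 30), "binary"), "two classes")
  expect_error(fit_balance(tab, rep(1.5, 30), "continuous"), "variance")
})

test_that("planted balance taxa dominate CV selection on synthetic cohorts", {
  sim <- simulate_cohort(cohort_config(seed = 42))
  top <- select_top_taxa(sim$abundance, 50)
  pos <- replace_zeros(top)
  fit <- fit_balance(pos, sim$metadata$group, "binary",
                     cv_folds = 5, cv_repeats = 3, seed = 11)
  rep_ <- balance_report(fit, top_n = 20)
  planted <- sim$truth$differential_taxa$taxon
  expect_true(all(rep_$frequency$taxon[1:3] %in% planted))
  expect_gt(max(rep_$frequency$frequency), 0.75)
  expect_gt(fit$cv_criterion, 0.8)
  # at least half of the global balance comes from planted taxa
  glob <- c(rep_$global_numerator, rep_$global_denominator)
  expect_gte(mean(glob %in% planted), 0.5)
})

test_that("planted continuous coefficient is recovered within 2 SE at n = 500", {
  sim <- simulate_cohort(cohort_config(n_gdm = 250, n_ngt = 250, seed = 31))
  b <- sim$truth$balance$scores
  # condition on the intent group, whose intercept shift is part of the
  # generative model; the balance slope is then identified
  fit <- lm(sim$metadata$ogtt_glucose_1h ~ b + sim$truth$intent)
  est <- coef(summary(fit))["b", ]
  expect_lt(abs(est["Estimate"] - sim$truth$balance$coeff), 2 * est["Std. Error"])
})
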