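papi_fixture <- function() {
  v <- rbind(S1 = c(m1 = 1, m2 = 2, m3 = 5),
             S2 = c(m1 = 2, m2 = 2, m3 = 5),
             S3 = c(m1 = 3, m2 = 2, m3 = 5))
  pm <- data.frame(metabolite = c("m1", "m2", "c_unmeasured"),
                   pathway = c("P1", "P1", "P1"))
  metabolite_table(v, pm, pathway_sizes = c(P1 = 4))
}

test_that("metabolite normalization divides by the per-metabolite mean", {
  norm <- normalize_metabolites(papi_fixture())
  expect_equal(unname(norm$values[, "m1"]), c(0.5, 1.0, 1.5))
  expect_equal(unname(norm$values[, "m2"]), c(1, 1, 1))  # constant -> 1
  v <- rbind(S1 = c(m1 = 1, m0 = 0), S2 = c(m1 = 3, m0 = 0))
  expect_warning(n2 <- normalize_metabolites(metabolite_table(v)), "all-zero")
  expect_equal(colnames(n2$values), "m1")
  expect_error(normalize_metabolites(
    metabolite_table(rbind(S1 = c(m = 0), S2 = c(m = 0)))), "all-zero")
})

test_that("pathway activity is coverage-normalized summed abundance", {
  # two measured metabolites with normalized values 1.0 and 0.5, K = 4
  v <- rbind(S1 = c(m1 = 2, m2 = 1), S2 = c(m1 = 2, m2 = 3))
  pm <- data.frame(metabolite = c("m1", "m2"), pathway = c("P1", "P1"))
  mt <- metabolite_table(v, pm, pathway_sizes = c(P1 = 4))
  norm <- normalize_metabolites(mt)
  ps <- pathway_activity(norm)
  expect_equal(unname(ps$scores["S1", "P1"]), (1.0 + 0.5) / 4)  # = 0.375
  expect_equal(ps$k_detected[["P1"]], 2L)
  # linearity: doubling all normalized abundances doubles the score
  norm2 <- norm; norm2$values <- 2 * norm$values
  expect_equal(pathway_activity(norm2)$scores, 2 * ps$scores)
  # all mapped metabolites zero in a sample -> score 0
  v3 <- rbind(S1 = c(m1 = 0, m2 = 0), S2 = c(m1 = 2, m2 = 2))
  ps3 <- pathway_activity(normalize_metabolites(
    metabolite_table(v3, pm, pathway_sizes = c(P1 = 4))))
  expect_equal(unname(ps3$scores["S1", "P1"]), 0)
  # coverage monotonicity: smaller K (fewer unmeasured compounds) raises AS
  mt_small <- metabolite_table(v, pm, pathway_sizes = c(P1 = 3))
  ps_small <- pathway_activity(normalize_metabolites(mt_small))
  expect_true(all(ps_small$scores > ps$scores))
  # unknown pathway size is an error naming the pathway
  pm2 <- rbind(pm, data.frame(metabolite = "m2", pathway = "P9"))
  expect_error(pathway_activity(normalize_metabolites(
    metabolite_table(v, pm2, pathway_sizes = c(P1 = 4)))), "P9")
})

test_that("the shipped synthetic dopamine fixture scores end to end", {
  mt <- read_metabolite_table(
    system.file("extdata", "synthetic_metabolites.tsv", package = "dualomics"),
    system.file("extdata", "synthetic_pathway_map.tsv", package = "dualomics"),
    system.file("extdata", "synthetic_pathway_sizes.tsv", package = "dualomics"))
  expect_equal(dim(mt$values), c(6L, 6L))
  expect_false(all(mt$pathway_map$measured))  # unmeasured compounds flagged
  ps <- pathway_activity(normalize_metabolites(mt))
  expect_setequal(colnames(ps$scores),
                  c("Dopaminergic synapse", "Isoquinoline alkaloid biosynthesis",
                    "Betalain biosynthesis"))
  # only measured metabolites contribute; K_total from the sizes file
  x <- ps$scores["S001", "Dopaminergic synapse"]
  nm <- normalize_metabolites(mt)$values
  expect_equal(unname(x),
               sum(nm["S001", c("Dopamine", "L-DOPA", "Homovanillic acid")]) / 12)
})

test_that("score ordering is invariant to metabolite column permutation", {
  set.seed(3)
  v <- matrix(runif(40, 1, 5), 8, 5,
              dimnames = list(paste0("S", 1:8), paste0("m", 1:5)))
  pm <- data.frame(metabolite = paste0("m", 1:5),
                   pathway = c("P1", "P1", "P2", "P2", "P2"))
  mt <- metabolite_table(v, pm, pathway_sizes = c(P1 = 3, P2 = 5))
  perm <- sample(5)
  mtp <- metabolite_table(v[, perm], pm, pathway_sizes = c(P1 = 3, P2 = 5))
  s1 <- pathway_activity(normalize_metabolites(mt))$scores
  s2 <- pathway_activity(normalize_metabolites(mtp))$scores
  expect_equal(s1, s2[, colnames(s1)])
})

test_that("pathway score comparison shares wilcoxon_bh semantics", {
  set.seed(5)
  scores <- matrix(runif(60), 20, 3,
                   dimnames = list(paste0("S", 1:20), paste0("P", 1:3)))
  g <- rep(c("GDM", "NGT"), each = 10)
  res <- compare_pathway_scores(scores, g)
  ora <- wilcoxon_bh(scores, g)
  expect_equal(res$p_value, ora$p_value)
  expect_equal(res$fdr_p, ora$fdr_p)
  # identical distributions per group: nothing passes discovery FDR
  sym <- rbind(scores[1:10, ], scores[1:10, ])
  rownames(sym) <- paste0("S", 1:20)
  res_sym <- suppressWarnings(compare_pathway_scores(sym, g))
  expect_false(any(res_sym$flag_discovery))
  # single pathway: fdr equals p
  one <- compare_pathway_scores(scores[, 1, drop = FALSE], g)
  expect_equal(one$fdr_p, one$p_value)
})
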