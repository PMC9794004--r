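test_that("build_network equals brute-force all-pairs computation", {
  for (s in 1:5) {
    set.seed(s)
    n <- 20; k <- sample(4:6, 1)
    m <- matrix(rnorm(n * k), n, k,
                dimnames = list(paste0("S", 1:n), paste0("T", 1:k)))
    for (fdr in c(TRUE, FALSE)) {
      net <- build_network(list(values = m), rho_min = 0.2, alpha = 0.3,
                           fdr_correct = fdr)
      ora <- oracle_network_edges(m, 0.2, 0.3, fdr)
      key <- function(df) sort(paste(df$u, df$v))
      expect_equal(key(net$edges), key(ora))
      ord_net <- order(net$edges$u, net$edges$v)
      ord_ora <- order(ora$u, ora$v)
      expect_equal(net$edges$rho[ord_net], ora$rho[ord_ora],
                   tolerance = 1e-12)
    }
  }
})

test_that("edge thresholds are strict: rho exactly at the cutoff is excluded", {
  set.seed(2)
  m <- cbind(A = rnorm(12), B = rnorm(12), C = rnorm(12))
  m[, "B"] <- m[, "A"] + rnorm(12, 0, 1)
  rownames(m) <- paste0("S", 1:12)
  all_edges <- build_network(list(values = m), rho_min = 0, alpha = 1,
                             fdr_correct = FALSE)
  ab <- all_edges$edges[all_edges$edges$u == "A" & all_edges$edges$v == "B", ]
  expect_equal(nrow(ab), 1L)
  # set the cutoff to the observed |rho|: strict > must drop the edge
  at_cut <- build_network(list(values = m), rho_min = abs(ab$rho), alpha = 1,
                          fdr_correct = FALSE)
  expect_false(any(at_cut$edges$u == "A" & at_cut$edges$v == "B"))
  below <- build_network(list(values = m), rho_min = abs(ab$rho) - 1e-9,
                         alpha = 1, fdr_correct = FALSE)
  expect_true(any(below$edges$u == "A" & below$edges$v == "B"))
})

test_that("perfectly monotone pair is always an edge; noise pairs rarely", {
  hit_ab <- 0; false_edges <- 0; trials <- 40
  for (s in 1:trials) {
    set.seed(s)
    m <- cbind(A = rnorm(30), C = rnorm(30), D = rnorm(30))
    m <- cbind(m, B = exp(m[, "A"]))  # monotone in A
    rownames(m) <- paste0("S", 1:30)
    net <- build_network(list(values = m), rho_min = 0.3, alpha = 0.05,
                         fdr_correct = FALSE)
    key <- paste(net$edges$u, net$edges$v)
    if ("A B" %in% key || "B A" %in% key) hit_ab <- hit_ab + 1
    false_edges <- false_edges +
      sum(!(key %in% c("A B", "B A")))
  }
  expect_equal(hit_ab, trials)
  # 5 independent pairs per trial at alpha 0.05 (and |rho|>0.3): rare
  expect_lt(false_edges / (5 * trials), 0.06)
})

test_that("graph metrics match hand-computed values on toy graphs", {
  tri <- cooccurrence_network(c("a", "b", "c"), data.frame(
    u = c("a", "a", "b"), v = c("b", "c", "c"), rho = rep(0.5, 3)))
  gm <- graph_metrics(tri)
  expect_equal(gm$global_transitivity, 1)
  expect_equal(gm$node_metrics$strength, rep(1.0, 3))
  expect_equal(gm$node_metrics$eigenvector, rep(1 / sqrt(3), 3),
               tolerance = 1e-8)
  # closeness in triangle: both neighbors at distance 0.5 -> 2/1.0 = 2
  expect_equal(gm$node_metrics$closeness, rep(2, 3))

  path3 <- cooccurrence_network(c("a", "b", "c"), data.frame(
    u = c("a", "b"), v = c("b", "c"), rho = c(0.5, -0.5)))
  gp <- graph_metrics(path3)
  expect_equal(gp$global_transitivity, 0)
  expect_equal(gp$node_metrics$strength, c(0.5, 1.0, 0.5))
  # ends: distances 0.5 and 1.0 -> 2/1.5; middle: 2/1.0
  expect_equal(gp$node_metrics$closeness, c(2 / 1.5, 2, 2 / 1.5))

  two <- cooccurrence_network(c("a", "b", "z"), data.frame(
    u = "a", v = "b", rho = 0.5))
  gt <- graph_metrics(two)
  expect_equal(gt$node_metrics$closeness, c(2, 2, 0))  # 1/0.5 and isolate

  empty <- cooccurrence_network(c("a", "b"), data.frame(
    u = character(0), v = character(0), rho = numeric(0)))
  expect_warning(ge <- graph_metrics(empty))
  expect_equal(ge$global_transitivity, 0)
  expect_equal(ge$node_metrics$eigenvector, c(0, 0))
})

test_that("eigenvector centrality is invariant to uniform weight scaling", {
  set.seed(9)
  ed <- data.frame(u = c("a", "a", "b", "c"), v = c("b", "c", "d", "d"),
                   rho = runif(4, 0.3, 0.9))
  n1 <- cooccurrence_network(letters[1:4], ed)
  ed2 <- ed; ed2$rho <- ed2$rho / 2
  n2 <- cooccurrence_network(letters[1:4], ed2)
  expect_equal(graph_metrics(n1)$node_metrics$eigenvector,
               graph_metrics(n2)$node_metrics$eigenvector, tolerance = 1e-10)
  # closeness strictly decreases when a used edge weakens
  ed3 <- ed; ed3$rho[1] <- 0.2
  n3 <- cooccurrence_network(letters[1:4], ed3)
  expect_lt(graph_metrics(n3)$node_metrics$closeness[1],
            graph_metrics(n1)$node_metrics$closeness[1])
})

test_that("core species ranking uses degree, then strength, then name", {
  star <- cooccurrence_network(c("hub", "x", "y", "z"), data.frame(
    u = rep("hub", 3), v = c("x", "y", "z"), rho = c(0.4, 0.5, 0.6)))
  cs <- core_species(star)
  expect_equal(cs$by_degree$node[1], "hub")
  # degree tie between x, y, z broken by strength (z strongest)
  expect_equal(cs$by_degree$node[2], "z")
  tie <- cooccurrence_network(c("a", "b", "c", "d"), data.frame(
    u = c("a", "c"), v = c("b", "d"), rho = c(0.9, 0.4)))
  ct <- core_species(tie)
  expect_equal(ct$by_degree$node[1:2], c("a", "b"))  # higher strength first
  expect_equal(core_species(star, top_n = 2)$by_degree$node,
               c("hub", "z"))
  none <- cooccurrence_network(character(0),
                               data.frame(u = character(0), v = character(0),
                                          rho = numeric(0)))
  expect_equal(nrow(suppressWarnings(core_species(none))$by_degree), 0L)
})
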