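# Small in-code fixtures shared across test files.

# samples x taxa abundance_table from a plain matrix, closed to `closure`.
make_table <- function(m, closure = 1) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("T%02d", seq_len(ncol(m)))
  abundance_table(m / rowSums(m) * closure, closure = closure)
}

# Random strictly positive composition for property tests.
random_table <- function(n, k, seed, closure = 1) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * k)), n, k,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("T%02d", seq_len(k))))
  make_table(m, closure)
}

# Write a tiny MetaPhlAn-style TSV; returns its path.
write_metaphlan_fixture <- function(path = tempfile(fileext = ".tsv")) {
  lines <- c(
    paste(c("clade_name", "S1", "S2"), collapse = "\t"),
    paste(c("k__Bacteria|p__Bacteroidetes", "60", "35"), collapse = "\t"),
    paste(c("k__Bacteria|p__Bacteroidetes|g__Bacteroides|s__Bacteroides_dorei",
            "40", "25"), collapse = "\t"),
    paste(c("k__Bacteria|p__Bacteroidetes|g__Prevotella|s__Prevotella_copri",
            "60", "75"), collapse = "\t"))
  writeLines(lines, path)
  path
}

# Fast forest for Shapley tests (small but deterministic).
small_forest <- function(n = 60, p = 6, seed = 4, n_trees = 60) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- 2 * X[, 1] + X[, 2] + rnorm(n, 0, 0.1)
  fit_forest(X, y, n_trees = n_trees, seed = seed)
}
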