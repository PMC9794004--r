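# Shared validation and small numeric helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dual <- function(..., class) {
  stop(structure(class = c(class, "dualomics_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ..., class = "dualomics_validation_error") {
  if (!isTRUE(ok)) stop_dual(..., class = class)
  invisible(TRUE)
}

# Matrix view of an abundance/metabolite table (samples x features).
values_of <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x) && is.matrix(x$values)) return(x$values)
  stop_dual("expected a matrix or a table object with a $values matrix",
            class = "dualomics_validation_error")
}

# Close each row (sample) of a non-negative matrix to `closure`.
close_rows <- function(m, closure = 1) {
  rs <- rowSums(m)
  assert_that(all(rs > 0), "cannot close rows with zero total abundance")
  m / rs * closure
}

# Deterministic child seeds below 2^31 for staged RNG.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919) %% 2147483647)
}
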