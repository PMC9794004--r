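# Greedy log-ratio balance selection with cross-validation, linking
# microbial signatures to GDM status and OGTT glucose.
#
# A balance over disjoint taxon sets (N, D) scores sample s as
#   B(s) = sqrt(k1*k2/(k1+k2)) * (mean log x_N - mean log x_D),
# a normalized log-contrast that is invariant to per-sample rescaling of
# the composition. The greedy forward search mirrors the selbal family:
# best single (numerator, denominator) pair by criterion, then repeated
# addition of the taxon/side that most improves it.

#' Replace zeros for log-ratio analysis
#'
#' Multiplicative replacement: zeros become half the smallest positive
#' value in the whole table; rows are then re-closed to the table's
#' closure constant.
#'
#' @param table an [abundance_table] (non-negative).
#' @return a strictly positive [abundance_table].
#' @export
replace_zeros <- function(table) {
  m <- values_of(table)
  closure <- if (is.list(table)) table$closure %||% 1 else 1
  assert_that(all(rowSums(m) > 0), "all-zero sample row")
  pos <- m[m > 0]
  if (any(m == 0)) m[m == 0] <- min(pos) / 2
  out <- if (is.list(table)) table else list(values = NULL, closure = closure)
  out$values <- close_rows(m, closure)
  class(out) <- "abundance_table"
  out
}

#' Balance score of two taxon sets
#'
#' @param table strictly positive [abundance_table] (see [replace_zeros()]).
#' @param numerator,denominator disjoint, non-empty character vectors of
#'   taxon names.
#' @return named numeric vector of per-sample scores (natural log).
#' @export
balance_score <- function(table, numerator, denominator) {
  m <- values_of(table)
  assert_that(length(numerator) > 0 && length(denominator) > 0,
              "numerator and denominator must be non-empty")
  assert_that(length(intersect(numerator, denominator)) == 0,
              "numerator and denominator overlap")
  assert_that(all(c(numerator, denominator) %in% colnames(m)),
              "balance taxa missing from table")
  assert_that(all(m[, c(numerator, denominator)] > 0),
              "table must be strictly positive; run replace_zeros() first")
  L <- log(m)
  k1 <- length(numerator); k2 <- length(denominator)
  sqrt(k1 * k2 / (k1 + k2)) *
    (rowMeans(L[, numerator, drop = FALSE]) -
       rowMeans(L[, denominator, drop = FALSE]))
}

# Rank AUC of score s for binary y (1 = case). Directional: > 0.5 means
# cases score higher. Equals trapezoidal ROC integration.
rank_auc <- function(s, y) {
  r <- rank(s)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Criterion for a matrix of candidate scores (columns), higher is better.
crit_cols <- function(S, y, type) {
  S <- as.matrix(S)
  if (type == "binary") {
    apply(S, 2, rank_auc, y = y)
  } else {
    v <- suppressWarnings(as.numeric(cor(S, y)))
    v[is.na(v)] <- 0
    v^2
  }
}

# Greedy forward balance search on a log-abundance matrix.
greedy_balance <- function(L, y, type, max_size = 8, tol = 1e-4) {
  taxa <- colnames(L)
  k <- ncol(L)
  best <- list(crit = -Inf)
  for (i in seq_len(k)) {
    D <- L - L[, i]                     # col j: num = {j}, den = {i}
    cr <- crit_cols(D[, -i, drop = FALSE], y, type)
    cand <- taxa[-i]
    ord <- order(-cr, cand)
    if (cr[ord[1]] > best$crit + 1e-12 ||
        (abs(cr[ord[1]] - best$crit) <= 1e-12 && is.finite(best$crit) &&
         paste(cand[ord[1]], taxa[i]) < paste(best$num, best$den))) {
      best <- list(num = cand[ord[1]], den = taxa[i], crit = cr[ord[1]])
    }
  }
  num <- best$num; den <- best$den; crit <- best$crit
  repeat {
    if (length(num) + length(den) >= max_size) break
    free <- setdiff(taxa, c(num, den))
    if (length(free) == 0) break
    mN <- rowMeans(L[, num, drop = FALSE])
    mD <- rowMeans(L[, den, drop = FALSE])
    k1 <- length(num); k2 <- length(den)
    Snum <- (k1 * mN + L[, free, drop = FALSE]) / (k1 + 1) - mD
    Sden <- mN - (k2 * mD + L[, free, drop = FALSE]) / (k2 + 1)
    crN <- crit_cols(Snum, y, type)
    crD <- crit_cols(Sden, y, type)
    cand <- data.frame(taxon = rep(free, 2),
                       side = rep(c("num", "den"), each = length(free)),
                       crit = c(crN, crD), stringsAsFactors = FALSE)
    cand <- cand[order(-cand$crit, cand$taxon, cand$side), ]
    if (cand$crit[1] <= crit + tol) break
    if (cand$side[1] == "num") num <- c(num, cand$taxon[1]) else
      den <- c(den, cand$taxon[1])
    crit <- cand$crit[1]
  }
  list(numerator = sort(num), denominator = sort(den),
       criterion = unname(crit))
}

stratified_folds <- function(y, k, type) {
  n <- length(y)
  fold <- integer(n)
  if (type == "binary") {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Fit a microbial balance by greedy search with cross-validation
#'
#' Greedy forward selection of a log-ratio balance maximizing AUC (binary
#' response, logistic association) or R-squared (continuous response,
#' linear association). Repeated k-fold cross-validation (stratified for
#' binary responses) reruns the whole search per training fold to
#' accumulate per-taxon selection frequencies and an out-of-sample
#' criterion; the global balance is fit on all samples.
#'
#' @param table strictly positive [abundance_table] (see [replace_zeros()]);
#'   restrict to a top-k universe first ([select_top_taxa()]) for large
#'   tables.
#' @param response binary (two-level factor/character/0-1) or numeric
#'   vector aligned to samples.
#' @param response_type "binary" or "continuous".
#' @param max_size maximum balance size (numerator + denominator, >= 2).
#' @param cv_folds,cv_repeats cross-validation design (default 5 x 10).
#' @param seed RNG seed for fold assignment.
#' @param case_label level treated as the positive class for binary
#'   responses; defaults to "GDM" when present, else the second sorted level.
#' @param tol criterion improvement tolerance in the greedy step.
#' @return object of class `balance_cv`: `frequency` (per-taxon selection
#'   frequencies with side counts), `global` (numerator, denominator,
#'   per-sample scores, fitted model), `apparent` and `cv_criterion`
#'   (AUC or R-squared), `cv_values`, `mse` (continuous), settings.
#' @export
fit_balance <- function(table, response, response_type = c("binary", "continuous"),
                        max_size = 8, cv_folds = 5, cv_repeats = 10, seed = 1,
                        case_label = NULL, tol = 1e-4) {
  response_type <- match.arg(response_type)
  m <- values_of(table)
  assert_that(all(m > 0), "table must be strictly positive; run replace_zeros()")
  assert_that(max_size >= 2, "max_size must be >= 2",
              class = "dualomics_parameter_error")
  assert_that(length(response) == nrow(m), "response not aligned to samples")
  if (response_type == "binary") {
    rv <- as.character(response)
    lev <- sort(unique(rv))
    assert_that(length(lev) == 2, "binary response needs exactly two classes")
    if (is.null(case_label)) case_label <- if ("GDM" %in% lev) "GDM" else lev[2]
    y <- as.integer(rv == case_label)
  } else {
    y <- as.numeric(response)
    assert_that(sd(y) > 0, "response has zero variance")
  }
  L <- log(m)
  taxa <- colnames(L)

  global_sets <- greedy_balance(L, y, response_type, max_size, tol)
  gscore <- balance_score(table, global_sets$numerator, global_sets$denominator)
  if (response_type == "binary") {
    fit <- suppressWarnings(glm(y ~ gscore, family = binomial()))
    cf <- coef(fit)
    cf[abs(cf) > 20] <- sign(cf[abs(cf) > 20]) * 20  # separation guard
    apparent <- rank_auc(gscore, y)
    mse <- NA_real_
  } else {
    fit <- lm(y ~ gscore)
    cf <- coef(fit)
    apparent <- suppressWarnings(cor(gscore, y))^2
    mse <- mean(fit$residuals^2)
  }

  n_fits <- cv_folds * cv_repeats
  sel <- matrix(0, length(taxa), 2, dimnames = list(taxa, c("num", "den")))
  cv_values <- numeric(0)
  if (cv_repeats > 0) {
    set.seed(derive_seed(seed, 17L))
    for (rep_i in seq_len(cv_repeats)) {
      fold <- stratified_folds(y, cv_folds, response_type)
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        if (response_type == "binary" && length(unique(y[tr])) < 2) next
        bs <- greedy_balance(L[tr, , drop = FALSE], y[tr], response_type,
                             max_size, tol)
        sel[bs$numerator, "num"] <- sel[bs$numerator, "num"] + 1
        sel[bs$denominator, "den"] <- sel[bs$denominator, "den"] + 1
        k1 <- length(bs$numerator); k2 <- length(bs$denominator)
        bt <- sqrt(k1 * k2 / (k1 + k2)) *
          (rowMeans(L[!tr, bs$numerator, drop = FALSE]) -
             rowMeans(L[!tr, bs$denominator, drop = FALSE]))
        if (response_type == "binary") {
          if (length(unique(y[!tr])) < 2) next
          cv_values <- c(cv_values, rank_auc(bt, y[!tr]))
        } else {
          btr <- sqrt(k1 * k2 / (k1 + k2)) *
            (rowMeans(L[tr, bs$numerator, drop = FALSE]) -
               rowMeans(L[tr, bs$denominator, drop = FALSE]))
          lmfit <- lm(y[tr] ~ btr)
          pred <- coef(lmfit)[1] + coef(lmfit)[2] * bt
          cv_values <- c(cv_values,
                         1 - sum((y[!tr] - pred)^2) / sum((y[!tr] - mean(y[tr]))^2))
        }
      }
    }
  }
  freq <- data.frame(taxon = taxa,
                     frequency = (sel[, 1] + sel[, 2]) / max(n_fits, 1),
                     freq_numerator = sel[, 1] / max(n_fits, 1),
                     freq_denominator = sel[, 2] / max(n_fits, 1),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(frequency = freq,
                 global = list(numerator = global_sets$numerator,
                               denominator = global_sets$denominator,
                               scores = gscore, coefficients = cf),
                 apparent = apparent,
                 cv_criterion = if (length(cv_values)) mean(cv_values) else NA_real_,
                 cv_values = cv_values, mse = mse,
                 response_type = response_type,
                 criterion_name = if (response_type == "binary") "AUC" else "R2",
                 case_label = if (response_type == "binary") case_label else NA,
                 n_fits = if (cv_repeats > 0) n_fits else 0L,
                 max_size = max_size, cv_folds = cv_folds,
                 cv_repeats = cv_repeats, seed = seed),
            class = "balance_cv")
}

#' @export
print.balance_cv <- function(x, ...) {
  cat("balance_cv (", x$response_type, " response)\n", sep = "")
  cat("  numerator:  ", paste(x$global$numerator, collapse = ", "), "\n")
  cat("  denominator:", paste(x$global$denominator, collapse = ", "), "\n")
  cat(sprintf("  apparent %s = %.3f; cross-validated %s = %.3f (%d fits)\n",
              x$criterion_name, x$apparent, x$criterion_name,
              x$cv_criterion, x$n_fits))
  invisible(x)
}

#' Ranked selection-frequency report for a fitted balance
#'
#' @param cv a `balance_cv` from [fit_balance()] (with at least one CV fit).
#' @param top_n number of taxa to report (default 20).
#' @return list: `frequency` (top taxa with dominant side annotation),
#'   `global_numerator`, `global_denominator`, `apparent`, `cv_criterion`.
#' @export
balance_report <- function(cv, top_n = 20) {
  assert_that(inherits(cv, "balance_cv"), "cv must be a balance_cv")
  assert_that(cv$n_fits > 0, "no cross-validation fits available")
  fr <- cv$frequency
  fr$side <- ifelse(fr$freq_numerator >= fr$freq_denominator, "numerator",
                    "denominator")
  fr <- fr[order(-fr$frequency, fr$taxon), ]
  fr <- fr[fr$frequency > 0, , drop = FALSE]
  list(frequency = head(fr, n = min(top_n, nrow(fr))),
       global_numerator = cv$global$numerator,
       global_denominator = cv$global$denominator,
       apparent = cv$apparent,
       cv_criterion = cv$cv_criterion,
       criterion_name = cv$criterion_name)
}
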