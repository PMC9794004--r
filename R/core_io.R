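# Data model and readers/writers shared by all pipeline stages.
#
# All tables are stored samples-as-rows internally; on-disk conventions
# follow the field (MetaPhlAn TSV is taxa-as-rows and is transposed on read).

RANK_PREFIX <- c(kingdom = "k__", phylum = "p__", class = "c__",
                 order = "o__", family = "f__", genus = "g__",
                 species = "s__", strain = "t__")

#' Construct an abundance table
#'
#' A compositional table of relative abundances, samples as rows, taxa as
#' columns. Each sample row sums (within tolerance) to a common closure
#' constant, 1 or 100.
#'
#' @param values numeric matrix, samples x taxa, with dimnames.
#' @param closure closure constant; inferred from the median row sum
#'   (nearest of 1 and 100) when `NULL`.
#' @param tol relative tolerance on per-sample sums (fraction of closure).
#' @param renormalize re-close rows exactly to `closure` instead of
#'   requiring sums to already match.
#' @return object of class `abundance_table` with elements `values` and
#'   `closure`.
#' @export
abundance_table <- function(values, closure = NULL, tol = 0.005,
                            renormalize = FALSE) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must have sample rownames and taxon colnames")
  assert_that(!anyNA(values), "abundance values must not be missing")
  assert_that(all(values >= 0), "abundance values must be non-negative")
  assert_that(!anyDuplicated(rownames(values)), "duplicate sample identifiers")
  assert_that(!anyDuplicated(colnames(values)), "duplicate taxon identifiers")
  rs <- rowSums(values)
  if (is.null(closure)) closure <- if (abs(median(rs) - 100) < abs(median(rs) - 1)) 100 else 1
  if (renormalize) {
    values <- close_rows(values, closure)
  } else {
    assert_that(all(abs(rs - closure) <= tol * closure),
                "per-sample sums deviate from closure ", closure,
                " by more than tolerance; set renormalize = TRUE to re-close")
  }
  structure(list(values = values, closure = closure), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table:", nrow(x$values), "samples x", ncol(x$values),
      "taxa (closure =", x$closure, ")\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Construct a metabolite table
#'
#' Samples x annotated metabolites, arbitrary non-negative instrument units,
#' with an optional metabolite-to-pathway map and pathway compound counts.
#'
#' @param values numeric matrix, samples x metabolites, with dimnames.
#' @param pathway_map data.frame with columns `metabolite`, `pathway`
#'   (one row per membership), or `NULL`.
#' @param pathway_sizes named numeric vector: total compound count per
#'   pathway (must cover every pathway in `pathway_map` and be at least the
#'   measured-metabolite count of that pathway).
#' @return object of class `metabolite_table`.
#' @export
metabolite_table <- function(values, pathway_map = NULL, pathway_sizes = NULL) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must have sample rownames and metabolite colnames")
  assert_that(all(values >= 0, na.rm = TRUE), "metabolite values must be non-negative")
  assert_that(!anyDuplicated(colnames(values)), "duplicate metabolite identifiers")
  if (!is.null(pathway_map)) {
    assert_that(all(c("metabolite", "pathway") %in% names(pathway_map)),
                "pathway_map needs columns metabolite, pathway")
    measured <- pathway_map$metabolite %in% colnames(values)
    pathway_map$measured <- measured
    if (!is.null(pathway_sizes)) {
      miss <- setdiff(unique(pathway_map$pathway), names(pathway_sizes))
      assert_that(length(miss) == 0,
                  "pathway size unknown for: ", paste(miss, collapse = ", "))
      k_meas <- table(pathway_map$pathway[measured])
      bad <- names(k_meas)[pathway_sizes[names(k_meas)] < as.numeric(k_meas)]
      assert_that(length(bad) == 0,
                  "pathway size smaller than measured-metabolite count for: ",
                  paste(bad, collapse = ", "))
    }
  }
  structure(list(values = values, pathway_map = pathway_map,
                 pathway_sizes = pathway_sizes),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("metabolite_table:", nrow(x$values), "samples x", ncol(x$values),
      "metabolites;", if (is.null(x$pathway_map)) "no" else
        length(unique(x$pathway_map$pathway)), "pathways mapped\n")
  invisible(x)
}

parse_clade <- function(clade) {
  # MetaPhlAn lineage string k__...|p__...|...|s__name, or a bare name.
  last <- vapply(strsplit(clade, "|", fixed = TRUE), function(p) p[length(p)], "")
  pref <- substr(last, 1, 3)
  known <- pref %in% RANK_PREFIX
  rank <- rep(NA_character_, length(clade))
  rank[known] <- names(RANK_PREFIX)[match(pref[known], RANK_PREFIX)]
  name <- last
  name[known] <- substring(last[known], 4)
  data.frame(name = name, rank = rank, stringsAsFactors = FALSE)
}

#' Read a MetaPhlAn-style relative abundance table
#'
#' Accepts taxa-as-rows TSV whose first column holds either full-lineage
#' clade strings (`k__...|p__...|s__name`) or bare taxon names; remaining
#' columns are samples. Rows with an inferable rank are filtered to the
#' requested rank; bare-name rows (no rank prefix anywhere) are kept as-is.
#'
#' @param path TSV file path.
#' @param rank taxonomic rank to retain ("species", "genus", "phylum", ...).
#' @inheritParams abundance_table
#' @return an [abundance_table] (samples x taxa).
#' @export
read_abundance_table <- function(path, rank = "species", closure = NULL,
                                 tol = 0.005, renormalize = FALSE) {
  assert_that(rank %in% names(RANK_PREFIX), "unknown rank: ", rank)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  assert_that(ncol(df) >= 2, "malformed header: need taxon column plus samples",
              class = "dualomics_format_error")
  assert_that(!anyDuplicated(names(df)[-1]), "duplicate sample column")
  info <- parse_clade(df[[1]])
  keep <- is.na(info$rank) | info$rank == rank
  df <- df[keep, , drop = FALSE]
  info <- info[keep, , drop = FALSE]
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  assert_that(is.numeric(m), "non-numeric abundance values",
              class = "dualomics_format_error")
  colnames(m) <- info$name
  abundance_table(m, closure = closure, tol = tol, renormalize = renormalize)
}

#' Write an abundance table as MetaPhlAn-style TSV (taxa as rows)
#'
#' @param table an [abundance_table].
#' @param path output path.
#' @export
write_abundance_table <- function(table, path) {
  m <- t(values_of(table))
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metabolite abundance table plus pathway annotation
#'
#' @param path metabolite TSV/CSV, metabolites as rows, samples as columns,
#'   first column metabolite name; separator inferred from the extension.
#' @param pathway_map_path optional 2-column TSV (metabolite, pathway).
#' @param sizes_path optional 2-column TSV (pathway, size).
#' @return a [metabolite_table].
#' @export
read_metabolite_table <- function(path, pathway_map_path = NULL,
                                  sizes_path = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df[[1]]
  pm <- NULL
  sizes <- NULL
  if (!is.null(pathway_map_path)) {
    pm <- read.table(pathway_map_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, quote = "")
    names(pm)[1:2] <- c("metabolite", "pathway")
  }
  if (!is.null(sizes_path)) {
    sz <- read.table(sizes_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, quote = "")
    sizes <- setNames(as.numeric(sz[[2]]), sz[[1]])
  }
  metabolite_table(m, pathway_map = pm, pathway_sizes = sizes)
}

#' Read a sample metadata table
#'
#' Comma- or tab-separated, one row per sample. Requires columns
#' `sample_id` and `group` (values GDM/NGT); clinical columns (OGTT glucose
#' at 0/1/2 h, insulin, HbA1c, BMI, blood counts) are kept as provided.
#'
#' @param path CSV/TSV path.
#' @param glucose_unit unit tag for the OGTT glucose columns
#'   ("mg/dL" or "mmol/L"); recorded as an attribute.
#' @return data.frame with attribute `glucose_unit`.
#' @export
read_metadata <- function(path, glucose_unit = "mg/dL") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "\"")
  assert_that(all(c("sample_id", "group") %in% names(df)),
              "metadata needs sample_id and group columns")
  assert_that(!anyNA(df$group), "group label missing for some samples")
  attr(df, "glucose_unit") <- glucose_unit
  df
}

#' Select the most abundant taxa
#'
#' Taxa are ranked by mean relative abundance across all samples (groups
#' pooled); ties at the cutoff are broken by taxon name so selection is
#' deterministic.
#'
#' @param table an [abundance_table].
#' @param k number of taxa to keep.
#' @return an [abundance_table] restricted to the top `k` taxa.
#' @export
select_top_taxa <- function(table, k) {
  m <- values_of(table)
  assert_that(is.numeric(k) && length(k) == 1 && k > 0,
              "k must be a positive count", class = "dualomics_parameter_error")
  assert_that(k <= ncol(m), "k exceeds the number of taxa",
              class = "dualomics_parameter_error")
  mu <- colMeans(m)
  ord <- order(-mu, colnames(m))
  keep <- sort(ord[seq_len(k)])  # preserve original column order
  out <- table
  out$values <- m[, keep, drop = FALSE]
  out
}

#' Write a result table to TSV
#'
#' Writes any result data.frame (differential tests, network edge lists,
#' association matrices in long form) with a header and no row names, so a
#' round-trip read reproduces it within float precision.
#'
#' @param results data.frame.
#' @param path output TSV path.
#' @export
write_results <- function(results, path) {
  assert_that(is.data.frame(results), "results must be a data.frame")
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE, quote = "")
}

#' Collapse a species-level table to genus level
#'
#' Species named "Genus species" (or MetaPhlAn "Genus_species") are summed
#' by their leading genus token, without renormalization.
#'
#' @param table an [abundance_table] at species level.
#' @return an [abundance_table] of genus aggregates.
#' @export
collapse_to_genus <- function(table) {
  m <- values_of(table)
  genus <- sub("[ _].*$", "", colnames(m))
  agg <- t(rowsum(t(m), genus))
  out <- table
  out$values <- agg
  out
}
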