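# Synthetic GDM/NGT dual-omics cohorts with planted, recoverable effects.
#
# Latent species log-abundances are multivariate normal with group-specific
# block-correlation structure (Gaussian copula over designated top taxa);
# group mean shifts are planted on differential taxa; values are
# exponentiated, zero-inflated for rare taxa, and closed per sample.
# Metabolites are weighted sums of centered latent log-abundances plus
# Gaussian noise, shifted positive. OGTT 1-h glucose is driven by a planted
# log-ratio balance; the GDM/NGT label is assigned by the IADPSG
# diagnostic rule on the generated OGTT values.

#' Diagnose GDM from a 75-g OGTT
#'
#' IADPSG criteria: GDM when fasting plasma glucose >= 92 mg/dL, 1-h
#' glucose >= 180 mg/dL, or 2-h glucose >= 153 mg/dL; otherwise NGT.
#' Vectorized.
#'
#' @param fpg,g1h,g2h plasma glucose in mg/dL at 0, 1 and 2 h.
#' @return character vector of "GDM"/"NGT".
#' @export
diagnose_gdm <- function(fpg, g1h, g2h) {
  assert_that(!anyNA(fpg) && !anyNA(g1h) && !anyNA(g2h),
              "missing OGTT value")
  assert_that(all(fpg >= 0) && all(g1h >= 0) && all(g2h >= 0),
              "OGTT values must be non-negative")
  ifelse(fpg >= 92 | g1h >= 180 | g2h >= 153, "GDM", "NGT")
}

#' Homeostatic model assessment of insulin resistance (HOMA1-IR)
#'
#' Standard convention: fasting glucose (mmol/L) x fasting insulin
#' (micro-IU/mL) / 22.5.
#'
#' @param fasting_glucose mmol/L, positive.
#' @param fasting_insulin micro-IU/mL, positive.
#' @return unitless index.
#' @export
homa_ir <- function(fasting_glucose, fasting_insulin) {
  assert_that(all(fasting_glucose > 0) && all(fasting_insulin > 0),
              "HOMA-IR inputs must be positive")
  fasting_glucose * fasting_insulin / 22.5
}

#' Configuration for a synthetic dual-omics cohort
#'
#' Defaults emulate the study conditions: 50 GDM and 54 NGT samples, 300
#' species with log-normally decaying compositional abundances and zero
#' inflation of rare taxa, 10 differentially abundant taxa at |log2 FC|
#' 1.5, a group-specific correlation block among the top taxa (within-block
#' rho 0.6 in GDM vs 0.2 in NGT) plus one shared block, 119 metabolites of
#' which three dopamine-related pathways' metabolites are coupled to driver
#' species, and OGTT 1-h glucose driven by a planted 2-vs-2 taxon balance.
#'
#' @param n_gdm,n_ngt intent-group sample counts.
#' @param n_species number of species.
#' @param n_diff_taxa number of planted differential taxa (even; half down,
#'   half up in GDM). The first two down and first two up taxa form the
#'   planted balance.
#' @param effect_log2 planted group shift in log2 units.
#' @param module_spec list of blocks, each `list(taxa = indices,
#'   rho = c(GDM = ., NGT = .))`; taxa indexed in abundance order (1 = most
#'   abundant).
#' @param balance_coeff mg/dL of 1-h glucose per unit of the planted
#'   balance score (negative: lower balance, higher glucose).
#' @param ogtt_noise_sd residual SD of the OGTT glucose values (mg/dL).
#' @param n_metabolites number of annotated metabolites.
#' @param metab_coupling weight of driver-species latent log-abundance in
#'   the planted pathway metabolites.
#' @param metab_noise_sd metabolite residual SD.
#' @param zero_inflation_prob zero-inflation probability for rare taxa.
#' @param zero_inflation_min_rank abundance rank from which zero inflation
#'   applies (top taxa stay dense so the network stage is informative).
#' @param seed RNG seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_gdm = 50, n_ngt = 54, n_species = 300,
                          n_diff_taxa = 10, effect_log2 = 1.5,
                          module_spec = NULL,
                          balance_coeff = -8, ogtt_noise_sd = 12,
                          n_metabolites = 119, metab_coupling = 0.8,
                          metab_noise_sd = 1,
                          zero_inflation_prob = 0.3,
                          zero_inflation_min_rank = 61, seed = 1) {
  if (is.null(module_spec)) {
    module_spec <- list(
      list(taxa = 1:12, rho = c(GDM = 0.6, NGT = 0.2)),
      list(taxa = 13:24, rho = c(GDM = 0.35, NGT = 0.35)))
  }
  for (b in module_spec) {
    assert_that(all(b$taxa >= 1 & b$taxa <= n_species),
                "block taxon index out of range",
                class = "dualomics_config_error")
    assert_that(all(b$rho > -1 & b$rho < 1), "block rho must lie in (-1, 1)",
                class = "dualomics_config_error")
    assert_that(all(b$rho > -1 / (length(b$taxa) - 1)),
                "compound-symmetry block not positive definite",
                class = "dualomics_config_error")
  }
  assert_that(zero_inflation_prob >= 0 && zero_inflation_prob <= 1,
              "zero_inflation_prob must lie in [0, 1]",
              class = "dualomics_config_error")
  assert_that(n_diff_taxa %% 2 == 0, "n_diff_taxa must be even",
              class = "dualomics_config_error")
  structure(list(n_gdm = n_gdm, n_ngt = n_ngt, n_species = n_species,
                 n_diff_taxa = n_diff_taxa, effect_log2 = effect_log2,
                 module_spec = module_spec, balance_coeff = balance_coeff,
                 ogtt_noise_sd = ogtt_noise_sd,
                 n_metabolites = n_metabolites,
                 metab_coupling = metab_coupling,
                 metab_noise_sd = metab_noise_sd,
                 zero_inflation_prob = zero_inflation_prob,
                 zero_inflation_min_rank = zero_inflation_min_rank,
                 seed = seed),
            class = "cohort_config")
}

# Draw n x p standard-normal latents with group-specific block correlation.
draw_latent <- function(n, p, blocks, group) {
  z <- matrix(rnorm(n * p), n, p)
  for (b in blocks) {
    rho <- unname(b$rho[group])
    if (abs(rho) < 1e-12) next
    k <- length(b$taxa)
    S <- matrix(rho, k, k); diag(S) <- 1
    z[, b$taxa] <- z[, b$taxa] %*% chol(S)
  }
  z
}

#' Simulate a GDM/NGT dual-omics cohort
#'
#' @param config a [cohort_config()].
#' @return list: `abundance` ([abundance_table], closure 100),
#'   `metabolites` ([metabolite_table] with pathway map and sizes),
#'   `metadata` (data.frame with group, OGTT glucose in mg/dL, insulin,
#'   HOMA-IR, HbA1c, BMI, blood counts), `truth` (planted differential
#'   taxa, balance, per-group block structure, metabolite coupling matrix,
#'   driver species, planted pathways, intent labels). Fully reproducible
#'   from `config$seed`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  assert_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  set.seed(config$seed)
  p <- config$n_species
  n <- config$n_gdm + config$n_ngt
  intent <- rep(c("GDM", "NGT"), c(config$n_gdm, config$n_ngt))
  sample_ids <- sprintf("S%03d", seq_len(n))
  taxa <- sprintf("G%03d_s%03d", ceiling(seq_len(p) / 3), seq_len(p))

  # base abundance profile: log-linear decay, most abundant first
  mu <- seq(4, -4, length.out = p)

  # planted differential taxa: outside the correlation blocks, within top 50
  block_taxa <- unique(unlist(lapply(config$module_spec, `[[`, "taxa")))
  free_top <- setdiff(25:min(50, p), block_taxa)
  assert_that(length(free_top) >= config$n_diff_taxa,
              "not enough non-block top taxa for the differential set",
              class = "dualomics_config_error")
  diff_idx <- free_top[seq_len(config$n_diff_taxa)]
  half <- config$n_diff_taxa / 2
  down_idx <- diff_idx[seq_len(half)]          # reduced in GDM
  up_idx <- diff_idx[half + seq_len(half)]     # increased in GDM
  delta <- config$effect_log2 * log(2)

  z <- matrix(0, n, p)
  gdm_rows <- intent == "GDM"
  z[gdm_rows, ] <- draw_latent(sum(gdm_rows), p, config$module_spec, "GDM")
  z[!gdm_rows, ] <- draw_latent(sum(!gdm_rows), p, config$module_spec, "NGT")
  latent <- sweep(z, 2, mu, "+")
  latent[gdm_rows, down_idx] <- latent[gdm_rows, down_idx] - delta
  latent[gdm_rows, up_idx] <- latent[gdm_rows, up_idx] + delta

  raw <- exp(latent)
  if (config$zero_inflation_prob > 0 && config$zero_inflation_min_rank <= p) {
    rare <- config$zero_inflation_min_rank:p
    mask <- matrix(rbinom(n * length(rare), 1, config$zero_inflation_prob),
                   n, length(rare)) == 1
    raw[, rare][mask] <- 0
  }
  dimnames(raw) <- list(sample_ids, taxa)
  ab <- abundance_table(close_rows(raw, 100), closure = 100)

  # planted balance: first two down vs first two up differential taxa;
  # with no planted effects the balance taxa are fixed but carry no signal
  if (half >= 2) {
    bal_num <- taxa[down_idx[1:2]]
    bal_den <- taxa[up_idx[1:2]]
  } else {
    bal_num <- taxa[free_top[1:2]]
    bal_den <- taxa[free_top[3:4]]
  }
  bscore <- balance_score(replace_zeros(ab), bal_num, bal_den)

  # metabolites: planted pathways coupled to driver species
  drivers <- if (half >= 3) taxa[down_idx[1:3]] else taxa[free_top[1:3]]
  driver_cols <- match(drivers, taxa)
  mets <- sprintf("Met_%03d", seq_len(config$n_metabolites))
  lat_c <- scale(latent[, driver_cols, drop = FALSE], center = TRUE,
                 scale = FALSE)
  planted_paths <- c("Dopaminergic synapse", "Betalain biosynthesis",
                     "Isoquinoline alkaloid biosynthesis")
  coupling <- matrix(0, config$n_metabolites, p,
                     dimnames = list(mets, taxa))
  mvals <- matrix(rnorm(n * config$n_metabolites, sd = config$metab_noise_sd),
                  n, config$n_metabolites, dimnames = list(sample_ids, mets))
  w <- c(rep(config$metab_coupling, 4),           # pathway 1 metabolites
         rep(config$metab_coupling * 0.6, 8))     # pathways 2-3
  for (j in seq_len(12)) {
    mvals[, j] <- mvals[, j] + rowSums(lat_c) * w[j] / length(drivers)
    coupling[j, driver_cols] <- w[j] / length(drivers)
  }
  mvals <- sweep(mvals, 2, apply(mvals, 2, min), "-") + 1  # shift positive

  n_other <- max(0, floor((config$n_metabolites - 12) / 4))
  pathway_map <- data.frame(
    metabolite = mets[seq_len(12 + 4 * min(n_other, 27))],
    pathway = c(rep(planted_paths, each = 4),
                rep(sprintf("Pathway_%02d", seq_len(min(n_other, 27))),
                    each = 4)),
    stringsAsFactors = FALSE)
  sizes <- setNames(rep(6, length(unique(pathway_map$pathway))),
                    unique(pathway_map$pathway))
  sizes[planted_paths] <- 8
  metab <- metabolite_table(mvals, pathway_map = pathway_map,
                            pathway_sizes = sizes)

  # OGTT glucose (mg/dL): group intercepts + planted balance effect on 1 h
  fpg <- rnorm(n, ifelse(gdm_rows, 94, 83), ifelse(gdm_rows, 5, 4))
  g1h <- ifelse(gdm_rows, 185, 152) +
    config$balance_coeff * (bscore - mean(bscore)) +
    rnorm(n, 0, config$ogtt_noise_sd)
  g2h <- rnorm(n, ifelse(gdm_rows, 158, 128), 12)
  fpg <- pmax(fpg, 50); g1h <- pmax(g1h, 60); g2h <- pmax(g2h, 50)
  group <- diagnose_gdm(fpg, g1h, g2h)

  insulin <- exp(rnorm(n, ifelse(gdm_rows, log(6), log(2.8)), 0.5))
  fpg_mmol <- fpg / 18.016
  metadata <- data.frame(
    sample_id = sample_ids,
    group = group,
    ogtt_glucose_0h = fpg, ogtt_glucose_1h = g1h, ogtt_glucose_2h = g2h,
    fasting_insulin = insulin,
    homa_ir = homa_ir(fpg_mmol, insulin),
    hba1c = rnorm(n, ifelse(gdm_rows, 5.17, 5.00),
                  ifelse(gdm_rows, 0.44, 0.31)),
    bmi_prepregnancy = rnorm(n, ifelse(gdm_rows, 20.2, 17.1),
                             ifelse(gdm_rows, 3.9, 1.8)),
    neutrophil_count = rnorm(n, ifelse(gdm_rows, 7.89, 6.98),
                             ifelse(gdm_rows, 1.89, 1.95)),
    neutrophil_pct = rnorm(n, ifelse(gdm_rows, 76, 73), 5),
    lymphocyte_pct = rnorm(n, ifelse(gdm_rows, 18, 21), 4),
    tg = rnorm(n, ifelse(gdm_rows, 2.32, 1.97),
               ifelse(gdm_rows, 0.74, 0.63)),
    stringsAsFactors = FALSE)
  attr(metadata, "glucose_unit") <- "mg/dL"

  truth <- list(
    differential_taxa = data.frame(
      taxon = taxa[diff_idx],
      direction = rep(c("down_in_GDM", "up_in_GDM"), each = half),
      effect_log2 = rep(config$effect_log2, 2 * half),
      stringsAsFactors = FALSE),
    balance = list(numerator = bal_num, denominator = bal_den,
                   coeff = config$balance_coeff, scores = bscore),
    module_spec = lapply(config$module_spec, function(b)
      list(taxa = taxa[b$taxa], rho = b$rho)),
    metabolite_coupling = coupling[seq_len(12), driver_cols, drop = FALSE],
    driver_species = drivers,
    planted_pathways = planted_paths,
    intent = intent)

  list(abundance = ab, metabolites = metab, metadata = metadata,
       truth = truth, config = config)
}
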