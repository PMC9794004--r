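---
title: "Methods: integrative microbiome-metabolome analysis of GDM cohorts"
author: "dualomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative microbiome-metabolome analysis of GDM cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualomics)
```

# Scope and data model

`dualomics` analyzes case-control pregnancy cohorts profiled by shotgun
metagenomics and untargeted serum metabolomics: women with gestational
diabetes mellitus (GDM, diagnosed from a 75-g OGTT by the IADPSG rule:
fasting glucose ≥ 92, 1-h ≥ 180, or 2-h ≥ 153 mg/dL) against pregnant
controls with normal glucose tolerance (NGT). Three tables drive every
stage:

* an `abundance_table` — per-sample relative abundances of taxa
  (MetaPhlAn-style, samples × taxa after reading, each row closed to 1 or
  100). Relative abundances are compositional: only ratios are meaningful,
  which shapes the balance module below.
* a `metabolite_table` — samples × annotated metabolites in arbitrary
  instrument units, plus a metabolite → pathway map and per-pathway total
  compound counts.
* sample metadata — group label, OGTT glucose at 0/1/2 h, insulin,
  HOMA-IR (glucose × insulin / 22.5), HbA1c, pre-pregnancy BMI, blood
  counts.

All stages share one statistical kernel: the two-sided Wilcoxon rank-sum
test per feature (exact enumeration when both groups have ≤ 12 samples and
no ties, otherwise the normal approximation with tie and continuity
correction) with Benjamini–Hochberg adjustment **within one analysis
table** — all metabolites form one family, all species another, all
pathways another, the four bootstrap network metrics another. Two working
FDR levels are used throughout: 0.2 for discovery screens and 0.05 for
strict calls. Fold changes are reported case/control (GDM/NGT).

# Pathway activity scores

Metabolite abundances are first made comparable across instrument response
by dividing each metabolite by its mean over all samples. The activity
score of pathway $p$ in sample $s$ is the coverage-normalized summed
abundance

$$AS(s,p) = \frac{1}{K_p}\sum_{i \in p,\ \text{measured}} \tilde x_{si},$$

where $K_p$ is the pathway's total compound count and unmeasured compounds
contribute zero (no imputation). The score is linear in abundances and
monotone in pathway coverage: removing an unmeasured compound from $K_p$
strictly increases it. This is a deliberate, documented formalization of
pathway-activity profiling ("PAPi-style"); the package does not attempt to
reproduce any specific external implementation numerically, and no
flux-style inverse interpretation is applied — scores are reported as
"score ∝ abundance" and group differences are stated without directional
flux claims.

# Co-occurrence networks and the bootstrap comparison

Networks are built over the top 50 most abundant species (pooled-mean
ranking, ties broken by name). For every pair, Spearman's ρ and its
t-approximation p-value are computed; an edge is retained when `|rho| >
0.3` (strict) and the p-value clears the significance level — BH-adjusted
p < 0.05 for the full-cohort networks, raw p < 0.05 inside bootstrap
replicates (both thresholds are explicit configuration). Negative
correlations are kept as signed edge attributes; all metric computations
use $|\rho|$ as the weight, since the standard centralities require
non-negative weights:

* global transitivity — fraction of closed triads (unweighted);
* strength (weighted degree) — sum of incident $|\rho|$;
* weighted closeness — (number of reachable nodes) / (sum of
  shortest-path distances), edge length $1-|\rho|$; isolated nodes score 0
  and are never dropped, keeping distributions comparable across
  replicates;
* eigenvector centrality — non-negative, L2-normalized principal
  eigenvector of the $|\rho|$ adjacency.

The group comparison subsamples 30 individuals per group **without
replacement** (with-replacement duplicates corrupt rank correlations; a
`with_replacement` switch exists), rebuilds the network 100 times per
group with identical thresholds, and compares the replicate metric
distributions by rank-sum test with BH across the four metrics. Node
metrics can be pooled over nodes × replicates or averaged per replicate;
both are exposed, and a focal species' per-replicate edge weights (absent
edges recorded as ρ = 0 by default, or dropped) can be compared partner by
partner.

**Known limitation.** Bootstrap replicates drawn from one finite cohort
are strongly correlated, so the rank-sum comparison treats what is really
one cohort-level quantity as 100 independent observations. Under a true
null (identical generating correlation structure in both groups) the
comparison therefore over-flags: simulation shows nearly every cohort pair
yields at least one metric at FDR < 0.05 purely from cohort-level sampling
noise. The comparison is faithful to its field use and is powerful in the
planted-module regime, but its p-values must be read as descriptive
contrasts of the two observed cohorts, not as calibrated tests of the
generating process. A calibrated alternative would require cohort-level
label permutation with full bootstrap re-runs, which is outside the
package's scope.

# Balance selection

A balance over disjoint taxon sets $(N, D)$ scores sample $s$ as

$$B(s) = \sqrt{\frac{k_1 k_2}{k_1+k_2}}\left(\frac{1}{k_1}\sum_{i\in N}\log x_{si} - \frac{1}{k_2}\sum_{j\in D}\log x_{sj}\right),$$

a normalized log-contrast invariant to per-sample rescaling (verified as a
property test). Zeros are first replaced multiplicatively by half the
smallest positive table value, rows re-closed. The greedy forward search
starts from the best single ordered (numerator, denominator) pair by
criterion — rank-AUC of $B$ for binary responses (equal to trapezoidal ROC
integration), $R^2$ of a linear fit for continuous responses — then
repeatedly adds the taxon/side pair that improves the criterion by more
than `1e-4`, ties broken by taxon name, up to `max_size = 8` taxa (balances
larger than that stop being interpretable signatures). Logistic
coefficients are fitted by IRLS with a ±20 cap so separation never
produces infinite criteria; the selection criterion itself is always the
rank-AUC, which is finite by construction.

Cross-validation repeats the *entire* search per training fold (5
stratified folds × 10 repeats by default), accumulating per-taxon
selection frequencies and an out-of-sample criterion: held-out AUC of the
fold's balance, or held-out predictive $R^2$ (which may be negative; the
in-sample MSE is also recorded). The search universe is restricted to the
top-abundance taxa (default 50) — the same universe as the network and
attribution stages. $R^2$ was chosen over MSE as the reported continuous
criterion; MSE is kept in the fitted object.

# sPLS integration and association heatmaps

The sparse PLS couples two column-centered, unit-variance blocks in
regression mode. Per component, the dominant singular pair of the
cross-covariance $X^\top Y$ is sparsified by soft-thresholding to the
`keep_x`/`keep_y` largest-magnitude entries (the keepX idiom — a fixed
retained count rather than a penalty weight), re-normalized, and iterated
to convergence; both blocks are deflated on the X scores. The sign is
fixed so the largest-magnitude X loading is positive, making fits
deterministic. The displayed surface is
$\mathrm{sim}(i,j)=\sum_h \mathrm{cor}(X_i,\xi_h)\,\mathrm{cor}(Y_j,\xi_h)$,
clipped to $[-1,1]$. Defaults (2 components, keepX = 10, keepY = 5) are
configuration, not estimates; the equivalent dense fit is pinned against a
power-iteration oracle in the tests. Spearman heatmaps against clinical
indices use pairwise-complete observations (pairs with < 3 complete
samples are flagged missing) and BH across the whole matrix; all
coefficients are written, with FDR < 0.05 flagged rather than thresholded
away.

# Random-forest attribution

Each pathway flagged at the discovery FDR is regressed on the top-50
species abundances with a standard regression forest (500 trees,
mtry = ⌊p/3⌋, minimum node size 5, out-of-bag $R^2$ reported). Shapley
values are estimated by the model-agnostic permutation sampler: for each
of 200 random feature orderings a background row is drawn, features are
switched one at a time from the background to the explained sample, and
marginal prediction changes are averaged. The estimator was chosen over
tree-path recursion because it can be verified directly against exact
$2^p$ subset enumeration (done in the tests for $p \le 10$). Attributions
are normalized post hoc so efficiency, $\sum_i \phi_i = f(x) - $ baseline,
holds exactly, the residual being spread uniformly — which also means a
never-used feature carries a share of the Monte-Carlo residual rather than
an exact zero (bounded by the noise floor in tests). The background
convention is interventional with the full training table as background;
the per-species group comparison (GDM vs NGT rank-sum over per-sample
$\phi$, BH across species) is restricted to species already flagged as
differentially abundant.

# The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: it defines the study
conditions under which every downstream guarantee is demonstrated.
Defaults: 50 GDM / 54 NGT intent samples and 300 species. Latent log
abundances are multivariate normal (Gaussian copula) with a log-linear
abundance decay (base means from 4 to −4 in natural log), unit latent SD,
and block correlation among designated top taxa — by default one
group-specific block of 12 taxa (within-block ρ 0.6 in GDM vs 0.2 in NGT,
the regime that separates network transitivity) and one shared block of 12
(ρ 0.35). Ten differential taxa (ranks 25–50, outside the blocks) get a
±1.5 log2-fold group shift, half up and half down in GDM. Log-normal +
copula was chosen over a Dirichlet because group-specific correlation
modules must be directly specifiable for the network stage. Zero inflation
(probability 0.3) applies only from abundance rank 61 down, after
exponentiation and before closure, so the top-50 universe stays dense.

The planted balance is two down-shifted versus two up-shifted differential
taxa; OGTT 1-h glucose is `group intercept (185/152 mg/dL) − 8 × centered
balance score + N(0, 12²)`, and fasting/2-h glucose get group-separated
normal draws. The GDM/NGT label is then *assigned by the diagnostic rule*
on the generated OGTT values; the intercepts are set so diagnosis agrees
with the generating intent for ≈ 95 % of samples, which deliberately
leaves a realistic trace of label noise. Metabolites (119) are weighted
sums of centered latent log abundances of three driver species (the first
three down-shifted taxa) plus unit Gaussian noise, shifted positive; the
first three pathways ("Dopaminergic synapse", "Betalain biosynthesis",
"Isoquinoline alkaloid biosynthesis" — the dopamine-metabolism trio) are
coupled at weights 0.8 and 0.48, the remaining ~26 pathways are pure
noise. Clinical columns draw from group-specific normal distributions
matching the reported cohort means and SDs (BMI, insulin, HbA1c,
triglycerides, blood counts).

What the generator does **not** emulate: sequencing depth and read-level
noise, taxon-specific zero-inflation linked to abundance, non-Gaussian
metabolite error, covariate structure (age, parity, diet), or a planted
richness deficit. Passing tests therefore demonstrate that the pipeline
recovers planted compositional, correlational and chained effects at
realistic sample sizes — not that it is robust to every artifact of real
metagenomic data.

# Numerical choices and problem sizes

* Closure tolerance 0.5 % of the closure constant, with optional
  renormalization (MetaPhlAn columns rarely sum exactly to 100).
* Genus collapse is by summation without renormalization.
* Zero-denominator ratios use half the smallest positive table value as
  pseudocount and are flagged.
* Detection threshold for richness defaults to 0 (any nonzero abundance
  counts); Shannon re-closes over detected taxa.
* ANOSIM uses Bray–Curtis dissimilarities and the standard statistic
  $R = (\bar r_B - \bar r_W) / (n(n-1)/4)$ with seeded permutation p-value
  $(1 + \#\{R^* \ge R\})/(1+\text{permutations})$, delegated to vegan.
* Greedy-step improvement tolerance 1e-4; all stochastic stages derive
  independent sub-seeds from one master seed, so a run configuration plus
  seed reproduces every table byte for byte.
* Test and validation problem sizes were chosen as the smallest that make
  each check decisive: kernel oracles use 200 random fixtures at n ≤ 8 per
  group; exact-Shapley checks use p ≤ 10 with an 8-row background and
  forests of 60–100 trees; chain-recovery and calibration checks run 20
  independent cohorts at the full 104-sample, 300-species study shape with
  100-replicate bootstraps, 25–300 Shapley permutations and 3–10 CV
  repeats depending on the statistic under test.

# Known limitations

Beyond the bootstrap-comparison calibration discussed above: the balance
search is greedy and not guaranteed globally optimal past the exhaustive
first pair; compositionality-aware correlation (SparCC-style) is out of
scope, so network edges inherit the usual relative-abundance artifacts;
sPLS tuning is configuration, not selected by cross-validation; and the
Shapley group comparison inherits whatever bias the forest has on
correlated species.
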