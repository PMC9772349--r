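---
title: "Methods: causal network modeling of single-nucleus RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal network modeling of single-nucleus RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `sncnm`, the choices
we made where more than one reasonable convention exists, and what the
synthetic-data validation does and does not establish about real data.

## The analysis problem

The package targets case/control single-nucleus RNA-seq studies of the
Huntington's disease type: a control genotype (NT) and a disease model
(HD), each under a vehicle and an active treatment, profiled across cell
types, regions and donors, with the human arm contributing donors of
varying CAG repeat length. The scientific questions are (i) which genes
change per cell type, (ii) how the causal organization of each cell type's
disease-relevant gene program differs between conditions, (iii) whether a
treatment pushes disease-altered genes back toward control levels, and
(iv) which genes track the CAG expansion itself.

## QC, normalization and differential expression

Nuclei are kept when the detected-gene count lies in `[min_genes,
max_genes]` (defaults 200 and 6000, both inclusive) and the mitochondrial
read fraction is at most `max_mito` (default 0.02). Counts are normalized
as `ln(1 + scale_factor * c / total)` with `scale_factor = 1e4`, the
standard single-cell log-normalization; the formula makes values invariant
to per-cell sequencing depth.

Differential expression uses the two-sided Wilcoxon rank-sum test on
log-normalized values, testing only genes detected in at least `min_frac`
(default 0.25) of *either* group — an OR rule, matching the behavior of the
mainstream single-cell toolkits for their expression-fraction filter. The
p-value path is exact (via the null rank-sum distribution) when both groups
have at most 25 cells and there are no ties, and otherwise a normal
approximation with tie and continuity correction. The log2 fold change is
the fold change of mean de-logged expression,
`log2((mean(expm1 x1) + 1e-9) / (mean(expm1 x2) + 1e-9))`; single-cell
tools differ in the base and pseudocount of this quantity, so the
convention is fixed here and stated in the output documentation. Multiple
testing is Benjamini–Hochberg across the tested genes only, with
significance at adjusted p < `alpha` (default 0.05). The adjustment level
and alpha are configuration because different studies legitimately differ
here.

`zscore_log2fc()` standardizes a table's fold changes with the population
(n-denominator) standard deviation; with the hundreds-to-thousands of genes
these tables carry, the distinction from the sample sd is negligible, but
the convention is fixed and documented so that the rescue classification is
exactly reproducible.

## Signed co-expression modules

The adjacency is the signed soft-thresholded correlation
`a_ij = ((1 + cor_ij) / 2)^beta`, so anti-correlated genes become
*unconnected* rather than connected (the signed convention). `beta` is
chosen by the scale-free topology criterion: the smallest candidate power
whose connectivity distribution fits a power law with signed R² at least
0.8 over 10 log-spaced bins, falling back to the best-fitting power when
none qualifies. The topological overlap similarity
`TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)` rewards
shared neighborhoods and tempers spurious pairwise correlation.

Module detection is average-linkage hierarchical clustering on `1 − TOM`
with a *static* cut at `cut_height` (default 0.99), discarding clusters
below `min_module_size` (default 30) into the unassigned label 0, then
iteratively merging modules whose eigengenes correlate above `merge_cor`
(default 0.75), and renumbering by decreasing size. We chose the static cut
over dynamic hybrid tree cutting because it is deterministic, has one
interpretable parameter, and is the documented fallback in the field's
co-expression methodology; the defaults are tuned to transcriptome-scale
inputs (roughly two thousand genes after the detection filter), where
between-module topological overlap is near zero. On toy inputs of a few
hundred genes the between-cluster dissimilarity is visibly below 0.99 and a
lower cut is appropriate — our own small-fixture tests pass `cut_height`
explicitly for this reason.

The module eigengene is the first principal component of the per-gene
standardized module submatrix, scaled to unit variance, signed so that the
mean correlation with member genes is nonnegative. kME is each gene's
Pearson correlation with each eigengene. Module–trait correlation reports
Pearson r against (typically one-hot cell type) traits with the two-sided
Student asymptotic p, `t = r sqrt((n−2)/(1−r²))`; constant traits are
reported as r = 0, p = 1 and flagged rather than erroring. Correlations are
computed on control-condition cells only (disease networks are compared
against this reference), pooled across regions and ages by default, with
subsampling to `wgcna_max_cells` (default 10,000) for tractability.

## Discrete Bayesian network learning

Features for a cell type are the union of its significant DEGs and its
correlated module's members (`select_features()`); the pipeline caps the
set at `bnet_max_features` (default 60), preferring the most significant
DEGs, to keep per-replicate structure learning tractable at single-CPU
scale.

Expression is discretized per gene into `n_bins = 3` equal-width intervals
over the observed range, half-open except the last (so the maximum falls in
the top bin). We read "three breaks" in the interval-discretization
convention of the discrete-network literature as three *intervals*;
`n_bins` is configurable for the alternative reading. Bins are computed
once on the full data and held fixed across bootstrap replicates, and the
same fixed coding is used for both conditions of a cell type, so that
replicate-to-replicate and condition-to-condition structure differences
reflect the data rather than bin drift. Constant genes collapse to a single
flagged level.

The score is BDeu with imaginary sample size `iss = 1` (the common default
of discrete-network software; configurable): for node i with cardinality
r_i and q_i parent configurations, priors α_ijk = iss/(r_i q_i) and
α_ij = iss/q_i give the likelihood-equivalent Dirichlet marginal
likelihood, so DAGs in one Markov equivalence class score identically — the
tests verify this exhaustively on three nodes, and verify the scorer against
a brute-force Dirichlet-multinomial computation.

Search is plain hill climbing from the empty graph — no restarts, no tabu
list, no priors, and no in-degree bound by default — applying at each step
the single arc addition, deletion or reversal that most improves the score
subject to acyclicity. Ties are broken deterministically (add < delete <
reverse, then parent label, then child label), so a rerun on identical data
returns an identical graph; the score trajectory is strictly increasing and
the result is a local optimum, both asserted in the tests.

Arc strength and direction are bootstrap frequencies: each of `n_boot = 200`
replicates draws `ceiling(0.5 · n)` cells *without replacement* (we take
"using 50% of samples" literally as half-subsampling; resampling with
replacement is the common alternative and can be emulated by configuration),
learns a structure, and accumulates, per gene pair, the fraction of
replicates containing the arc (strength) and the orientation split among
them (direction). The averaged network keeps pairs with strength ≥ 0.85 and
orients by direction ≥ 0.5; an exact 0.5/0.5 split is oriented from the
lexicographically smaller gene and flagged loudly. Because per-pair
thresholding can assemble a directed cycle even though every replicate was
acyclic, cycles are repaired by dropping the weakest-strength arc on each
cycle, with a warning. Thresholds are applied per condition *before*
merging.

Merging annotates nodes and edges as control-only, case-only or shared;
shared edges carry the control condition's strength as their weight, making
the control network the visual reference. A node is "present" in a
condition when it is incident to at least one retained edge there. Key
drivers are hubs (out-degree strictly greater than 10) and connectors —
non-hub nodes on a directed path from one hub to a different hub. Whether a
connector requires directed edges or mere adjacency is ambiguous in common
usage; we implement the directed reading with `undirected_connector = TRUE`
as the alternative.

## Treatment-rescue analysis

For one cell type, three contrasts: genotype (case+vehicle vs
ctrl+vehicle), treatment (case+treated vs case+vehicle) and residual
(case+treated vs ctrl+vehicle). Genes significant in both the genotype and
treatment contrasts are classified by the signs of their Z-scored log2 fold
changes: opposite signs = rescued, same signs = exacerbated.

Two summary fractions are reported, deliberately. The *discordance
fraction* rescued/(rescued+exacerbated) conditions on the overlap and is
undefined when the treatment moves nothing — in particular, on synthetic
data with a planted rescue fraction of zero the treatment contrast is null,
the overlap is empty, and this fraction is NA. The *disease-level
fraction* rescued / (number of significant genotype DEGs) is defined in
that case (it is 0), is monotone in the planted rescue fraction, and
approaches 1 under a full rescue; it is the quantity our parameter-recovery
validation checks. The DEG-count reduction is
`log2((n_treated + 1)/(n_vehicle + 1))` with a pseudocount of 1 so zero
counts stay finite; negative values mean the treatment shrank the disease
signature.

## CAG regression

Counts are summed per (donor, region) group — optionally within one cell
type — log-normalized per pseudo-sample, and scaled per gene to zero mean
and unit variance. Each gene is fit by ordinary least squares on
[intercept, CAG, age, sex, batch, region] with treatment-coded dummies and
a two-sided t-test on the CAG coefficient, BH-adjusted. We use the union of
the age/sex and batch/region covariate sets, individually removable via
`covariates`; constant covariates are dropped automatically, but a constant
CAG column is an error because the target coefficient would be aliased.
Plain OLS with per-gene t-tests is the core inference; the tests verify the
coefficients coincide with a moderated linear-model fit (which differs only
in its variance shrinkage) and with direct normal-equations solutions.

Because the response is scaled per gene, `beta_cag` is in standard
deviations per CAG repeat and saturates for strong-effect genes (their own
sd contains the effect). `cag_fit()` therefore also reports `beta_log =
beta_cag * sd(gene)`, the coefficient de-standardized back to log-expression
units per repeat — the scale on which planted and fitted slopes are
linearly comparable, used by the slope-recovery validation. Cross-cell-type
comparison (`classify_cag_quadrants()`) categorizes genes by the two
significance flags and the sign quadrant of the two coefficients, with the
positive/positive quadrant upper-right.

## The synthetic-data generator

`generate_dataset()` plants, in this order on disjoint gene blocks:
co-expression modules (a per-cell latent factor per module, loading 1, sd
`module_factor_sd = 1`, with a cell-type-dependent factor mean so modules
correlate with cell identity), a causal DAG (linear structural equations on
latent log-expression, `child = Σ edge_effect · parent + N(0, dag_noise_sd)`,
using the full DAG for control cells and an edge-depleted DAG for disease
cells — edge loss is *marginal-preserving*: disease cells keep the full
structural equations but feed removed edges from an independent replica of
the parent, so the dependence disappears while every gene's marginal
distribution, and hence library size, is identical across conditions;
naive edge removal would shrink child variances and, through
`E[exp(z)] = e^{σ²/2}` and per-cell normalization, plant a compositional
pseudo-differential signal in every gene), genotype differential effects (log2 effects converted to natural
log; zeroed for rescued genes in treated disease cells), CAG slopes
(per-gene slope times donor CAG minus the mean donor CAG), and
mitochondrial genes whose expected count share matches a planted per-cell
fraction, above 2% for a `frac_bad_mito` subset so the QC filter has true
positives. Counts are negative binomial, `mu = s_c · exp(latent)` with a
lognormal library factor `s_c` and variance `mu + mu²/theta`.

Default parameter choices, made once on realism grounds:

* `nb_dispersion = 10`: UMI counting noise is close to Poisson; the
  overdispersion seen in real count matrices is largely biological and is
  carried here explicitly by the latent structure, so the residual
  dispersion is mild.
* DAG genes get a baseline abundance boost (+2.5 natural-log units, about
  a dozen counts per cell): causal network analyses operate on
  well-detected regulators and identity genes, not tail-detected
  transcripts.
* `dag_max_parents = 2` with `edge_effect = 0.8` and `dag_noise_sd = 1`: a
  gene in a 20-node subnetwork is typically regulated by one or two
  upstream factors at substantial effect size.
* Donors default to 4 control (CAG ≈ 18) and 4 disease (CAG 43–58)
  animals/donors; cells are assigned round-robin, with the region cycle
  blocked on the donor cycle so every donor contributes to every region
  (otherwise donor and region alias in pseudobulk designs).
* `deg_lfc = 1.5` log2 units and `n_deg = 100` of 2000 genes; planted
  effect signs alternate so the compositional shift from normalization
  stays small.

All randomness derives from the design seed through named substreams
(`derive_seed()`), so identical designs give bit-identical outputs and
partial re-runs are reproducible.

What the generator does *not* emulate — ambient RNA, doublets, batch
effects, gene-length bias, zero-inflation beyond NB, non-linear regulatory
effects, and cell-state continua — bounds what the validation shows:
passing tests demonstrate that each stage recovers the structure it is
designed to find when that structure is present under clean, known
conditions, not that the pipeline is robust to every artifact of real
tissue data. One planted confounding is deliberate: CAG length is carried
by disease donors only, so CAG-responsive genes are genuine genotype DEGs,
as in the disease itself; validation fixtures that need a clean readout of
one effect therefore disable the others.

## Validation scales and numerical choices

The test suite and `scripts/acceptance.R` run the stages at deliberately
desk-sized but non-trivial scales, chosen to finish in minutes on one CPU:
structure recovery on a 20-node DAG with 2000 cells and 200 bootstrap
replicates of 50%; module recovery with 4 modules of 50 genes among 2000 on
about 1000 control cells; DEG characteristics with 100 planted effects among
2000 genes at 300 vs 300 cells; rescue at 600 cells per arm; CAG recovery on
24 pseudo-samples from 12 donors by 2 regions. Skeleton-level F1 is the
structure-recovery metric because orientation is identifiable only up to
the Markov equivalence class; recovery varies with the random DAG
realization, so the seeded checks fix the design seed.

Numerical conventions worth knowing: BDe local scores are cached per
(node, parent set) within one search; score-improvement comparisons use a
1e-10 floor so floating-point noise cannot cycle the search; hill-climbing
tie-breaks are lexicographic and documented above; the hypergeometric
upper tail is inclusive (`P(X ≥ k)`); BH is applied across tested genes
only; degenerate inputs (constant genes, rank-0 module submatrices,
single-pseudo-sample designs, empty DEG overlap) warn and return flagged
or degenerate values rather than erroring, while genuinely broken inputs
(cyclic edge sets, aliased design matrices, unknown configuration keys,
out-of-range parameters) raise classed errors before any work is done.

## Known limitations

* Hill climbing returns a local optimum; with weak or shielded
  dependencies, different subsamples legitimately disagree, and the 0.85
  strength threshold then prunes recall. This is inherent to
  model-averaged discrete structure learning, not a defect of the
  implementation.
* Interval discretization is sensitive to single extreme cells, which
  stretch a gene's range and crowd the lower bins; fixed full-data breaks
  mitigate replicate drift but not the stretch itself.
* The CAG regression treats pseudo-samples as exchangeable given
  covariates; donor random effects and voom-style precision weights are
  out of scope.
* The rescue classification depends on the significance calls feeding it;
  underpowered contrasts shrink the classified overlap before they bias
  the fractions.
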