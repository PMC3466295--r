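---
title: "Methods: gene-phenotype network inference for drought response"
author: "droughtnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-phenotype network inference for drought response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtnet)
```

# The problem

Drought tolerance in crops is a systems property: water deficit triggers
transcriptional programs whose consequences surface as morpho-physiological
responses (osmotic adjustment, stomatal closure, reduced leaf expansion),
and the strength of each response differs between genotypes. `droughtnet`
implements a pipeline that connects the two layers for a pot experiment
with eight sunflower genotypes under two drought scenarios:

- **FDS** (fixed-duration stress): all plants of the scenario's blocks are
  harvested on the first day at least half of the treated plants drop below
  a fraction of transpirable soil water (FTSW) of 0.35. Stress *duration*
  is shared; stress *intensity* at harvest differs between genotypes.
- **FIS** (fixed-intensity stress): each treated plant is harvested when its
  own FTSW falls below 0.1, with its paired control. Intensity is shared;
  duration differs.

The pipeline takes a log2 expression matrix, a sample sheet, daily pot
weights and a phenotype table, and produces per-gene ANOVA effect classes,
a sparse-PLS model per scenario, a thresholded bipartite gene-phenotype
network merged across scenarios, and hypergeometric enrichment tests of an
independent (field-derived) gene list against the trait-linked network
genes.

# Water-balance statistics

Pot water status is tracked by FTSW,
$\mathrm{FTSW}_d = (\text{weight}_d - \text{weight}_\text{final}) / \mathrm{TTSW}$,
clamped to $[0, 1]$, where TTSW (total transpirable soil water) is the
difference between the initial (field-capacity) and final (stomatal-closure
calibration) pot weights. Control plants are re-watered daily, pinning their
FTSW at 1. Integrated transpired water accumulates the deficit,
$\mathrm{ITW} = \sum_d (1 - \mathrm{FTSW}_d)$.

Numerical conventions that the data sources leave open, fixed here once:

- **ITW discretization**: a daily rectangle sum from the day irrigation
  stops through the day *before* harvest. Weighing is daily, so a finer
  quadrature would manufacture precision the measurements do not have.
- **"50 %" in the FDS rule** is read inclusively (at least half), with ties
  resolved to the earlier day; the FIS rule is a strict first crossing.
- FTSW below 0 (a pot drier than the calibration endpoint) clamps to 0 with
  a warning; leaf relative water content slightly outside $[0,1]$ is kept,
  warned about, and only clamped on request, since it arises from
  measurement noise rather than a logic error.

# Normalization

Two steps, in this order, applied to the log2 intensity matrix:

1. **Block centering**: per gene, subtract the block mean and add back the
   gene's global mean. This removes block shifts exactly while preserving
   each gene's global mean (a property the tests assert at $10^{-12}$).
2. **Quantile normalization** across samples (delegated to
   `limma::normalizeQuantiles`, ties averaged), forcing every chip onto the
   common reference distribution.

Normalization is joint across the 96 chips by default; a `per_scenario`
flag restricts it within scenario, since either reading of the upstream
protocol is defensible.

# Per-gene ANOVA, pooling and effect classes

For each scenario separately, every gene is fit with the fixed-effects
model `block + genotype + treatment + genotype:treatment`. Sums of squares
are Type II, computed for all genes simultaneously from reduced-model
residual sums of squares; on the balanced design this equals the classical
decomposition, and it remains well-defined when a chip is missing. The
implementation is verified per-gene against `car::Anova(type = 2)` at
$10^{-8}$.

**Residual-variance pooling.** Genes with homoscedastic residuals share a
mean common residual variance, with Bartlett's test as the gate. The
criterion for membership in the homoscedastic set is an interpretation
fixed here: Bartlett's statistic is computed over the per-gene residual
variances; while it rejects at $\alpha = 0.05$, the largest-variance gene
is trimmed (up to 25 % of genes); the surviving set pools its variance and
residual degrees of freedom, trimmed genes keep their own. If the cap is
reached without homogeneity, no gene is pooled.

**Multiplicity.** Each effect's p-values are Bonferroni-adjusted with $m$
equal to the number of genes tested in that scenario, and flagged at
adjusted $p < 0.05$. The (genotype, treatment, g×t) significance pattern
maps to eight exclusive classes (`none`, `t_o`, `g_o`, `g*t_o`, `g_t`,
`g*t_g`, `g*t_t`, `All`); roll-ups ("at least treatment", etc.) are always
recomputed from the exclusive cells, never stored. Block is fitted and
reported but carries no class information.

**Post hoc.** For interaction-modulated genes, Tukey HSD compares all
genotype-by-treatment cell means (the studentized-range family is all cell
pairs) using the model's pooled MSE when the gene is pooled, and reports
the treated-vs-control contrast within each genotype. Whether the post hoc
should use the pooled or gene-specific MSE is not fixed by the protocol;
the default follows the gene's pooling flag.

**Double hierarchical classification** of significant genes and of samples
uses distance $1 - r$ (Pearson) with average linkage — the standard
expression-heatmap convention; both are arguments. Undefined correlations
(constant profiles) fall back to distance 1 with a warning.

# Sparse PLS and the association network

The engine is a from-scratch sparse partial least squares in regression
mode. Columns of $X$ (samples × genes) and $Y$ (samples × phenotypes) are
centred and unit-scaled. Per component $h$: initialize $(u, v)$ from the
leading singular pair of $M = X_h^\top Y_h$; iterate

$$u \leftarrow \mathrm{soft}(M v,\ \mathrm{keepX}_h), \qquad
  v \leftarrow \mathrm{soft}(M^\top u,\ \mathrm{keepY}_h)$$

with rank-based soft-thresholding that retains exactly the budgeted number
of entries (threshold at the first excluded magnitude), renormalizing to
unit norm, until the change in $u$ falls below $10^{-9}$ (cap 500
iterations). The X-variate $t_h = X_h u_h$ deflates both blocks
($X_{h+1} = X_h - t_h t_h^\top X_h / t_h^\top t_h$, same for $Y$):
regression-mode deflation by the X-variate, matching the asymmetric
"predict phenotypes from expression" reading. Each $u_h$ is oriented so its
largest-magnitude entry is positive, making fits deterministic. In the
penalty-free limit the fit coincides with dense PLS (checked against an
SVD oracle and against `mixOmics` in the tests).

Defaults: 3 components (the ordination axes interpreted downstream are
1-3), `keepX = 50` per component at the synthetic scale (a cardinality
budget rather than a continuous lasso penalty — reproducible and free of
λ tuning), `keepY` = all phenotypes.

**Association scores.** The bipartite relevance score of gene $i$ and
phenotype $j$ is

$$s_{ij} = \sum_{h=1}^{H} \mathrm{cor}(x_i, t_h)\,\mathrm{cor}(y_j, t_h),$$

the standard latent-variate similarity for PLS relevance networks; it
approximates the gene-phenotype correlation as components accumulate. This
formula is an interpretation (the upstream description names "pairwise
association scores" without a formula) and is documented as such. Scores
are computed for every gene — not only sPLS-selected ones — with a
`selected` flag recorded; they are not clipped, and magnitudes above 1
(possible with several components) are flagged. Edges keep pairs with
$|s_{ij}|$ *strictly* above 0.65. The FDS and FIS networks are merged by
edge union (an edge in both scenarios is tagged `both`), gene membership is
FDS-only / shared / FIS-only, and each gene node carries three flags from
the ANOVAs: treatment effect under FDS, treatment effect under FIS, g×t
effect under FIS.

# Enrichment

All enrichment is hypergeometric. For an urn of $N$ genes with $K$
successes and a draw of $n$, the package reports both the point
probability $P(X = k)$ — the statistic the original field analysis prints —
and the upper tail $P(X \ge k)$, the standard one-sided enrichment
p-value; the two are labelled and never conflated. Term enrichment tests
every term with at least one query hit and at least 2 annotated universe
genes (a configurable floor), adjusting across terms with
Benjamini-Yekutieli FDR, the step-up procedure valid under arbitrary
dependence — matching a "FDR under dependency" adjustment. Annotations are
consumed as given; no ontology-graph propagation is attempted.

The trait-link transfer test asks whether an independently derived gene
list is enriched among network genes linked to one trait: $N$ = merged
network genes, $K$ = genes with an edge to the trait, $n$ = list genes in
the network, $k$ = their overlap with the trait-linked set. At the
published counts (28/49 vs 523/1263 for RWC and 28/49 vs 628/1263 for OP)
the point probabilities are 0.00913 and 0.06655; note the second value
standard-rounds to 0.067, so the published "0.066" is evidently a
truncation — the package reports the exact value.

# The synthetic-data generator

Every stage is testable without any external download because the
generator plants known structure at the scale of the real design: 8
genotypes × 2 treatments × 3 blocks per scenario, 96 pots, 2000 genes,
nine phenotypes.

**Water.** Daily transpiration follows a two-segment FTSW response:
relative transpiration is 1 above a threshold $\theta = 0.4$ and declines
linearly to 0 below it (the classical transpirable-soil-water framework
gives no single functional form; the two-segment response is its standard
parameterization). Genotype coefficients spread around 450 g/day
(log-normal, CV 0.25) to create the vigour differences that make FDS and
FIS genuinely different treatments; calibration pots give TTSW = 4000 g.
With these defaults the FDS harvest rule triggers on day 7 and FIS
harvests span days ~9-13 — the same order as the real experiment.

**Expression.** Gene baselines are $N(8, 1.5^2)$ with residual SD 1.
Planted effects use balanced-sign patterns of fixed magnitude (default 2.5
residual SDs): the treatment shift is $\pm d/2$ per arm; genotype offsets
put half the genotypes at $+d/2$ and half at $-d/2$; interaction patterns
assign genotype-specific treatment responses of $\pm d$, double-centred so
they load only on g×t. Fixed magnitudes give every gene of a class the
same non-centrality, so class recovery measures the classifier rather than
the luck of a random effect draw. Classes are planted to populate all
eight cross-tab cells (defaults: 4 % `t_o`, 6 % `g_o`, 1.5 % `g*t_o`, 4 %
spread over the four combination classes). Block shifts are small
($\mathrm{SD} = 0.1$) — fitted, never significant, mirroring a design where
block effects are nuisance only.

**Phenotypes.** Eight modelled phenotypes load on three sample-level
latent factors — a water-status factor (OP negatively, E and RWC
positively), a vigour factor (PHe, CoD, TLA) and a leaf-structure factor
(LMA, CID) — because in the real data the phenotypes occupy a
low-dimensional ordination, not nine independent axes; this also makes
recovery by a 3-component sPLS well-posed rather than trivially
impossible. Each phenotype is the planted signed linear combination of its
factor's gene pool (15 genes per phenotype by default, loading 2 residual
SDs) plus Gaussian noise, mapped affinely to plausible units. The
water-status factor carries a treatment component (alignment 0.5), so OP
opposes ITW as it should; the alignment is deliberately moderate so that
ITW — which comes from the water simulation, not the linear model — does
not drag every stress-responsive gene over the network threshold. gs is a
noisy affine companion of E, a pass-through measurement downstream.

**Truth and recovery.** The planted association list pairs every pool gene
with every phenotype of its factor, with the product sign. The merged
network recovered at $|s| > 0.65$ achieves precision and recall near 1 at
the defaults (measured over 20 seeds in the acceptance suite), and planted
effect classes are recovered with per-class agreement above 0.99.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: probe-level microarray signal and its artifacts
(simulation starts at normalized-intensity scale), heavy-tailed or
gene-correlated noise beyond the planted factors, genotype-specific
phenotype variances, missing chips (available by subsetting, not planted),
and any biological pathway structure. Recovery rates here are upper bounds
tied to the planted effect sizes, not estimates for any real experiment.

# Numerical choices and degenerate inputs

- ANOVA sums of squares are flushed to exact zero below $10^{-9}$ of a
  gene's total sum of squares, so noise-free constructed signals yield
  $F = 0$ rather than round-off ratios; constant genes give $F = 0$,
  $p = 1$ throughout.
- An empty genotype × treatment cell makes the design untestable and is an
  error, not a silent drop.
- sPLS drops zero-variance columns with a message; an over-tight sparsity
  budget that zeroes a weight vector is an error.
- Hypergeometric mass is evaluated in log space.
- Quantile-normalization ties receive the mean of the reference values at
  the tied ranks.

# Problem sizes used by the tests

The acceptance suite runs the hypergeometric-vs-enumeration check over all
urn sizes up to 60; 50 random 30 × 50 / 30 × 9 problems for the dense-PLS
limit; 1000 global-null datasets of 500 genes on the 8 × 2 × 3 design for
the empirical FWER bound (1000 rather than a few hundred keeps the
Monte-Carlo error of the estimated rate — true value
$1 - (1 - 0.05/500)^{500} \approx 0.0488$ — small against the 0.07
acceptance margin); and 20 seeds of the full default design for
planted-structure recovery. The complete suite and the acceptance script
each finish in well under a minute per stage on one core.

# Known limitations

- The Bartlett-gated pooling rule (trim-largest-until-homogeneous) is one
  reasonable reading of "pooling across homoscedastic genes"; other
  readings (e.g. mixture-based variance moderation) would give slightly
  different pooled sets. No empirical-Bayes moderation is offered — the
  FWER stage is deliberately classical.
- The association-score formula is the standard PLS relevance-network
  similarity, but it is an interpretation, as is computing scores for all
  genes rather than the sPLS-selected subset (the selection flag is kept
  so either convention can be recovered).
- sPLS tuning (components, keepX) is configuration, not cross-validation;
  the package takes budgets as scientific inputs.
- The merged network is strictly bipartite; gene-gene co-expression edges
  are out of scope, as is any graph layout.
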