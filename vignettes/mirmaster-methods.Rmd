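---
title: "Methods: miRNA master regulator discovery with mirmaster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA master regulator discovery with mirmaster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`mirmaster` implements a complete discovery pipeline for miRNA master
regulators (MMRs) in tumor expression cohorts. The chain of reasoning
is: a miRNA that is (i) consistently upregulated in tumors of every
clinical stage, (ii) statistically coupled, by mutual information, to a
large set of mRNAs in tumor tissue, and (iii) whose inferred target set
is strongly enriched at one end of the tumor-vs-normal expression
signature, is a candidate driver of the tumor transcriptome. Each
candidate is then scored by its *Oncogenic Activity* - the balance of
known cancer driver genes it appears to push in an oncogenic versus a
tumor-suppressive direction - and screened as a survival biomarker.

Every stage is exercised end-to-end on synthetic cohorts with planted
ground truth, so the statistical behavior of the whole chain is
testable without any external download.

# The pipeline stages and their models

## Normalization and differential expression

Sequencing depth is estimated by the median-of-ratios estimator
(`size_factors()`): for sample $j$,
$\hat{s}_j = \mathrm{median}_i \; k_{ij} / (\prod_j k_{ij})^{1/n}$
over features $i$ with a positive geometric mean. The
variance-stabilizing transform is the deterministic stand-in
$\log_2(k_{ij}/\hat s_j + 1)$; it has no fitted spline, so identical
inputs always give identical outputs.

Differential expression (`nb_differential_expression()`) fits, per
feature, a negative-binomial model in the mean/dispersion
parameterization ($\mathrm{Var} = \mu + \alpha\mu^2$). The dispersion
$\alpha$ is a method-of-moments estimate from the normalized counts,
pooled across the two groups and floored at $10^{-8}$; the Wald
statistic compares the log of the two group means of normalized counts
with a delta-method standard error. This is intentionally a simplified
test - no shrinkage, no outlier replacement - because downstream stages
consume only the calls (fold change, p, BH-adjusted p). Its type-I
error is verified by simulation to sit within [0.03, 0.07] at the 5%
level. Features with all-zero counts are reported as `NA` and excluded
from the Benjamini-Hochberg step, which is implemented directly
(step-up with a cumulative minimum) and tested against a brute-force
oracle.

**Depth estimation at fixture scale.** The plain median-of-ratios
estimator assumes most features are not differentially expressed. A
desk-scale cohort can violate this badly: the reference benchmark has
100 of 200 genes repressed by ~1.5 log2 in tumors, which biases the
per-group ratio medians by ~0.6 log2 and reverses the apparent
direction of null genes. The pipeline therefore estimates one depth
factor per sample from the *combined* miRNA+mRNA matrix, restricted to
the half of features with the smallest cross-sample variance of
$\log_2(k+1)$ (`depth_factors()`). Stable features are unaffected by
planted group shifts, so the anchored median recovers the library-depth
signal; the idea is the same as least-variable-gene normalization. The
exported `size_factors()` keeps the textbook definition.

## Stage-consistency filter

Each miRNA is tested in four per-stage contrasts (stage-k tumors vs all
normals; sub-stages collapse to their parent stage) and retained only
if every contrast passes FDR $\le$ 0.05 *and* log2 fold change
$\ge +0.5$, and its expression correlates positively with stage
(Spearman, average-rank ties, p from the t approximation with $n-2$
degrees of freedom, $p \le 0.05$). All three thresholds are pipeline
parameters; the defaults are the published gates. Using all normals in
every per-stage contrast is an assumption (the source analysis does not
state the normal subset); it is the default and is documented here.

## Mutual-information network

Pairwise MI (`mutual_information()`) uses the rank-based adaptive
partitioning estimator of the ARACNe family: both vectors are mapped to
average ranks on the unit square, cells are split into quadrants while
a $\chi^2_3$ test (5% critical value 7.815) rejects uniformity, and
leaves contribute $p\log(p/\mathrm{area})$. The estimate is exactly
invariant under strictly monotone transforms, non-negative by
construction (it is a discrete KL divergence), and calibrated: at
$\rho = 0.8$, $n = 2000$ it reproduces the Gaussian closed form
$-\tfrac12\ln(1-\rho^2) \approx 0.511$ nats within $\pm 0.08$. A cell
whose points are fully coincident (a sample drawn many times in a
bootstrap replicate) is treated as a leaf - such points can never be
separated and would otherwise recurse without bound.

The significance threshold (`mi_threshold()`) is the $(1-p)$ quantile
of MI between independently permuted vectors. When the requested tail
is deeper than the permutation sample resolves
($n_{null} \cdot p < 10$), the naive empirical quantile is just the
sample maximum and fluctuates by a factor of ~2 across seeds; the
upper tail is instead extrapolated with an exponential
peaks-over-threshold fit on the top 5% of null draws, which is how the
ARACNe family reaches deep tail probabilities. The default
$p = 10^{-4}$ is for fixture scale (genome-scale analyses use far
smaller values over vastly more pairs).

**Bootstrap consensus.** Each of `n_boot` (default 100, the published
replication count) replicates resamples samples with replacement,
computes all miRNA $\times$ gene MI, thresholds, and applies the data
processing inequality. Triangles are closed in the regulator-hub
convention: two miRNAs sharing a passing target, with their
miRNA-miRNA MI (computed on the same replicate) as the closing edge.
Closing triangles with gene-gene MI instead would prune essentially
every true regulator-target edge, because co-regulated targets
correlate more strongly with each other than with their regulator (the
regulator's expression is a noisy proxy of its activity); this is a
known failure mode of DPI under co-regulation and the reason the
regulator-hub convention exists.

Resampling with replacement duplicates ~37% of samples, and duplicated
points inflate rank-based MI: measured at $n = 300$, roughly 10% of
truly independent pairs clear a clean-data $10^{-4}$ threshold per
replicate. The consensus step absorbs exactly this: an edge is kept
only when its support count across replicates is inconsistent with a
Poisson null of spurious rediscovery, Bonferroni-corrected over all
candidate pairs. The Poisson mean is estimated from the fraction of
candidate pairs *never* observed ($\hat\mu_0 = -\log(n_0/N)$), a
zero-truncated moment estimator that remains valid whether
truly-regulated pairs are a small or a large fraction of the
candidates (the naive mean-support estimate degenerates in small,
pre-filtered candidate sets and can reject edges supported by every
replicate). Finally, the consensus edge set receives one more DPI pass
with MI evaluated on the original samples: per-replicate DPI decisions
are noisy under bootstrap inflation, and classic ARACNe applies DPI to
the aggregate network. With `n_boot = 1` the single replicate is
returned verbatim.

MI is symmetric and carries no direction; each edge's
`direction_sign` is the sign of the Spearman correlation between miRNA
and gene across the original tumor samples, and is the regulon *mode*
used by the Oncogenic Activity stage.

## Target-database filter

An edge is retained iff it appears in the union of the supplied
databases - the union, not the intersection, because union of
prediction algorithms has the higher sensitivity. Identifiers are
case-normalized and stripped of the `hsa-` species prefix on both
sides; each retained edge records its supporting databases. An
explicit `allow_empty` opt-out exists because silently filtering
against an empty union would drop everything.

## Master regulator calls

The gene signature is $z_g = \mathrm{sign}(\mathrm{lfc}_g)\cdot
\Phi^{-1}(1 - p_g/2)$, capped at $\pm 10$ (the cap also absorbs
$p = 0$). Regulons are built per miRNA from the filtered network with
weight = bootstrap support normalized by the network's maximum support
and mode = direction sign; regulons below `min_size` (default 10;
3 at fixture scale) are dropped.

The enrichment score is the single-tail weighted mean
$S = \sum_g w_g z_g / \sqrt{\sum_g w_g^2}$ over regulon targets present
in the signature. The mode deliberately does **not** multiply into the
score: the score's sign then reports the expression direction of the
targets, so a repressive regulon whose targets are downregulated in
tumors scores negative - matching the interpretation that a negative
NES means coordinated target downregulation. (Multiplying in a
uniformly repressive mode would only flip the sign; modes are retained
in the regulon and drive the Oncogenic Activity tally instead.) The
null is MARINa-style gene sampling: `n_null` size-matched random gene
sets drawn from the signature with the same weights;
$\mathrm{NES} = (S - \bar S_0)/\mathrm{sd}(S_0)$, with a two-sided
empirical p (add-one smoothed). Calls are BH-adjusted over all tested
regulons at FDR 0.05.

Because the null is drawn from the signature itself, NES measures
*relative* extremity: a regulon whose realized repression merely equals
the signature-wide average cannot be called, regardless of its absolute
effect. This matters at fixture scale, where planted regulons make up
half the signature (see limitations).

## Oncogenic Activity

For each called MMR, its regulon targets are looked up in the driver
annotation (oncogene / tsg / dual / none) and in the pooled
tumor-vs-normal DE table. The tally counts upregulated oncogenes
(UONC), downregulated tumor suppressors (DTSG), downregulated oncogenes
(DONC), upregulated tumor suppressors (UTSG) and dual-role genes
(ONCTSG; counted once, regardless of direction). Then

$$ Oe = (UONC + DTSG) - ONCTSG, \qquad
   Ae = (DONC + UTSG) - ONCTSG, \qquad
   OA = (Oe - Ae)/T $$

with $T$ the total driver-target count. Dual genes cancel in
$Oe - Ae$, so $OA \in [-1, 1]$ always, and adding dual targets only
dilutes $|OA|$. Genes with role `none`, zero or missing fold change are
excluded (all documented boundary conventions). $T = 0$ yields an
undefined score, flagged and classified neutral-by-absence. OA is kept
exact internally and rounded to two decimals for tables. OA > 0 is
oncogenic, OA < 0 suppressor, OA = 0 neutral.

## Survival screen

Tumor samples are split at the median expression of each candidate
(ties at the median go to "low" - deterministic and documented; a
split that would empty a group is an error). Kaplan-Meier curves,
the two-group log-rank test and Cox proportional-hazards models
(Efron tie handling; Wald CIs) are delegated to the survival package -
the same engine the original analysis used - behind thin, contract-
checked wrappers, and are verified in the test suite against
hand-computed oracles (product-limit toy, observed-minus-expected
log-rank sums, and the classical identity between the log-rank
statistic and the Cox score test). The multivariate model adjusts for
age ($\ge 58$ vs $<58$), ordinal stage, and ER/PR status; the log-rank
significance threshold is exposed as a parameter (default 0.05 - the
source states 0.01 in its methods but reports 0.05-level calls in its
results, a contradiction we expose rather than resolve).

# The synthetic cohort generator

`generate_cohort()` draws negative-binomial counts (mean/size
convention: `size = 1/dispersion`, variance $\mu + \alpha\mu^2$) for a
tumor/normal cohort with:

- **Library sizes**: one lognormal depth factor per sample
  (`libsize_lognormal_sd`, default 0.3), shared by the miRNA and mRNA
  assays. This exercises the normalization stage.
- **Planted miRNAs**: log2 elevation
  $\lambda_{ij} = \mathrm{trend}\cdot \mathrm{stage}_j +
  \tau u_{ij}$ in tumors, with $u \sim N(0,1)$ per tumor and
  $\tau$ = `activity_sd` (default 0.5). Upregulation is monotone in
  stage by construction.
- **Planted edges**: each edge shifts its target's log2 mean in tumors
  by $\mathrm{sign}\cdot\mathrm{effect}\cdot z_{ij}$, where
  $z_{ij} = (\lambda_{ij} - \mu_\lambda)/\sigma_\lambda + 1$ is the
  regulator's z-score (population moments) offset so that the planted
  regulator sits one s.d. above its normal-tissue level. A strictly
  mean-zero z would leave targets with no tumor-vs-normal shift and no
  recoverable signature, so the +1 offset is part of the stated world.
  Because $z$ contains the stage trend, targets inherit a stage
  association - deliberate, and the source of the stage-confounding
  limitation below.
- **Survival**: exponential proportional hazards with baseline median
  60 time units and log-hazard `survival_beta` $\times$ the mean
  regulator z; censoring by an independent exponential whose rate is
  set so the expected censoring fraction approximates `censor_rate`
  for a baseline subject. Stage influences survival only through the
  planted regulators.
- **Defaults** describe the reference benchmark: 300 tumors,
  100 normals, stage probabilities (0.20, 0.55, 0.20, 0.05)
  (a breast-tumor-like stage mix), base means 500 (miRNA) and 300
  (mRNA), dispersion 0.1.

`benchmark_cohort_config()` pins the standard planted-truth benchmark:
10 miRNAs, 200 genes, 5 planted regulators each repressing a disjoint
block of 20 genes with effect 1.5, stage trend 1.0 (so even stage-I
tumors clear the +0.5 gate in truth), TSG roles for the targets of the
first three regulators and oncogene roles for the last two.

Mock databases contain a Bernoulli(`recall`) subset of the true edges
plus uniform decoys sized so the stated precision holds in
expectation; the driver annotation assigns `round(frac * n)` genes per
role in a seeded random order (oncogene, then tsg, then dual -
the deterministic rounding rule).

**What the generator does not emulate**: isomiRs or miRNA biogenesis,
batch effects, copy-number coupling, compositional sequencing effects,
and realistic transcriptome-wide expression heterogeneity. A green
planted-truth test establishes that the statistical chain recovers the
planted structure at the stated effect sizes and sample sizes - not
that it would behave identically on a real sequencing cohort.

# Numerical and reproducibility choices

- All randomness flows from explicit integer seeds; the pipeline fans
  its master seed into per-stage substreams by a fixed arithmetic hash
  (`stage_seed`), so rerunning a downstream stage from serialized
  tables reproduces the full-run output byte for byte.
- MI ties: average ranks, stable order; the estimator is deterministic
  given data.
- BH: `NA` p-values pass through and do not count toward the number of
  tests.
- DPI: edges are marked against the original weights and removed
  simultaneously, so the result is independent of edge order; ties for
  the triangle minimum remove nothing.
- Median-split ties go to "low"; fold-change sign boundaries (exactly
  zero) are excluded from driver tallies.
- All tables are written as plain TSV with fixed headers; the run
  manifest records version, seed and thresholds.

# Known limitations

- **Relative enrichment at fixture scale.** With half the fixture
  transcriptome planted, the gene-sampling null is dominated by other
  regulons' targets; a regulon whose realized repression is average
  for the signature is undetectable in principle. The benchmark's
  blocks are homogeneous enough that this does not cost calls at the
  stated effect size, but it is the binding constraint on recovery.
- **Stage is a latent confounder.** Planted miRNAs and all planted
  targets load on clinical stage, so tumor-only MI finds genuine
  stage-mediated cross-block associations. DPI cannot remove them:
  the weakest leg of the closing triangle is usually the miRNA-miRNA
  edge, and the true mediator (stage) is not a network node. In the
  reference benchmark this contaminates regulons with targets of other
  regulators; measured across benchmark seeds 1-5 the Oncogenic
  Activity sign of every planted regulator is recovered in 3 of 5
  seeds, with failures occurring when cross-block contamination from
  the (asymmetric, 60 TSG vs 40 oncogene) driver pools outweighs a
  regulator's own 20 targets. Partialling stage out of the expression
  matrix before MI would be the natural extension; it is out of scope
  here.
- **Composition bias.** The anchored depth estimator assumes at least
  `anchor_frac` of features are stably expressed. Worlds violating
  that assumption (e.g. global amplification) need external anchors.
- **The simplified DE test** controls type-I error at the simulated
  sizes but is less efficient than a shrinkage-based test at small n;
  per-stage contrasts against all normals inherit whatever biases the
  stage assignment carries.
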