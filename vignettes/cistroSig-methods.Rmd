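---
title: "Methods: from tumor cistromes to a prognostic signature"
author: "cistroSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tumor cistromes to a prognostic signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

cistroSig implements an integrative analysis of transcription-factor
chromatin binding in a tumor cohort: per-sample ChIP-seq peak sets for
several steroid hormone receptors (ER&alpha;, AR, GR, PR), the pioneer
factors FOXA1 and GATA3, and the enhancer mark H3K4me1 are reduced to
per-factor consensus binding landscapes, compared across factors and
patients, stratified by clinical group, coupled to proximal target genes,
and distilled into a penalized-regression gene-expression signature whose
prognostic value is assessed on an independent validation cohort. This
vignette explains the model behind each stage, the tunable parameters and
their defaults, what the synthetic cohort generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

# Consensus binding sites

A binding site is called *consensus* for a factor when peaks from at least
`consensusThreshold(n)` of the `n` profiled samples overlap a common
region. The threshold rule is: both samples when `n = 2`, otherwise
`max(1, floor(n/2))`. The floor (rather than ceiling) convention matters
only for odd `n` and was adopted because it reproduces the per-factor
thresholds used in practice for cohorts of 30, 10, 7, 4, 3 and 2 samples
(15, 5, 3, 2, 1 and 2 respectively); the rule is an explicit argument of
`consensusSites()` so any other convention can be supplied.

Candidate regions are built by single-linkage merging of all samples'
peaks (any 1-bp overlap chains intervals together); a region's *support*
is the number of distinct samples contributing at least one overlapping
peak. Coordinates follow the BED convention on disk (0-based, half-open)
and the GRanges convention (1-based, closed) in memory; overlap always
means at least one shared base.

Two peak callers can be reconciled before any of this with
`intersectCallers()`, which keeps the caller-A peaks corroborated by at
least one caller-B peak. A is the reference set: its coordinates are
reported, matching the convention that per-factor Venn counts are
anchored in the factor's own peak list.

# Overlap structure and correlation

`overlapPartition(A, B)` splits A's intervals into those that do and do
not touch B (A-anchored, so the two part counts always add to `|A|`);
`overlapRatio()` is the A-anchored fraction by default. Whether published
overlap-ratio heatmaps are row-anchored, Jaccard or min-anchored is
generally not stated; row-anchored was chosen as the default because it
reproduces asymmetric statements like "practically all AR sites are
co-occupied" and the other two are available via `method=`.

Sample-sample similarity uses read counts in the union of all factors'
consensus sites (`unionSites()`, `countInSites()`). Fragments are counted
by midpoint so each fragment contributes at most once to a disjoint site
set. Counts are scaled to the median column total and transformed as
log2(x+1) before Pearson correlation - raw ChIP counts are heavy-tailed
and a handful of strong sites would otherwise dominate r. Clustering of
the correlation matrix is agglomerative with average linkage on distance
1 - r; samples are ordered lexicographically before linkage so the
dendrogram is deterministic.

# Genomic context and target genes

Each site is assigned exactly one category by its midpoint with
precedence promoter > exon > intron > distal intergenic. The promoter is
TSS +/- 3 kb. The published analyses delegate this step to an external
annotator whose settings are not recorded; the fixed precedence, the 3-kb
window and the midpoint rule are this package's own fully specified
choices.

A gene is a *potential target* of a site when the site overlaps the gene
body or lies within 20 kb of it (`assignTargetGenes()`, strict
inequality on the edge-to-edge gap). Whether distance should be measured
from the site edge, midpoint or summit is not stated in the source
analyses; edge-to-edge was chosen as the most inclusive deterministic
reading.

# Differential binding

`differentialSites()` performs a per-site Welch t-test on the
log-normalized count layer followed by Benjamini-Hochberg correction.
Significance is declared in one of two modes mirroring common practice:
`"fdr"` (q < 0.1), used when comparing two factors, and `"pvalue"`
(p < 0.01), used when comparing clinical groups such as lymph-node
status. The Welch test is a deliberately simple, calibration-testable
stand-in for negative-binomial differential-binding machinery whose
normalization and shrinkage settings are package-internal elsewhere; the
interface accepts any per-site matrix, so other tests can be swapped in.
Sites with zero counts in every sample are dropped (their variance is
undefined). The test suite verifies null p-value uniformity, realized
FDR within 1.5x nominal and near-complete power at a 4-fold shift with
10 vs 10 samples; that calibration simulation uses equal library sizes
so its normalized layer is exactly log2(x+1), isolating the test and the
correction from depth normalization (which has its own scale-invariance
tests).

# Expression processing and subtypes

RNA-seq counts are filtered by `filterSamples()`. The retention rule "at
least 5 reads across each gene" admits two readings; both are
implemented. The literal per-gene reading (every gene >= 5 reads in the
sample, over a configurable gene subset) is the default; the aggregate
reading (total counts >= 5 x number of genes) is available as
`rule = "total"`. On realistic data the literal rule over *all* genes
removes essentially every sample - lowly expressed genes always carry
zeros - so the pipeline orchestrator uses the aggregate rule; callers
wanting the literal rule should restrict it to a curated core gene set.

Normalization is median-of-ratios size factors (via DESeq2's estimator:
for each sample the median over genes of count / per-gene geometric mean,
over genes with no zero count) followed by log2(count/factor + 1). This
is a fully specified, monotone variance-dampening stand-in for
regularized-log transforms whose shrinkage is internal to other packages.

Subtype assignment (`subtypeCluster()`) z-scores the normalized
expression of a supplied classifier gene list, clusters samples with Ward
linkage on Euclidean distance, cuts at two groups, and names the group
with the higher mean marker expression "M1". Which published cluster was
anchored as "M1" is not recorded anywhere, so the marker subset is an
explicit argument and defaults to the whole classifier list; the
labeling is deterministic either way. The partition is invariant to gene
and sample order (rows and columns are sorted internally before
clustering).

# The prognostic signature

`fitElasticNet()` minimizes the penalized binomial deviance

$$-\frac1n\sum_i \left[y_i \log p_i + (1-y_i)\log(1-p_i)\right] +
\lambda\left[\tfrac{1-\alpha}{2}\|\beta\|_2^2 +
\alpha\|\beta\|_1\right]$$

over a 100-point log-spaced lambda path from the smallest
all-coefficients-zero lambda down to 1e-4 of it, with lambda selected by
minimal mean leave-one-out deviance (deviance, not CV-AUC, because AUC is
undefined on single-sample folds). Predictors are standardized internally
and coefficients reported on the original scale. The mixing parameter
alpha defaults to 0.5 and is recorded in every output; the published
analysis does not state its alpha or whether predictors were
standardized. The *signature* is the set of genes with nonzero
coefficients; the risk score of a sample is the linear predictor. With
genome-wide input at these sample sizes the selected model is typically
empty - candidate genes must be pre-filtered, here by differential
binding.

Model quality is measured by validation-cohort ROC/AUC (rank statistic,
ties get half credit). Patients are split into equal-sized high- and
low-risk groups at the median score (scores strictly above the median are
"high"; all-equal scores therefore all land in "low").

The significance of an observed AUC is assessed against a *size-matched
random-gene-set bootstrap null*: B = 1000 models are trained and
validated through the identical pipeline on gene sets drawn uniformly
without replacement from the expression matrix, and the one-tailed
p-value is the add-one-smoothed (1 + #{AUC_b >= AUC_obs}) / (B + 1),
which can never be exactly zero. A replicate whose fit fails is logged
and resampled, never silently dropped.

# Survival analysis

Kaplan-Meier curves, the two-group log-rank test (1-df chi-square) and
Cox proportional-hazards regression are thin validated wrappers over the
survival package, with Efron's tie correction (better behavior on the
discrete times synthetic cohorts produce; the choice of correction is
not recorded in the source analyses). Wald p-values are two-sided.
Records censored at time zero are excluded with a warning - they carry no
risk-set information. Convergence and separation problems surface as an
honest `converged` flag plus exploding standard errors rather than being
hidden. The test suite checks the product-limit table against a hand
estimator, the log-rank statistic on mirrored groups, type-I error under
null exponentials, and the partial likelihood against a grid-search
oracle.

# Cross-cohort k-NN transfer

`knnPredict()` labels each test sample by the majority outcome of its
k = 5 nearest training samples under Minkowski distance (order p = 2 by
default; the published analysis names the metric family but not the
order, so it is exposed and recorded). Distance ties at the k-th position
include all tied neighbors; vote ties are broken by the smaller summed
neighbor distance, then by the lexicographically smaller label - fully
deterministic and independent of training-sample order. Counts are
normalized before distances; sequencing depth would otherwise dominate.

# The synthetic cohort generator

`cohortConfig()` / `simulateCohort()` generate cohorts with the
statistical structure the analysis assumes, with known ground truth:

* **Genome and genes.** One linear 50-Mb chromosome holding 2,000
  disjoint genes of 5-20 kb with random strand. A single chromosome
  suffices because every interval operation is chromosome-local. The
  compressed genome (genes cover roughly half of it) makes promoter and
  intron fractions higher than in a real genome; the genomic-distribution
  machinery is therefore validated against oracles on toy annotations,
  not against published pie-chart fractions.
* **Co-binding architecture.** Master sites are laid out in modules
  reflecting the observed biology: a shared steroid-hormone-receptor
  module (ERa/AR/GR/PR), an ERa/FOXA1/GATA3/H3K4me1 enhancer module, a
  promoter-enriched ERa-only module (promoter bias 0.7), a
  FOXA1-selective module and small PR-/GATA3-private modules. Sample
  counts per factor default to the study design: 30 ERa, 10 AR, 7 GR,
  4 PR, 7 FOXA1, 3 GATA3, 7 H3K4me1, drawn from 46 patients.
* **Counts.** Reads at a site follow a negative binomial with mean
  depth x (bound ? 100 : 5) x patient effect and shared dispersion
  (size 8). The log-normal patient-by-site effect (sd 0.5) is shared
  across factors, planting the within-patient ERa-AR correlation
  observed in tumors. Presence of a site in a sample is
  Bernoulli(module presence rate).
* **Differential binding.** 10% of ERa/FOXA1 sites are lymph-node
  linked with a 3-fold intensity change (direction random per site).
  These sites are modeled as constitutively occupied in ERa/FOXA1
  samples: differential cistrome hits are by construction
  high-confidence consensus sites, and Bernoulli occupancy would
  conflate occupancy noise with the intensity effect being planted.
* **Expression and survival.** Twenty signature genes are drawn from the
  genes proximal (<20 kb) to differential sites and shifted 1.5-fold
  between LN groups (sign random per gene). The true risk score is the
  standardized signed mean of their log2 expression; OS and DMFS times
  are exponential with hazard h0 exp(gamma x risk), gamma = 1,
  h0 = log(2)/60 per month, independently exponentially censored at a
  rate calibrated to a ~30% censoring fraction (exponential hazards keep
  every recovery test closed-form). Treatment covariates are independent
  noise; the M1/M2 label is the risk median split with 15% label noise.
* **Cohort pairs.** `simulateCohortPair()` shares the genome, the master
  sites and the planted signature between a discovery and a validation
  cohort but draws independent patients, presence, counts and survival -
  the structure cross-cohort validation assumes.

Everything is drawn from a single root seed; identical config + seed
reproduces the cohort byte for byte. What the generator does *not*
emulate: raw reads and fragment-level coverage, copy-number structure,
multi-chromosome genomes, correlated treatment assignment, or any
realistic linkage between covariates and outcome beyond the planted
signature. Passing tests therefore demonstrate correctness and
calibration of the machinery under the stated generative model, not
performance on real tumors.

# Problem sizes used by the test suite

The acceptance-style checks run at these sizes, chosen to exercise each
property well inside a desktop R session: 200 random toy genomes
(3-10 kb) for the interval oracles; 2,000 sites x 10 vs 10 samples x 50
simulations for differential calibration; 20 planted genes among 500
candidates, n = 60/60, 50 seeded simulations at alpha = 0.9 (the
sparse-recovery setting; effect 1.5 SD) for signature recovery; B = 100
bootstrap models x 200 repetitions (5-fold CV inside replicates) for
null calibration; 50 split-signal simulations (10 signal genes per
factor set at 0.6 SD, validation n = 200 so AUC noise does not mask the
structural union advantage); 500 null log-rank simulations and 100 Cox
recovery simulations at n = 200; 200 random k-NN instances; and a
double pipeline run on a 20-patient cohort for determinism.

# Known limitations

The Welch stand-in lacks the shrinkage of negative-binomial differential
binding tools and will be conservative at very low counts. The consensus
rule is single-linkage: two peaks chained by a third are merged even if
they never touch each other. The bootstrap null shares the training
cohort across replicates, so null AUC draws are not independent of each
other (the p-value is still valid as a conditional test). Published
site counts and the exact 14-gene signature depend on the original raw
cohorts and are not reproducible from synthetic data by design; the
package targets the *properties* of the method - calibration, recovery,
determinism - rather than those numbers.
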