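---
title: "Methods: variance decomposition and cluster-level network inference for longitudinal multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance decomposition and cluster-level network inference for longitudinal multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lomnet)
```

`lomnet` implements an analysis pipeline for small longitudinal multi-omic
studies: a few animals, repeated sampling across a drug-dosing schedule,
RNA-seq from bone marrow (BM) and peripheral blood (PB), an LC-MS plasma
metabolome measured in technical triplicate, and complete blood counts.
This vignette explains the statistical procedures, the choices behind
their defaults, what the synthetic-data generator does and does not
emulate, and the known limitations.

## The design and the drug-phase factor

The design is a full factorial of animals (default 5) by timepoints
(default 7) per compartment, with the plasma metabolome restricted to
timepoints 3–7. Drug phase is a fixed function of the timepoint:
timepoints 1–2 precede the first dose ("pre"), 3, 5 and 7 fall about a
week after a dose ("post"), and 4 and 6 fall about a month after the most
recent dose ("inter"). Because phase is determined by timepoint, phase
contrasts are sub-contrasts of the timepoint factor; the package treats
them as separate factors of the same design rather than as a nested
model.

## Preprocessing

RNA counts are normalized with median-of-ratios size factors (the median,
over features with all-positive counts, of the ratio of each sample's
count to the feature's geometric mean; the median is taken on the
log-ratio scale, which interpolates geometrically between the two middle
ratios when the feature count is even). Values are then
`log2(count/factor + 1)`; the pseudocount of 1 keeps zeros finite and is
the conventional choice. Features whose mean log2 abundance falls below 5
(transcripts) or 17 (metabolites) are removed: low-abundance features
carry high coefficients of variation that mostly add measurement noise to
the variance components. Both thresholds are exposed as parameters; they
are heuristic cutoffs, not optimized quantities.

Metabolite tables pass through a fixed order of operations: technical
replicates are collapsed to per-sample medians; features missing in more
than 30% of samples are dropped (exactly 30% is kept); features whose
median intensity falls below 256 peak-area units are dropped; remaining
missing cells are imputed as half the feature's minimum observed
intensity (PCA requires complete data; half-minimum is the standard
left-censoring surrogate); then values are log2-transformed. The 256-unit
cutoff is applied to the per-feature median rather than per cell — the
per-cell reading would interact with the missingness filter in
order-dependent ways.

Animal residualization subtracts each feature's per-animal mean — the OLS
residual of a one-factor fit — and is always applied *before* any
standardization in the network stage, since the two operations do not
commute.

## PC variance components

PCA is run on feature-centered but unscaled log2 data: the variance
attribution is meant to reflect raw log2 variance, and scaling would
reweight features by the inverse of their variance. Components are
retained up to 90% cumulative percent variance explained (PVE). For a
factor with k levels, each component's R² is the between-group sum of
squares over total (equivalently the squared correlation with the
group-mean predictor), and the factor's overall share is the PVE-weighted
average of the per-component R². Two properties matter for
interpretation:

* the estimator is invariant to component sign flips and to reordering of
  equal-PVE components;
* per-component R² carries the usual (k−1)/(n−1) null inflation, so a
  factor explaining nothing still receives a small positive share —
  roughly 0.12 for 5 animals and 0.18 for 7 timepoints at 35 samples.
  With 2000 features the recovered weighted R² for planted fractions
  0.6/0.15 lands near 0.66/0.22; both the tests and the acceptance script
  treat recovery within ±0.08 as successful, which accommodates exactly
  this inflation.

## Integration

The first 10 PCs of each of the four omic datasets are correlated
pairwise — C(40, 2) = 780 tests — and flagged at a Bonferroni-adjusted
0.05. Datasets are matched on (animal, timepoint) keys, so the metabolome
(timepoints 3–7) is compared with the transcriptomes on their 25-sample
overlap.

The lagged concordance test selects genes deviating in one direction in
BM at a source timepoint (default: positive deviation of the
animal-averaged timepoint mean from the grand mean, on
animal-residualized values) and counts sign agreement of the PB deviation
one timepoint later, under an exact two-sided binomial null of 0.5. The
selection rule is injectable; a magnitude cutoff (`min_abs`, log2 units)
concentrates the selection on strongly excursive genes — with the pure
sign rule the selection is half the transcriptome and genuine lag signals
are diluted toward the null. Genes with zero target deviation are
excluded from the count. Two-sided testing is used because the control
contrast is expected to give an unremarkable mid-range p-value rather
than one near 1.

## Axis scores and per-feature ANOVA

Each axis is PC1 of the standardized 10-gene submatrix, sign-oriented so
the majority of gene loadings are positive (PCA flips signs arbitrarily),
and scaled to unit variance. Axes with fewer than 5 of their 10 genes
present are skipped with a warning. The drug ANOVA runs on
animal-residualized scores, with residual degrees of freedom charged for
both factors (n − animals − phases + 1), so removing the animal effect
does not silently inflate the test. Under that convention the power to
detect a one-standard-deviation post-phase shift at 35 samples is about
0.7.

Per-feature ANOVA uses OLS throughout. "Animal as a random effect" is
implemented as a fixed blocking factor: in a balanced single-replicate
design the F-test for the within-animal factor is identical under either
formulation, and the OLS route is dependency-free and vectorizes over
thousands of features with one QR decomposition. The consistent-response
test requires a paired t-test (pairing by animal, two-sided, df =
animals − 1) at p < 0.05 *and* a consistent sign at every one of the
three post-versus-preceding contrasts; with null data the expected list
size is about n · 0.025³ per direction.

## Pathway summaries

Pathway scores are PC1 of the standardized member-gene submatrix,
computed per compartment independently (loadings can legitimately reverse
sign between compartments). A set must have at least 5 expressed members
in every compartment to be scored, where "expressed" means it survived
the abundance filter. Scores are averaged over animals within timepoints
and Ward-clustered; both a fixed-k cut and a height cut are supported
because cluster counts, not criteria, are usually what is reported. The
BM–PB association is a Pearson chi-square on the cross-tabulated
labelings with Cramér's V² reported as the fraction of one labeling
explained by the other.

## The network stage

**Feature selection.** The n most drug-responsive features by ANOVA F
(ties broken by id); defaults 1000 transcripts / 500 metabolites.

**QT clustering.** Distance is 1 − Pearson r (a jackknifed variant —
the minimum correlation over leave-one-sample-out subsets — is available
behind a flag for outlier robustness). For every remaining feature as
seed, a candidate cluster grows by adding the feature that keeps the
diameter (max pairwise distance) minimal and ≤ d = 0.3; the largest
candidate is kept (ties: smaller diameter, then earlier seed), removed,
and the procedure iterates. Clusters below 10 members are discarded,
though the permutation check can relax this to observe the near-empty
structure of permuted data. On instances of ≤ 12 features the greedy
first cluster matches an exhaustive-search oracle in the test suite.

**Observation concatenation.** Structure learning on 35 samples is
hopeless, so each cluster's top 10 centroid-correlated members are
stacked into 10 × 35 = 350 observations per node (250 for the 25-sample
metabolome). This is deliberate pseudo-replication: the 10 blocks share
the same 35 sample-level latent values, which boosts the effective
evidence for dependences. The gene-order shuffles exist precisely to
guard against artifacts of one particular gene-to-gene alignment — but
they cannot undo the within-node replication itself, so modest chance
correlations between cluster latents can and do become robust edges. The
tolerance of at most one spurious robust edge in the planted-truth tests
reflects this honestly.

**Discretization.** Each node starts at 20 quantile bins; adjacent bins
are merged greedily, always choosing the (node, bin-pair) whose merge
loses the least total pairwise mutual information against all other
nodes, until each node reaches its target level count — 7 for transcripts
and 5 for metabolites by default, or an automatic elbow (maximum distance
to the chord of the remaining-MI-versus-levels curve). Merging adjacent
quantile bins keeps the map monotone, and since any sequence of adjacent
merges can reach any ordered partition, the brute-force optimum over
partitions is a valid oracle on small instances. The level count sets an
implicit sensitivity threshold through the score's complexity penalty: at
350 observations, 7 levels detect dependences of roughly |r| ≥ 0.7, 5
levels roughly |r| ≥ 0.55. That is why the integrated
transcript–metabolite analysis (7-level transcript nodes) reports no
robust cross-type edges on independent data while weaker settings would.

**Structure learning.** Sparse Candidate with k = 5 candidate parents per
node (chosen by pairwise MI, current parents always retained), greedy
add/delete/reverse hill climbing within candidates under a BDeu score
with equivalent sample size 1, max 3 parents, up to 20 restrict/maximize
rounds. All tie-breaks are deterministic (lowest node index), so learning
is a pure function of its input. None of these constants are
study-prescribed; they are conventional values for discrete networks of
this size and are exposed as arguments.

**Robustness.** For the original table and each of 3 gene-order-shuffled
copies, networks are learned on 1000 subsamples of 90% of the rows
(defaults; tests and the acceptance script use 25–100 subsamples to stay
interactive — frequencies stabilize to ±0.03 by a few hundred). An edge
is robust when its frequency reaches 50% in the original *and every*
shuffle (strict mode); a pooled mode requires 50% of all runs combined,
since both readings of the criterion are defensible. Edge identity is
directed by default with an undirected skeleton mode available, and the
reported overlap between datasets is the Jaccard percentage of
above-threshold edge sets.

**Conservation.** A cluster found in one compartment is scored in the
other by the distribution of member-to-centroid correlations, compared
against 100 same-size random draws from the pool of all clustered genes
using a one-tailed Kolmogorov–Smirnov test for right shift; the reported
statistic is the number of significant comparisons out of 100.

**Integration.** Transcript observations are restricted to the
metabolome's timepoints, metabolite node values are scaled to unit
variance, rows are aligned on (gene block, animal, timepoint), and
discretization is performed jointly with 7 transcript / 5 metabolite
levels before the same robustness procedure; cross-data-type edges are
reported separately.

## The synthetic-data generator

Per feature, the log2 signal is grand mean + animal effect + timepoint
effect + drug-phase effect (drug genes only, post-phase samples) +
cluster latent (members only) + heteroscedastic noise; counts arise by
exponentiating, applying a per-sample depth factor drawn log-uniformly
over [0.5, 2] (so size-factor estimation is non-trivial), and rounding.
The total log2 sd follows an abundance-dependent curve, so low-abundance
features have larger coefficients of variation and the abundance filter
has real work to do. Variance fractions default to 0.6/0.15
(animal/timepoint) for transcriptomes — the regime seen in filtered
expression data where individual identity dominates — 0.15/0.15 for the
metabolome, and 0.3/0.1 for blood counts. Log-normal-then-rounded counts
are used instead of a negative-binomial draw because every downstream
computation operates on log2 values; matching the log-scale variance
structure matters more here than count dispersion.

Planted clusters replace a member's entire after-animal variation with
`sqrt(rho)` of a shared latent plus `sqrt(1-rho)` idiosyncratic noise, so
the `within_cor` parameter governs exactly the correlation the clustering
stage sees on residualized data. The latent has a timepoint-structured
share (`cluster_tp_share`, default 0.6) and directed couplings between
cluster latents implement the planted inter-cluster edges. Because a
timepoint profile has only 7 values, two clusters' profiles can collide
by chance (correlation sd ≈ 0.4 on the timepoint share); fixtures that
need clean null pairs therefore lower `cluster_tp_share`. The
marrow-to-blood lag is a signed log2 excursion (magnitude a parameter,
default 1, sign random per gene) added to BM timepoint 4 and echoed at PB
timepoint 5; its magnitude is a parameter because no canonical value
exists for it.

The generator deliberately does not emulate: count overdispersion beyond
log-normal noise, batch or library-preparation effects, correlated
missingness in the metabolome (missingness is sample-level at random),
compositional effects, or annotation structure. Passing tests therefore
demonstrate that the procedures recover the statistical structure they
target — not that they are robust to every artifact of real sequencing
or mass-spectrometry data.

## Problem sizes and determinism

The test suite and acceptance script run the generator at 400–2000
features, networks at 3–5 nodes, and robustness at 10–100 subsamples;
these sizes were chosen so a full run completes interactively while
leaving every recovery margin intact. One global seed drives everything:
each stochastic operation derives a sub-stream from the seed and a text
tag, so independent operations do not perturb each other and any run is
bit-identical under a fixed seed.

## Known limitations

* The PC-weighted R² is biased upward by its null component; it is a
  descriptive attribution, not an unbiased variance-component estimate
  (a REML mixed model would be, but is a different procedure).
* Observation concatenation trades independence for sample size; edge
  frequencies are interpretable as stability measures, not as posterior
  probabilities.
* Directed edges from score-based learning on observational data carry
  no causal guarantee; the skeleton is the trustworthy object.
* The QT greedy growth matches exhaustive search on small instances but
  is not globally optimal in general; its determinism, not optimality,
  is the contract.
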