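---
title: "Methods: the double-hit methylation–GWAS pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the double-hit methylation–GWAS pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doublehit)
```

This vignette is the package's own account of the statistics it implements:
the models, the tunable parameters and why their defaults are what they are,
what the synthetic-data generators do and do not emulate, and the numerical
and design choices made where the method left room.

## The analysis in one paragraph

Blood DNA-methylation beta values (methylated fraction per CpG probe, in
[0, 1]) for FTD / FTD-ALS cases and controls are batch-adjusted, filtered,
imputed and zero-mean normalised; each probe is tested case-vs-control with
a pooled Student t and Benjamini–Hochberg (BH) control across probes.
Unsupervised clustering with Davies–Bouldin model selection asks whether the
FTD-ALS subtype separates. The significant genes are checked for
tissue-specific expression (hypergeometric overrepresentation against
atlas-derived specificity sets) and pathway membership. GWAS summary
statistics, pre-annotated with functional class and CADD deleteriousness,
supply the second "hit": genes with a nominally associated
(P < 0.05), exonic/splicing, nonsynonymous/stopgain, CADD > 15 variant
*and* a significant methylation probe form the candidate table. Candidates
are prioritised by their degree in a thresholded Spearman co-expression
network and checked against independent case/control expression sets with a
moderated t-test.

## Preprocessing

**Batch adjustment** (`combat_adjust()`) is a parametric empirical-Bayes
location/scale model. Each probe is standardised against the pooled
batch-mean fit; per-batch, per-probe location (`gamma`) and scale (`delta`)
effects are shrunk toward batch-level priors — normal for location,
inverse-gamma for scale, hyperparameters by method of moments on the raw
estimates — with the posterior solved by fixed-point iteration
(relative tolerance `1e-8`), then the matrix is back-transformed. Edge
behaviour is part of the contract: a single batch returns the input
unchanged; a batch with fewer than two samples is an error naming the
batch; constant probes are adjusted by location only; cells missing from a
probe are left missing and all moments use the observed cells. Adjustment
runs **before** probe filtering because the preprocessing cascade is
defined in that order; adjusted raw-scale values are clipped back to
[0, 1].

**Probe filtering** (`filter_probes()`) applies the standard 450K rules in
a fixed order, each probe charged to the *first* rule it fails, so the
per-rule counts in the `filter_report` sum exactly to the input probe
count: missingness strictly above 20%; chromosome X/Y; annotated SNP with
minor-allele frequency strictly above 0.1; control probes; blacklisted
("spurious") probes, consumed as a user-supplied flag rather than a
hard-coded list; and gene-region classes outside TSS1500, TSS200, 5'UTR,
1st exon, body, 3'UTR. Both thresholds are strict, so boundary probes
(exactly 20% missing, MAF exactly 0.1) are retained.

**Imputation** (`knn_impute()`, K = 3) fills each missing cell with the
unweighted mean of the K nearest probes' values at that sample. Because
probes share different numbers of observed samples, the distance is the
root-mean-square difference over co-observed samples — an
overlap-normalised Euclidean distance that is comparable across overlap
sizes. Neighbours must be observed at the target sample; if none is, the
probe's own mean is used and the event is reported. The implementation is
checked against a brute-force all-pairs oracle in the tests.

**Zero-mean normalisation** centres every probe at mean 0 across *all*
samples, cases and controls together, because the downstream direction call
reads hypermethylation as "case mean above 0". It is idempotent.

## Differential methylation

The per-probe test is the pooled-variance two-sample Student t with
`df = n_a + n_b − 2` (a Welch option exists but is off by default, matching
the method's plain reading of "Student t-test"). Degenerate probes with
zero pooled variance give `t = 0, p = 1` when the group means agree and the
smallest representable positive p (flagged) when they differ, so they can
never silently dominate a ranking. BH correction runs across the retained
probes — the multiplicity unit is the probe, not the gene, and the tested
count is exposed as `n_tests`. A probe annotated to several genes
contributes every symbol to the significant-gene set, which is why gene
counts can exceed probe counts. `gene_probe_report()` is a pure lookup into
the genome-wide result: requesting a gene never re-corrects its p-values.

## Class discovery

Clustering uses average linkage on Euclidean distances of the zero-mean
values — the method states neither linkage nor metric, and this is the
common default for methylation arrays; both are arguments. The number of
clusters is the minimiser of the Davies–Bouldin index over `k_range`
(default 2–6), ties toward the smaller k; a flat index curve (range within
1% of its level) triggers a warning because it indicates no real structure.
The association between clustering and diagnosis is a two-sided Fisher
exact test after collapsing one-vs-rest onto the cluster most enriched for
the target diagnosis (highest within-cluster target fraction, ties toward
the larger count). The method behind the original study's separation
p-value is not stated in its source; this package *defines* the test as
above and makes no claim to reproduce that particular number. PCA
(`pca_components()`) is the centred SVD on the significant-probe submatrix.

## Enrichment

Tissue-specificity sets are built per tissue by a gene-wise t-test of the
tissue's samples against all remaining samples, BH-corrected within the
tissue, keeping genes with adjusted p ≤ 0.05 *and* linear-scale fold
difference strictly above 1.5 or strictly below 1/1.5 ("absolute fold
difference", two-sided; expression must be nonnegative linear-scale
values). No exclusivity is imposed: a gene can enter two tissues' sets if
it passes both. The overrepresentation statistic is the exact
hypergeometric upper tail `P(X ≥ x)` computed in log space; BH correction
spans exactly the sets tested in one `enrich()` call, mirroring
per-resource corrections (e.g. 25 tissues, or 26 brain regions, in one
run). The universe size M is a declared property of each collection —
16,115 for a GTEx-style atlas, 18,107 / 23,093 for BrainSpan-style
resources, 25,318 for an hg19 pathway background — never inferred silently
from the sets. Keyword pre-selection of pathway collections
(`filter_brain_sets()`) is a case-insensitive substring match over set
names with a user-supplied keyword list, since no canonical "brain or
neurological" keyword list exists.

## GWAS integration

`filter_gwas()` keeps SNPs with unadjusted association p strictly below
0.05 and drops blacklisted genes. `double_hit_overlap()` is a single
hypergeometric upper-tail test of the GWAS-gene / methylation-gene overlap
against the declared background M (default 25,318, configurable — the
effective background behind the original study's overlap p is ambiguous,
so the package exposes M rather than tuning it). The candidate filter then
requires, per SNP: p < 0.05, exonic or splicing location, nonsynonymous or
stopgain consequence, CADD strictly above 15, and at least one
significantly methylated probe in the mapped gene; one output row per
retained SNP, joined with the gene's most significant probe, genes
partitioned by the probe t sign. `min_p_for_gene` is computed over the
*unfiltered* SNP table so intronic and intergenic SNPs count toward a
gene's best association. Variant annotation (functional class,
consequence, CADD) is consumed as input columns: these are external
database lookups, not part of this analysis. Coordinates are 1-based
inclusive; BED gene models for the synthetic positional mapper are
converted from 0-based half-open internally, and "chr1" / "1" naming is
normalised before colocalization, which by default tests exact containment
in the 2-bp CpG site (`window = 0`).

## Co-expression network

Spearman correlations (average ranks for ties) over the candidate genes,
with two-sided p from the t approximation
`t = ρ√((n−2)/(1−ρ²))`; constant genes are dropped with a warning. An edge
requires `|ρ| > 0.6` **and** unadjusted `p < 0.001` — both strict, no
multiplicity correction, as the thresholded-network definition prescribes.
Isolated genes are removed by default (`keep_isolated = FALSE`) so the
network contains only connected genes; degrees are re-derived from the
edge list at prioritisation time as an internal consistency check.

## Validation meta-analysis

Each validation set is tested case-vs-control with a moderated t: the
per-gene pooled variance is shrunk toward a common prior,
`s̃²ᵍ = (d₀s₀² + dᵍs²ᵍ)/(d₀+dᵍ)`, with `(d₀, s₀²)` estimated by method of
moments on the log sample variances (the digamma/trigamma identities of
the scaled-F marginal; the trigamma inverse is a Newton iteration). When
the observed variances are too homogeneous the `d₀ = ∞` limit (full
pooling) is used and reported. Injecting `d₀ = 0` recovers the ordinary
pooled t exactly, which the tests exploit, and the estimated fit is
cross-checked against an independent reference implementation. BH runs per
data set over that set's own platform probe count — validation platforms
differ in size and each set answers for its own multiplicity. A query gene
is "validated" by a set when significant there, with *no* direction
requirement by default (a `require_direction` flag adds the stricter
hyper ↔ down-regulated rule); genes absent from a platform are counted
not-assayed, distinct from not-DE, and the cross-set ranking (validating
sets, then best adjusted p) is monotone in added data sets.

## The synthetic-data generators

`simulate_methylation()` draws per-probe baselines from a bimodal logit
mixture and adds Gaussian noise on the logit scale before
inverse-transforming — this keeps the [0, 1] support and reproduces the
boundary-compressed, heteroscedastic noise of real beta values. Truly
differential probes (the designated truth set) get an exact ±`delta_beta`
case-mean shift on the beta scale, planted only on probes that survive
every filter, with baselines in [0.2, 0.8] so the shift stays
representable; configs whose shift cannot stay in [0, 1] are rejected.
Batches are assigned round-robin and contribute an additive location
offset and a multiplicative noise scale, which is exactly the structure
the batch adjustment estimates. Missingness is uniform missing-at-random —
the source analysis states no missingness mechanism, so no informative
pattern is invented. Defaults mirror the cohort the pipeline targets
(128 cases of which 7 FTD-ALS, 193 controls, two batches); the default
probe count (2,000) and truth size (50) are desk-scale choices so a full
run takes seconds, and the default noise (`sd_logit = 0.35`, about 0.05 on
the beta scale at mid-range methylation) is a free parameter chosen once —
per-probe variances are not reported for the original cohort.

`simulate_gwas()` draws uniform p-values with risk-gene SNPs forced below
0.05, functional classes with a configurable exonic fraction, consequences
only for coding classes, and CADD from a mixture with a configurable
fraction above 15. `simulate_expression_atlas()` plants tissue-specific
genes by raising their within-tissue log2 mean; `simulate_coexpr_blocks()`
plants correlated cliques through a shared latent factor
(`√ρ·factor + √(1−ρ)·noise`).

What the generators do **not** emulate: linkage disequilibrium and realistic
allele frequencies; probe-probe correlation along the genome; cell-type
composition and age/sex covariates; array-specific technical artefacts
beyond location/scale batch effects; real platform probe-to-gene
many-to-many maps beyond a small planted fraction of two-gene probes.
Passing tests therefore demonstrate that the *statistics* behave as
specified under the assumed structure — calibration under the null,
recovery of planted signal — not that any biological conclusion transfers
to a given cohort.

## Numerical choices and degenerate inputs

* BH adjustment delegates to the standard step-up implementation and
  rejects p-values outside (0, 1]; the test suite holds an independent
  step-up oracle.
* Hypergeometric and Fisher probabilities are computed exactly (log-space
  tails; exact conditional enumeration), never by normal approximation.
* Zero-variance probes, coincident cluster centroids, constant genes in
  correlation, empty contrast groups, and degenerate 2×2 tables each have
  a defined outcome (error, warning + neutral value, or flagged extreme),
  listed in the function documentation.
* Clustering ties: the merge order follows the standard agglomerative
  implementation; Davies–Bouldin ties between k values resolve to the
  smaller k.
* All simulators restore the caller's RNG state; every stochastic function
  of the pipeline is reproducible from integer seeds.

## Test and calibration design

Calibration checks pool null p-values over ≥100 independent seeds and
apply a Kolmogorov–Smirnov test at level 0.01. For discrete statistics
(hypergeometric enrichment, Fisher) exact uniformity holds only in the
continuous limit, so those checks use large counts (universes of 1,000–2,000
genes, sets and queries of 100–200) where the support is fine, and test the
one-sided alternative of excess small p-values — the direction that matters
for false positives. Recovery checks run at the planted-signal conditions
stated with them (e.g. Δβ = 0.15 at n = 50/50 over 1,000 probes for the
differential-methylation power check; ρ = 0.9 blocks of 10 genes for the
network check); the two fixtures that assert *exact* or *exclusive*
recovery (tissue sets, two-cluster separation) use effect-to-noise ratios
large enough that their premise — a false positive or a mixed cluster is
essentially impossible — actually holds. Problem sizes throughout the suite
(hundreds of probes, tens of samples, ~120 calibration seeds) are the
package's choice of desk scale: large enough for the asymptotics the checks
rely on, small enough that the whole suite runs in about a minute.

## Known limitations

* The main contrast models no covariates (age, sex, cell composition,
  smoking); the control-vs-external-control contrast is the only guard
  against cohort-level confounding, as in the method this package
  implements.
* Blood methylation is a proxy for brain; the tissue-enrichment stage
  quantifies, but cannot remove, that gap.
* The candidate filter inherits the annotation it is given: CADD scores and
  consequence calls are not recomputed, and a different annotation release
  will move genes in and out of the table.
* The double-hit overlap p depends visibly on the declared background M;
  the package refuses to guess it.
* The separation test is this package's definition (Fisher exact on the
  one-vs-rest collapse); other reasonable definitions would give other
  p-values.
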