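---
title: "Methods: integrated metabolome-microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated metabolome-microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabologenomics)
```

## The problem this package addresses

Dietary intervention studies in mice commonly collect two parallel
readouts from the same faecal samples: a targeted metabolome
(CE-TOFMS-style concentration tables for one to two hundred
metabolites) and a 16S rRNA amplicon survey summarised at genus level
(roughly a hundred genera).  The question is not only whether either
layer responds to diet, but which metabolite-microbe pairs move
together — for example whether short-chain fatty acids such as butyrate
track the abundance of putative producer genera and of the predicted
gene content for butyrate metabolism.  This package implements that
"metabologenomic" workflow as composable, tested R functions, and ships
a synthetic-data generator so every stage can be exercised and
calibrated without access to the original animals.

The emulated design is 6 control and 5 intervention-diet ("AD") mice,
each sampled at 8, 12, 24, 36 and 52 weeks of age: 55 samples with
repeated measures per mouse.

## Metabolome stage

**Quantification.**  Raw peak areas are referenced to the
internal standard of each metabolite's ion mode (methionine sulfone for
cations, camphor-10-sulfonic acid for anions):
`conc = (area / IS_area) / standard_relative_area * standard_concentration`,
yielding nmol per g faeces when sample masses are folded into the
standards table.  A sample lacking an internal-standard area cannot be
quantified at all and is rejected with a warning rather than silently
zeroed.

**Detection filter.**  "Not detected" is a first-class state: empty
cells on disk, `NA` in memory, never conflated with a measured zero.  A
metabolite is kept only when detected in at least 4 samples in *every*
diet group (`min_per_group = 4`).  The filter is idempotent and order
preserving.

**Imputation and scaling.**  Remaining `NA` cells are imputed as half
the per-metabolite minimum observed value — the standard metabolomics
convention for below-detection-limit data — before multivariate
analysis.  Features are then Pareto scaled: centred and divided by the
square root of the sample standard deviation (n−1 everywhere).  Pareto
scaling damps the dominance of high-abundance metabolites without
inflating near-constant ones the way unit-variance scaling does; a
zero-variance feature is centred and flagged instead of dividing by
zero.

**PCA.**  SVD on the scaled matrix, no further centring.  Axis signs
are made deterministic by forcing the largest-magnitude loading of each
component positive.  The loading report lists metabolites with
|coefficient| above a threshold (default 0.11 on PC2, the axis that
separates the diets in this design).

**OPLS-DA.**  Implemented in-package as Trygg–Wold NIPALS O-PLS:
class-orthogonal variation is removed component by component (default
1 orthogonal component, configurable — the number of useful orthogonal
components is data dependent and the convention in discriminant
metabolomics tools is to keep it small), then a single predictive
component is extracted against the ±1-coded class vector.  Features are
ranked by `cov(x_j, t_pred)`, the x-axis of an S-plot, with a report
threshold of 0.16 for metabolites and 0.11 for genera.  Predictive
ability Q2 is estimated by 7-fold cross-validation with venetian-blind
fold assignment after a seeded shuffle (the convention of the
commercial tool this models); folds are reduced with a message when
samples are fewer than folds.  `t_pred` and `t_orth` are orthogonal by
construction and the suite asserts it to 1e-8.

**Enrichment (MSEA/ORA).**  Over-representation of a query set (the
diet-significant metabolites) in each library pathway, via the
hypergeometric upper tail.  Each row reports `total` K, `hits` k,
`expect = K·n/N`, `fold = k/expect` (so `fold × expect = hits` exactly)
and p.  The library universe size N must be supplied with the library:
enrichment p-values are meaningless without an explicit universe, so
the TSV format stores the universe alongside the pathway memberships.

## Microbiome stage

**Rarefaction.**  Every sample is subsampled without replacement to a
common depth, default 16,014 reads, the filter-passed read count the
emulated workflow standardised on.  Samples below depth are dropped
with a warning.  Sampling is delegated to `vegan::rrarefy` under a
local seed; the suite checks exact totals and sampling-distribution
unbiasedness.

**Alpha diversity.**  Observed genera, bias-corrected Chao1
(`S + F1(F1−1)/(2(F2+1))`) and Shannon entropy (natural log), on the
rarefied integer table.  These are the defaults of the standard
amplicon pipelines; the workflow treats them as a negative control
(diet shifts composition without necessarily changing richness).

**UniFrac.**  Implemented in-package from the branch-length
definition, because the contract fixes the exact per-branch form and
the raw/normalised weighted variants.  For each tree edge the
abundance of its descendant leaves is accumulated per sample;
unweighted UniFrac is unique branch length over covered branch length,
weighted UniFrac is `Σ_b l_b |A_b/A_T − B_b/B_T|`, optionally divided
by `Σ_b l_b (A_b/A_T + B_b/B_T)`.  Raw (non-normalised) weighted
UniFrac is the default, matching the historical default of the
pipeline this emulates.  The implementation is verified against an
exhaustive branch-walk oracle on every rooted topology with up to 5
leaves and every presence/absence profile pair, and against
`phyloseq::UniFrac` on random instances.

**PCoA, ANOSIM.**  PCoA is Gower double-centring + eigendecomposition
(`stats::cmdscale`); negative eigenvalues are reported, not hidden, and
axis signs are deterministic.  ANOSIM uses `vegan::anosim` (999
seeded permutations, p with the +1 correction).

**LDA effect size.**  A two-class LEfSe-style score: per-sample
scaling to 1e6, Kruskal–Wallis screen at α = 0.05, then 30 bootstrap
rounds drawing two thirds of each class, fitting `MASS::lda` (with a
tiny jitter to keep the within-class covariance invertible) and
averaging a per-feature effect — the mean of the absolute class-mean
difference and the feature's contribution to the discriminant gap.
Score = log10(effect), signed by the enriched group, reported above
|2.0|.  The original tool's multi-subclass Wilcoxon step is omitted:
this design has no subclasses, and that restriction is documented
rather than half-implemented.

**Metagenome prediction.**  PICRUSt-style arithmetic on a supplied
gene-content reference: counts divided by 16S copy number, multiplied
by the taxon × KO matrix, aggregated into pathways through the KO →
pathway map (a KO in several pathways contributes to each).  The
operation is linear in the counts and the suite asserts it.  No NSTI
or real reference trees: the reference tables are explicit inputs.

## Integration stage

**Procrustes.**  The metabolome PCA scores and the weighted-UniFrac
PCoA scores are superimposed by least-squares Procrustes with
translation, uniform scaling and rotation/reflection over the first 3
dimensions.  The symmetric form (both configurations standardised) is
used so M² does not depend on which block is called the reference; by
convention the metabolome PCA is the reference configuration for the
reported coordinates.  M² = 0 iff the configurations agree up to a
similarity transform; the suite checks that invariance and a
brute-force grid-search minimum.

**Autocorrelation maps and clusters.**  Per block, a feature ×
feature Spearman correlation matrix.  Rows of that matrix are
clustered by Euclidean distance with complete-linkage agglomeration
and the tree is cut to exactly k clusters — 7 for metabolites, 5 for
genera, 3 for predicted gene sets.  Clustering correlation-matrix rows
(rather than raw profiles) groups features by the company they keep,
which is what the shared-pattern clusters are for; a caller can pass a
raw profile matrix instead.  Cluster labels are renumbered by first
appearance in feature order, making the assignment deterministic.

**Differential selection and the network.**  Each block is tested
feature-wise with the two-sided Mann–Whitney U test, BH-adjusted
within the block, selected at q < 0.05.  Observations pool the five
timepoints (n = 30 vs 25); a `per_subject` option averages within mice
first for callers worried about pseudo-replication.  Fold change is
mean(AD)/mean(control), reported to two decimals, with "−" when the
control mean is zero.  The network then computes Spearman rho and a
t-approximation p for every cross-block pair of selected features
(within-block pairs behind a flag, off by default — the portrayed
network is cross-type), BH-adjusts all computed pairs as one family,
and keeps q < 0.05 as signed edges.  Nodes carry block, cluster and
direction of change; export is GraphML plus a flat edge-list TSV.

**Statistical conventions.**  Two-sided p-values throughout.  The
Mann–Whitney p is exact by enumeration when the pooled n ≤ 12 with no
ties, and the tie- and continuity-corrected normal approximation
otherwise — the study's pooled per-feature tests (n = 55) always use
the approximation, while small per-timepoint contrasts get exact
p-values.  BH is applied per family (per block, per stage; the network
is one family), never pooled across blocks.  Degenerate inputs are
defined rather than accidental: an all-tied pooled sample gives p = 1,
a zero-variance feature gives an undefined (flagged) rho, and
undefined pairs are excluded from the FDR family with a warning.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical skeleton the analysis relies
on: 55 samples in two diet groups with stable subject identities;
log-normal metabolite concentrations (baseline log-mean 2 ± 1.2 on the
natural-log scale of nmol/g) with per-mouse random intercepts
(sd 0.3), residual noise (sd 0.6) and ~5% non-detections biased toward
low concentrations; 40 of 184 metabolites shifted by |log2 FC| = 2,
85% of them downward in AD (matching the observed preponderance of
decreases); Dirichlet-multinomial genus counts (concentration 200)
over a log-normal rank-abundance curve, 20,000–40,000 reads per sample
so the 16,014-read rarefaction is always exercised, 15 of 106 genera
with |log2 FC| = 2 effects on the Dirichlet weights; a random
bifurcating phylogeny with exponential branch lengths; and
metabolite–genus couplings through shared latent factors.  A coupling
with target Spearman ρ regenerates the metabolite on the log scale
from the genus' normal scores with mixing weight `r = 2 sin(πρ/6)`
(the bivariate-normal Pearson–Spearman map), so the realised rank
correlation lands within ±0.1 of the target at n = 55.  The default
couplings attach 6 planted metabolites to 6 AD-elevated genera at
ρ = 0.7, the gene-content reference gives those genera elevated counts
on a designated SCFA-pathway's KOs, and the pathway library places the
planted metabolites in one enriched pathway — giving ground truth for
differential recovery, MSEA ranking, metagenome prediction and network
recovery at once.

It does not emulate: compositional coupling between the two blocks
beyond the planted pairs, age trends, taxonomic label structure,
realistic phylogenetic signal in abundances (the tree is independent
of the abundance ranks), chimeras/contaminants, or any raw-read-level
artefact.  Passing tests on this generator therefore demonstrate that
the statistics recover the structure they claim to recover under a
clean repeated-measures two-group design — not that the pipeline is
robust to the full messiness of real amplicon data.

## Problem sizes and determinism

The test suite runs the generator at the full emulated scale (55 × 184
and 55 × 106) for the end-to-end recovery checks (20 seeds), a
100-seed null calibration of the network FDR on reduced 15-feature
blocks, and exhaustive small-instance oracles (all rooted trees to 5
leaves, all two-group rank splits to n = 10, 1,000 random BH vectors)
— sizes chosen so each property is checked exhaustively where
exhaustiveness is feasible and at the study's own scale where it is
not.  Every stochastic step takes an explicit seed; the pipeline
derives per-stage seeds from one master seed recorded in its JSON
manifest, and regenerating inputs from the same master seed is
byte-identical.

## Known limitations

- OPLS-DA Q2 is estimated for the one-predictive-component model only;
  no automatic component-count selection.
- The LDA effect size is the two-class recipe; multi-class and
  subclass designs are out of scope.
- Enrichment requires an explicit library universe; results are not
  comparable across libraries with different universes.
- The network's FDR family is "all pairs computed in one run": adding
  blocks changes the family and hence individual q-values.
- UniFrac requires every table taxon to be a tree leaf; there is no
  fuzzy matching or automatic pruning.
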