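---
title: "Methods: stratified miRNA-mRNA integration with stratomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified miRNA-mRNA integration with stratomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratomir)
```

## The analysis problem

Triple-negative breast cancer (TNBC) disproportionately affects Black women,
and obesity reshapes both miRNA and mRNA expression in breast tissue.
stratomir implements an integrative analysis for cohorts of the following
shape: paired tumor and adjacent-normal small-RNA libraries from patients
stratified by ancestry (European American, EA; African American, AA) and
BMI class (obese, BMI >= 30; lean, normal BMI), plus tumor-only mRNA
libraries from the same patients. The goal is a set of miRNAs *exclusively*
associated with tumors of obese patients within one ancestry, together with
the target genes they plausibly regulate.

The pipeline has six statistical stages, each exposed as ordinary functions
that take data frames or matrices and return tibbles:

1. **Count preprocessing** - low-count filtering, TMM normalization,
   log2-CPM, row Z-scores.
2. **Differential expression** - a negative-binomial Wald test per feature,
   with the paired design modeled by fixed patient effects.
3. **Signature subtraction** - set arithmetic that distills six
   tumor-vs-normal DE lists into ancestry-specific obesity signatures.
4. **Correlation network** - Spearman correlation over tumor samples,
   restricted to predicted miRNA-target pairs, with a sign-based
   direct/indirect regulation classification.
5. **Enrichment** - hypergeometric over-representation of network target
   genes in user-supplied gene sets (GMT).
6. **Separation check** - a two-cluster purity statistic that turns
   "perfect separation in the heatmap" into a number.

A synthetic-study generator (`simulate_study()`) produces data of exactly
this shape with known planted signal, so every stage is tested against
ground truth.

## Preprocessing

`filter_low_counts()` keeps a feature when it has at least `min_count = 5`
counts in at least 80% of samples. The fraction rule uses the ceiling: with
48 samples a feature must qualify in at least `ceiling(0.8 * 48) = 39`.
Ceiling is the conservative reading of "at least 5 counts in 80% of the
samples"; the filter is idempotent and applied globally across all samples
of an assay (per-stratum filtering is possible by subsetting first, but the
global filter is the default because one shared feature universe keeps the
downstream set arithmetic well defined).

`tmm_factors()` implements trimmed-mean-of-M-values normalization with the
method's published defaults: 30% two-sided trim on M-values, 5% on
A-values, precision weighting by the inverse asymptotic variance, reference
sample chosen by upper-quartile relative abundance closest to the mean.
Factors are re-centered to geometric mean 1. The implementation agrees with
`edgeR::calcNormFactors(method = "TMM")` to 1e-8, which the test suite
asserts; edgeR serves only as an independent oracle, never as the
implementation. Two numerical notes:

* A *pure depth change* (one sample's counts all doubled) leaves the
  composition factors at 1; depth is carried by the library size. The
  resulting log2-CPM values are invariant only up to the depth-dependence
  of the precision weights (about 6e-3 log2 units at typical depths), so
  the invariance test asserts 0.02, not machine precision.
* TMM assumes most features are not differentially expressed. With a large
  one-sided DE fraction (around 20% of features, all up) the trim window
  slides off the null features and fold changes are attenuated; the
  calibration simulations therefore plant balanced up/down effects, as the
  generator itself does.

`log2_normalize()` computes `log2(count / effective_size * 1e6 + 1)`; the
prior count of 1 maps zero counts to exactly 0 and is configurable.
`zscore_rows()` uses the sample (n - 1) standard deviation - the
convention of heatmap displays - and emits constant rows as all-zeros with
a warning rather than an error, because a constant filtered feature is a
display problem, not a data error.

## The differential-expression engine

The engine is a deliberate approximation of the DESeq2 family of NB Wald
tests, not a clone: the scientific content of this pipeline lies
downstream of the DE engine, which only needs to be a *correct* NB test.

* **Dispersions** (`estimate_dispersions()`): per-feature method-of-moments
  `phi_hat = max(phi_min, (s^2 - mu) / mu^2)` on offset-normalized counts
  under the `var = mu + phi mu^2` parameterization, then shrunk 50/50 (on
  the log scale) toward a log-log linear mean-dispersion trend. The floor
  is `phi_min = 1e-4`. The moment estimate pools all samples of the
  contrast stratum, so strongly DE features get inflated dispersions and
  conservative p-values; the null calibration is unaffected (the type-I
  fraction at p < 0.05 sits near 0.05 in the suite's Monte-Carlo check).
* **The fit**: per feature, `stats::glm.fit` with
  `MASS::negative.binomial(theta = 1/phi)` and a log effective-library-size
  offset. Tumor-vs-normal contrasts add fixed patient-indicator terms
  (the paired design); obese-vs-lean contrasts are unpaired by necessity.
  Wald z uses the dispersion-1 covariance; failed or non-converged fits are
  reported with `p = 1` and flag `"unstable"`, never a crash.
* **Thresholds**: miRNA contrasts call DE at BH-FDR <= 0.05 *and*
  |log2FC| >= 1 (the "fold change >= 2" rule, inclusive at the boundary,
  both directions); mRNA contrasts use raw p <= 0.05, reflecting the lower
  power of the 6-vs-6 unpaired comparison. Exactly one rule governs each
  table.
* No covariate adjustment (age, menopause) is applied; the paired design
  controls inter-individual variability for the tumor-vs-normal contrasts.

`run_study_contrasts()` produces the study's contrast set: miRNA
tumor-vs-normal for each ancestry at BMI strata both/obese/lean (six
tables) and mRNA obese-vs-lean per ancestry (two tables), with direction
conventions tumor-over-normal and obese-over-lean. DE runs on raw counts
with TMM effective sizes as offsets - TMM is the stated normalization of
the study design this models, and using it for the offsets resolves the
otherwise unusual "TMM then NB test" combination in one consistent way.

## Signature subtraction

`run_signature_pipeline()` is pure set algebra on feature ids (membership
by exact string; -5p/-3p arms are distinct features and never collapsed):

1. per ancestry: `obese_unique = obese_TvsN \ lean_TvsN` (and vice versa);
2. across ancestries: `ea_only = ea_obese_unique \ aa_obese_unique`;
3. the *shared core* - miRNAs DE between tumor and normal in **both**
   ancestries regardless of BMI - is subtracted from each ancestry-
   exclusive list to remove shared tumor biology.

The shared core defaults to the intersection of the two all-patients
contrasts (`shared_mode = "all_contrasts"`); an alternative reading that
intersects the per-ancestry unions of the stratified lists is available as
`shared_mode = "union_stratified"`. An optional normal-tissue background
list can be subtracted after stage 1; it is off by default because the
study design this models defines no such contrast table.

Every stage set, its cardinality and its parent sets are recorded, each
final signature member carries a provenance chain, and the disjointness
invariants (refined sets disjoint from each other and from the shared core)
are asserted on every run. On the bundled study-shaped Venn fixture the
chain reproduces 92/15 and 53/20 obese/lean-unique miRNAs, 79/40
ancestry-exclusive, a shared core of 61, and refined signatures of 55 (EA)
and 33 (AA).

## Correlation network and regulation classes

`correlate_pairs()` tests exactly the (miRNA, gene) pairs that satisfy all
three membership conditions - miRNA in the refined signature, gene in the
ancestry's mRNA DE list, pair present in the target-prediction table - and
nothing else. Correlation is Spearman's rho on midranks across **all**
tumor samples of the ancestry (obese and lean, n = 12 in the study shape):
using both BMI classes maximizes n and matches the obese-vs-lean
fold-change framing used for classification. miRNA and mRNA libraries are
matched by patient. Pairs are retained at p <= 0.05 inclusive, with **no**
multiple-testing correction on edge p-values - the edge list is an
exploratory candidate set, and the raw-p rule is part of the procedure
being modeled. Both the number of pairs tested and retained are recorded
on the result.

p-values come from `spearman_test()`: exact permutation enumeration of all
n! rank arrangements for n < 10 (at these sample sizes the t-approximation
is marginal), the t-approximation `t = rho sqrt((n-2)/(1-rho^2))`
otherwise. Ties get midranks, and the exact route conditions on the
observed tie pattern. Constant vectors have no defined correlation: the
pair is skipped and counted, with a warning.

`classify_edges()` applies the sign rule: an inverse correlation with
miRNA up and gene down in obese tumors is a candidate **direct**
post-transcriptional repression; inverse with miRNA down and gene up is
**indirect** (loss of miRNA-mediated control); positive correlations, and
the residual case of inverse correlation with concordant fold-change
signs, stay `positive_unclassified`. A fold change of exactly zero never
classifies. The three classes partition every edge list, and the class is
a pure function of the three signs. The miRNA obese-vs-lean fold changes
needed by the rule come from a dedicated unpaired tumor-only contrast that
`run_study()` fits per ancestry.

## Enrichment

`hypergeom_enrich()` computes the upper-tail hypergeometric p for each
gene set (`p = P[X >= k]`), BH-FDR across sets, and flags significance by
the raw p <= 0.05 rule with the FDR reported alongside. The default
universe is the set of genes surviving the mRNA count filter (the measured
background); `"geneset_union"` is available when no measured universe is
meaningful. Enrichment against a web pathway service is deliberately out
of scope: pathway-count results are database-version dependent, so the
package takes any GMT collection as input instead. Note that the
upper-tail p is monotone nonincreasing in the overlap k and also
nonincreasing in the universe size N - padding the universe makes a fixed
overlap rarer under the null, i.e. *more* significant, which is why the
measured-background default matters.

## Separation check

`two_cluster_purity()` makes the qualitative heatmap claim testable:
complete-linkage agglomerative clustering on Euclidean distances between
the Z-scored sample columns, cut at two clusters; purity is the fraction
of samples correctly grouped under the best cluster-to-label matching
(1 = perfect separation, 0.5 = chance for balanced labels). Columns are
sorted by sample id before clustering so distance ties resolve
deterministically; there is no random initialization.

## The synthetic-study generator

`simulate_study()` emulates the study design: 2 ancestries x 2 BMI classes
x 6 patients, each patient contributing a paired tumor/normal miRNA
library (48 samples) and a tumor-only mRNA library (24 samples). Counts
are NB with `var = mu + phi mu^2`, `phi = 0.2`, baseline means log-uniform
on [20, 3000], and log-normal library-size multipliers (sd 0.3) - values
chosen as typical of moderately dispersed bulk miRNA/mRNA counts at modest
depth. Defaults plant:

* stratum-specific tumor-vs-normal miRNA effects (|log2FC| = 2, random
  sign, tumor samples only; the adjacent-normal mean is the shared
  baseline, mirroring the paired contrast): 20 EA-obese, 12 EA-lean,
  16 AA-obese, 12 AA-lean, plus 10 shared-core miRNAs planted in tumors of
  all four strata so the refinement stage has real work to do;
* 60 obese-vs-lean DE genes per ancestry (|log2FC| = 2, random sign,
  applied to obese tumors);
* 30 true miRNA-target pairs: the target's NB mean is multiplied by
  `2^(repression_strength * z)` with `repression_strength = -1.5` and `z`
  the standardized abundance of the paired miRNA sample. Coupling at the
  mean level (rather than resampling) makes the induced negative
  correlation controllable and sign-correct. Target miRNAs are
  up-regulated members of the obese strata, so recovered pairs should
  classify as `direct`;
* a prediction table containing every true pair plus 3 decoys per true
  pair. Decoy genes are drawn from background genes - not from the planted
  DE genes, because a gene that genuinely tracks obesity is not a null
  partner for an obesity-tracking miRNA; a decoy models a target-prediction
  false positive, i.e. a pair with no regulatory coupling;
* one gene set containing all true targets (padded to size 50) among 15
  random sets, giving the enrichment stage a planted positive.

Planted features are drawn among features with baseline mean >= 50 so the
recovery conditions are well defined. All effect magnitudes are >= 1 in
log2 so planted features sit at or above the fold-change call threshold.
A single master seed feeds a named RNG substream per output object, so
identical (config, seed) gives byte-identical outputs and adding a new
output never perturbs existing ones.

What the generator does **not** emulate: FFPE degradation and UMI
artifacts, batch effects, isomiR structure, patient-level random effects,
and realistic mRNA depth heterogeneity. Passing the recovery tests
therefore shows the pipeline's statistical machinery is correct and
calibrated under its stated model - not that the biological conclusions of
any real cohort are reproduced.

## Verification problem sizes

The suite verifies, among others: null calibration of the Wald engine on
3 x 2000 NB features (phi = 0.1, 6 vs 6; raw p < 0.05 fraction within
[0.03, 0.07]); planted |log2FC| = 2 recovery to within 0.3 (median);
TMM/BH/exact-Spearman/hypergeometric agreement with independent
brute-force oracles; and five full default-scale synthetic studies
(800 miRNAs, 5000 genes) through every stage, requiring >= 70% signature
recall, >= 50% of true pairs recovered as `direct` edges, <= 20% decoy
edges, the planted pathway at rank 1, and separation purity 1.
`scripts/acceptance.R` recomputes the same quantities from scratch.

## Known limitations

* The DE engine approximates the DESeq2 family: no Cox-Reid adjusted
  profile likelihood, no outlier replacement, no LFC shrinkage, no
  independent filtering. Dispersion estimates pool over contrast groups
  and are conservative for strong effects.
* Edge p-values are uncorrected by design; the network is a candidate
  set, not a confirmatory inference.
* The measured-gene enrichment universe differs from web-service
  backgrounds, so absolute pathway counts are not comparable across tools.
* With fewer than ~4 informative features, the two-cluster purity of
  Z-scored data is unstable; the pipeline warns and skips rather than
  reporting a misleading number.
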