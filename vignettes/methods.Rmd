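---
title: "Phenotype clustering and CNV-process classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype clustering and CNV-process classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpheno)
```

`cnvpheno` connects two views of a neurodevelopmental cohort: a
multidimensional clinical phenotype, summarised as membership in one of
two data-driven severity subgroups, and a genetic profile, summarised as
the set of biological processes disrupted by rare copy-number variants
(CNVs) spanning brain-expressed genes. This vignette describes each
model, its assumptions and its tunable parameters, the synthetic data the
package validates itself on, and the design decisions taken where the
procedure was genuinely open.

## 1. Clinical preprocessing

Seven clinical fields enter the analysis: the dichotomous ADI-R verbal
status, the ADOS severity metric (1–10, defined only for modules 1–3),
three VABS subscale scores (communication, daily living, socialization),
a performance IQ, and gender.

**Categories.** ADOS severity collapses to Non-spectrum (1–3), ASD (4–5)
and Autism (6–10). A VABS subscale score of 70 or less is
"dysfunctional". IQ maps to severe intellectual disability below 50, mild
in [50, 70), and normal at 70 or above. The published cut-offs for IQ are
strict inequalities that leave 50 and 70 unassigned; we adopt the
conventional closed-above reading (≥ 70 normal, ≥ 50 mild) and expose the
two boundaries as the `iq_boundaries` argument of `derive_categories()`
for cohorts coded differently.

**Filtering.** Module-4 individuals carry no severity metric and are
dropped. A clinical feature is retained only when observed in strictly
more than 70 % of the remaining individuals; individuals missing more
than two retained features are then excluded. The individual rule is
applied to retained features only — a feature that was itself dropped for
incompleteness cannot count against an individual. `filter_cohort()` is
idempotent and logs every exclusion with its reason.

**Imputation.** `impute_missforest()` implements the iterative
random-forest scheme: mode/median initialisation, feature sweeps in order
of increasing missingness, refit-and-predict per feature, and a stopping
rule that returns the previous sweep the first time either the numeric
(normalised RMS) or the categorical (disagreement fraction) sweep-to-sweep
change increases. The random-forest base learner is the `randomForest`
package; the iteration logic, stopping rule and error measures are the
package's own. Imputation quality is reported as the proportion of
falsely classified categorical cells (PFC) on held-out masked data, with
a numeric NRMSE companion that is computed but never used for gating.

## 2. Phenotype clustering

**Encodings.** Verbal status and gender are nominal; the ADOS category
(Non-spectrum < ASD < Autism) and IQ category (severe < mild < normal)
are ordinal, contributing `|rank difference| / (R − 1)`; the VABS
subscales enter as their binary dysfunctional/normal categories by
default. The choice of categories over raw VABS scores matches how the
cluster profiles are reported downstream; `clustering_feature_spec(vabs_mode
= "raw")` switches to the numeric scale.

**Correlation screen.** Pearson correlations are computed on the raw
scores (the three VABS subscales correlate strongly through a shared
adaptive-functioning construct; their binary categories may not), and
connected components of the "> 0.75" graph form correlated groups. Every
member of any group has its Gower weight halved — per feature, not per
group, so a trio of correlated subscales still contributes 1.5 feature
weights in total. Membership in overlapping groups halves a weight only
once.

**Clustering.** Ward2 agglomeration (`stats::hclust`, method
`"ward.D2"`: Lance–Williams on squared dissimilarities, square-root
heights) on the weighted Gower matrix, cut at k = 2. Two subgroups is the
default because a severity dichotomy is the recurring structure in
multidimensional ASD phenotype clustering; a silhouette-over-k scan is
available as a diagnostic by calling `ahc_ward2()` with other k and
comparing `silhouette_report()` summaries.

**Pruning and validation.** Individuals with silhouette width below
0.300 are removed and the remainder re-clustered, in a single pass by
default (`iterate = TRUE` repeats to a fixpoint; the single pass is the
default because the removal-and-recluster step is described as a one-shot
cleanup, and iterating changes little on well-separated cohorts).
Stability is estimated by `bootstrap_stability()`: for each of B
resamples, the distinct resampled individuals are re-clustered and each
reference cluster records its best Jaccard overlap. We subset the
full-cohort dissimilarity matrix rather than recomputing it per resample
— with the default categorical encodings the per-feature ranks and ranges
are fixed by the level sets, so the two are identical, and this is the
convention of dissimilarity-input bootstrap validation in the clustering
literature. Boot means above 0.85 are read as stable.

**Feature contribution.** One feature at a time is removed, the cohort
re-clustered at the same k, new clusters matched to the reference by
greedy maximal overlap (ties toward the larger reference cluster), and
the change in per-cluster mean silhouette reported; positive values mean
the feature supports that cluster's cohesion.

## 3. CNV filtering and gene mapping

Coordinates are 0-based half-open throughout (`to_bed_coords()` converts
1-based inclusive input). A call is high-confidence when supported by at
least two callers and strictly larger than 30 kb. Rarity is assessed
against a control cohort: a case CNV's frequency is the fraction of
distinct control individuals carrying a same-type CNV with at least 50 %
reciprocal overlap, and calls at or above 1 % are removed. The
reciprocal-overlap matching rule is a design decision — the matching
criterion between case and control calls is not fully specified by the
procedure we follow — and both the threshold and the overlap fraction are
arguments. Deletions and duplications are filtered identically. A gene is
"hit" when its interval overlaps a retained CNV by at least one base and
carries the brain-expressed flag; an audit trail links every reported hit
to its source CNV.

## 4. Ontology, enrichment and redundancy reduction

The ontology is a single-rooted DAG of `is_a` edges (minimal OBO or
edge-list input; cycles, orphans and multiple roots are hard errors).
Annotations propagate to all ancestors (true-path rule). Term probability
is annotation-frequency based, `p(t) = |genes(t)|/|genes(root)|`, and
`IC(t) = −ln p(t)` — the definition SimRel itself requires, which is why
it is the default over purely structural IC variants.

Enrichment is the upper-tail hypergeometric test per term over an
annotated background (all annotated brain-expressed genes by default),
BH-corrected, significant at FDR < 0.05. Unannotated query genes are
dropped and counted, mirroring how enrichment services silently ignore
unknown identifiers.

Redundancy reduction processes significant terms in increasing p-value
order: a term joins the first group whose representative it resembles
with SimRel strictly above 0.7, else founds a group. The representative
is always the group's most significant term. This greedy
lowest-p-first rule is a deliberate, auditable approximation of
dispensability-based clustering; the audit in the test suite verifies
that no merged term sits at or below the threshold against its
representative.

## 5. Classification and IC stratification

The feature matrix is binary (individual × significant process, column
order by enrichment p-value), rows restricted to individuals with both a
cluster label and at least one disrupted process; the positive class is
the more severe cluster. The classifier is Bernoulli Naive Bayes with
Laplace `α = 1` — the faithful generative model for 0/1 features, exactly
testable against closed-form counts (the test suite also cross-checks
posteriors against `e1071::naiveBayes` on factor-coded data). Evaluation
is stratified five-fold cross-validation reporting precision, recall,
specificity and F score; a ratio with zero denominator in a fold is
reported as 0 and flagged, so degenerate folds deflate rather than
silently inflate means.

Per-individual IC is the sum of IC over disrupted representative
processes. `ic_quantiles()` ranks individuals by IC descending and splits
them into q near-equal groups, earlier quantiles taking the extra
individual when q does not divide n (1301 → 326, 325, 325, 325); ties
break by stable input order. `ic_stratified_evaluation()` then evaluates
the classifier on the cumulative subsets Q1, Q1–2, Q1–3 and all rows.
Published cumulative subset sizes of the form 325/649/974 cannot arise
from any consistent quantile rule (325 + 325 = 650); the package
documents its own remainder rule and does not attempt to reproduce that
arithmetic.

Process importance is permutation importance under stratified ten-fold
cross-validation: per fold, a random forest is fit on the training split
and each feature's held-out column permuted ten times, recording the mean
accuracy drop; importances average across folds. Held-out permutation
(rather than out-of-bag) is used because the protocol is explicitly
fold-based.

## 6. The synthetic-data generator

`generate_clinical()` draws a two-group cohort: a larger "milder" group
(verbal rate 0.97, mostly normal IQ at mean 95 ± 14, VABS means ~70–76)
and a smaller "severe" group (verbal rate 0.03, IQ 55 ± 16, VABS means
~42–44), mixing proportions 0.65/0.35, with the three VABS scores sharing
a per-individual latent (r ≈ 0.85) so the correlation screen has real
structure to find. These defaults are loosely calibrated to the category
margins a severity-split ASD cohort exhibits and are configuration, not
constants. Missingness is MCAR (`inject_missingness()`), each clinical
cell masked independently — the mechanism is pluggable because nothing is
known about the real missingness process; PFC evaluation on MCAR masks is
therefore an optimistic bound for informative missingness.

`generate_genes()` lays out non-overlapping genes (hand-countable
fixtures; the mapper itself supports overlapping genes).
`generate_ontology()` builds a single-rooted DAG by construction (each
new term draws parents among earlier terms) with at least one annotation
per gene, biased toward specific terms so IC spreads.

`generate_cnvs()` drives the genotype–phenotype link: every case
individual aims each CNV at every designated term set with a baseline
rate, at a group-independent "common process" set with its own rate, and
— if the individual is one of the `informative_fraction` signal carriers
of its latent group — at its own group's set with the baseline times an
odds multiplier. A multiplier of 1 therefore leaves the groups exactly
exchangeable (the null case), and the targeted hit-rate ratio grows
monotonically with the multiplier. Targeting picks a term uniformly and
then a gene within it, so small specific terms are hit as often as large
ones. Recurrent polymorphic regions present in a few percent of both
cohorts give the rarity filter realistic work. Sizes are log-normal
(median 80 kb) so most calls survive the 30 kb rule, callers are sampled
1–3, and CNVs exceeding a chromosome are resampled.

**What the generator does not emulate:** linkage structure, sex
chromosomes, de novo/inherited status, caller-specific error modes,
informative missingness, and the deep (16-level) topology of the real
Gene Ontology. Passing tests therefore demonstrate correctness of the
machinery and recoverability of planted signal under the stated
conditions — not clinical performance on real cohorts.

## 7. Validation studies and their sizes

Three seeded studies (exported as `experiment_*` functions, rerun by
`scripts/acceptance.R`) validate the pipeline end to end:

* **Latent-group recovery** (`experiment_parameter_recovery`): 20
  cohorts of n = 1000 under the default strong effects; after silhouette
  pruning the adjusted Rand index against the latent groups exceeds 0.9
  in every replicate and both clusters' bootstrap Jaccard means (B = 100)
  exceed the 0.85 stability criterion. B = 100 rather than 1000 keeps the
  study at ~45 s; at these separations the boot means are ≈ 1 and do not
  move with B.
* **IC-stratified precision contrast** (`experiment_ic_signal`): 20
  replicates of n = 1200 with signal carried by 30 % of each group
  (carriers aim 75 % of CNVs at their group's designated specific
  processes; everyone hits generic shared processes at 15 % and the other
  group's processes at 1 %). The designated processes are chosen
  specific (8–25 genes), pairwise SimRel ≤ 0.5 so redundancy reduction
  cannot collapse the two groups' signals, with the most specific set
  assigned to the severe class. First-quantile Naive Bayes precision
  exceeds whole-cohort precision in ≥ 18 of 20 replicates — the
  qualitative high-IC pattern. The genome (600 genes over 810 Mb) is
  sized so the hit-gene set stays well below the background and the
  enrichment test keeps power.
* **Null calibration** (`experiment_null_calibration`): with features
  independent of labels, mean CV recall sits in [0.4, 0.6] and every
  permutation importance lies within 2 SD of zero across 20 seeds.

## 8. Numerical choices and degenerate inputs

Zero-range numeric features contribute 0 to Gower distances with a
warning; singleton-cluster silhouettes are 0; equal agglomeration costs
are broken deterministically; a silhouette threshold that would empty the
cohort, a single-cluster silhouette request, a class missing from a
training fold, an all-missing feature, a zero marginal in a contingency
table, and annotation to an unknown term are all hard errors rather than
silent repairs. All randomness flows from one master seed through named
per-stage seeds (`provenance.json` records them), so any pipeline run is
byte-reproducible.

## 9. Known limitations

The IC definition is annotation-frequency based; cohorts annotated
against very shallow ontologies compress the IC range and weaken the
stratification. The greedy redundancy reduction is order-dependent by
design (p-value order) and can differ from dispensability-based tools on
ties. Bootstrap stability subsets a fixed dissimilarity matrix, which is
exact for categorical encodings but approximate if raw-score VABS mode is
combined with range-normalised features. The Fisher/χ² selection rule
(all expected counts ≥ 5, else Fisher for 2×2) is the package's own; any
fixed rule will occasionally disagree with per-table judgement calls.
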