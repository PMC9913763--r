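---
title: "Methods: dependence classification from factorial knockout RNA-seq"
author: "koSets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dependence classification from factorial knockout RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koSets)
```

# The inference problem

Two positively acting transcription factors, AtfA and AtfB, can regulate
overlapping target genes. Profiling the factorial strain panel — control,
ΔatfA, ΔatfB and the ΔatfAΔatfB double mutant — lets each gene be placed
in one of nine dependence categories by *which* deletions reduce its
expression:

| category | meaning | down-membership bits (s1, s2, s3, s11, s12) |
|---|---|---|
| AA | needs AtfA only | 1,0,1,1,0 |
| BB | needs AtfB only | 0,1,1,0,1 |
| AB | needs both; either deletion is as severe as the double | 1,1,1,0,0 |
| A/B | either factor suffices; only the double deletion matters | 0,0,1,1,1 |
| A-B1–A-B5 | both contribute; single deletions give intermediate levels | the five remaining patterns with s3 = 1 |

The five bits record downregulation in ΔatfA vs control (s1), ΔatfB vs
control (s2), the double vs control (s3), the double vs ΔatfB (s11) and
the double vs ΔatfA (s12). Using both directions of evidence (single vs
control *and* double vs the other single) is what suppresses
misidentification: each category corresponds to an intersection of two
independent set constructions, e.g. AA genes are
Set21 = Set8 ∩ Set18 with Set8 = (Set1 ∩ Set3) \\ Set2 and
Set18 = (Set11 ∩ Set13) \\ Set12. `assignCategory()` encodes the unique
bit pattern each of these intersections forces; `deriveSets()` and
`dependentSets()` evaluate the literal formulas, and the test suite
verifies that the two routes agree on all 32 patterns and that exactly
nine patterns receive a category. The AtfA-dependent set is
Set26 = Set21 ∪ Set23 ∪ Set24 ∪ Set25, the AtfB-dependent set
Set27 = Set22 ∪ Set23 ∪ Set24 ∪ Set25; because their constituents are
pairwise disjoint, the totals always equal the sum of the category
breakdown, and `summarizeCondition()` enforces this partition.

Each (cell type × treatment) condition is analyzed independently; the
upregulated mirror system (Set1⁺–Set27⁺) applies the identical algebra to
the upregulation calls. Set0/Set0⁺ hold the MSB stress-responsive genes
of the control strain; `msbResponsive()` also exposes the any-strain
union used when "MSB stress-responsive" is meant across the panel.

# Differential expression

The engine is deliberately simple and fully specified:

* **Normalization** — median-of-ratios size factors over genes positive
  in every sample of the comparison.
* **Dispersion** — per-gene method of moments,
  α = max(floor, (v − m)/m²) with v the pooled within-group variance and
  m the grand mean of normalized counts; floor 1e−8; no empirical-Bayes
  shrinkage, no outlier replacement, no independent filtering. For the
  five strain comparisons of a condition, `callDependence()` pools the
  estimate over all four strains (`conditionDispersion()`, 12 samples,
  8 residual df) rather than over the two groups of one comparison
  (4 df), which roughly halves the estimate's noise at no modelling
  cost.
* **Model** — NB log-link GLM, mean = sizefactor × exp(β₀ + β_batch +
  β_group), fitted by Fisher scoring (tolerance 1e−8 on the coefficient
  change, at most 100 iterations, linear predictor clamped to ±30 so
  groups with all-zero counts converge to a finite, extreme fold
  change). The batch term is additive on the log scale and is used for
  the conidial scenario, whose samples span two experiments.
* **Test** — Wald statistic z = β_group/se referenced to a **t
  distribution with the dispersion estimate's residual df** rather than
  a standard normal. With three replicates per group a plug-in normal
  reference is visibly anti-conservative (about twice the nominal
  type-I error in our null simulations); the t reference restores
  calibration to within half a percentage point of nominal across
  dispersion regimes, at the cost of conservatism for near-Poisson
  genes. BH adjustment is applied within each comparison over the
  tested genes (all-zero genes are `not_tested` and excluded from the
  denominator).

## Regulation calls and the significance gate

A gene is called regulated only by a strict fold-change rule: up if
log2FC > 1, down if log2FC < −1. What to require on top of the fold
change is genuinely open — the source methodology defines regulation
purely by |log2FC| > 1 while computing those fold changes with a DE tool,
implying some significance screen without stating it. `classifyRegulated()`
exposes three gates:

* `"nominal"` (default): the call's direction must have one-sided
  nominal evidence at α (one-sided t p < 0.05). This suppresses the
  spurious |log2FC| > 1 excursions of near-zero-count genes — which
  otherwise contaminate the A-B categories with mislabelled AA/BB genes
  — without the multiplicity penalty of a BH gate, which in a
  three-replicate design masks genuine 16-fold effects in weakly
  expressed genes and roughly halves Set26/Set27 recall in simulation.
* `"adjusted"`: BH padj < α, the conservative choice for screening-style
  use.
* `"none"`: the literal fold-change-only rule.

# The synthetic generator

`simulateExperiment()` draws one sample per (strain, treatment,
replicate): counts are NB(mean = baseline × strain multiplier × treatment
multiplier × depth factor × batch factor, dispersion α). Defaults, chosen
once as typical bulk RNA-seq values:

* baselines log-uniform over [10, 10⁴] expected counts at the 10⁶-read
  reference depth; gene lengths log-uniform over [316 bp, 10 kb];
* per-gene dispersion gamma with shape 2 and mean 0.05;
* effect multipliers high = 1, mid = 0.25, low = 0.0625, i.e. log2 gaps
  of 2, so every designed contrast clears the |log2FC| > 1 threshold
  with one unit of margin;
* class proportions: AA 5%, BB 2%, AB 1%, A/B 1%, each A-B sub-class
  0.5%, MSB-up 5%, MSB-down 5%, remainder unaffected;
* MSB-responsive genes shift 4-fold (up or down) under MSB in every
  strain; dependence categories and MSB response are disjoint classes;
* three replicates per group; per-sample depth jitter lognormal(0, 0.05);
* conidium scenario: two batches (replicates alternate) with a per-gene
  lognormal(0, 0.1) batch factor, mimicking a two-experiment origin;
* two knockout marker genes, `atfA` and `atfB`: each has zero mean in
  the strains carrying its deletion, and `atfB` is additionally reduced
  to the mid level in the ΔatfA background, emulating the downregulation
  of *atfB* upon *atfA* deletion. Markers carry no category and are
  excluded from recovery scoring.

Every multiplier pattern comes from `canonicalPattern()`, whose
noiseless log2 ratios reproduce exactly the category's membership bits —
a property the tests assert for all nine categories. All randomness
derives from one seed; the generator order (baselines, lengths,
dispersions, classes, batch factors, depth jitter, counts) is fixed, so
identical configurations are bitwise reproducible.

What the generator does **not** emulate: count correlation between genes,
length-dependent sampling bias, 3'-coverage effects, condition-dependent
dispersion, incomplete knockouts, or genes whose category differs between
treatments or cell types. Recovery results on synthetic data therefore
demonstrate the pipeline's correctness and its power at given depths and
effect sizes, not performance on any particular real data set.

# Enrichment and reporting

`fisherEnrichment()` computes the one-sided enrichment p-value as the
hypergeometric tail P(X ≥ overlap) — identical to a one-sided Fisher
exact test on the 2×2 table — with BH adjustment across the groups of one
call; raw p-values are retained so either convention can be reported. The
universe defaults to the genes tested in the condition.
`msbCrosstab()` annotates a dependent set with its Set0/Set0⁺ overlaps
and their enrichment, reproducing the "(x upregulated and y downregulated
MSB stress-responsive genes)" lines of the condition summaries;
`crossConditionOverlaps()` tabulates overlaps between two conditions, with
percentages relative to the reference condition rounded half-up to whole
percent, matching the published presentation.

# Numerical and design notes

* Strict inequalities throughout the call rule: log2FC = −1 exactly is
  never a call.
* Genes not tested in any required comparison of a condition are
  excluded from that condition's universe and hence from all sets.
* Ties and degenerate fits: genes whose Fisher scoring does not converge
  are flagged `not_converged` and excluded from calls and from the BH
  denominator; all-zero groups converge to clamped, finite estimates
  with very large standard errors, so gated calls on them require
  evidence from the other comparisons.
* `setSystemFromMembership()` provides a direct entry into the algebra
  from explicit bit patterns; this is how published per-category
  breakdowns are replayed through the machinery in the acceptance
  script.
* Problem sizes used by the validation suite were chosen to exercise the
  pipeline at realistic scale while keeping the default test run short:
  10,000 genes for end-to-end recovery, 2,000 null genes for type-I
  calibration, and exhaustive enumeration up to universe size 25 for the
  hypergeometric oracle.

# Known limitations

* The DE engine is a transparent reimplementation of the
  normalization/GLM/Wald contract, not a drop-in for any specific DESeq2
  version: no dispersion shrinkage, no Cook's-distance outlier handling,
  no independent filtering. On well-behaved simulated data its log2 fold
  changes correlate > 0.98 with DESeq2's (a cross-check in the test
  suite), but p-values differ by design.
* Dependence categories are purely observational set labels; the package
  deliberately makes no claim about direct versus indirect regulation or
  heterodimer formation.
* With three replicates, power for 2-fold effects below ~20 expected
  counts is intrinsically poor; the A-B sub-categories are the first to
  suffer, whichever gate is chosen.
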