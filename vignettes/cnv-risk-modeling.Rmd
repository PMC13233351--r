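---
title: "Window-level CNV risk modeling in admixed mNGS data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-level CNV risk modeling in admixed mNGS data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how the pieces of `cnvrisk` fit together, the
assumptions behind each stage, and the reasoning behind the design choices
that were genuinely open. The README shows the package in action; this
document explains why it is built the way it is.

## The modeling problem

A BALF mNGS library yields two usable signals per sample: a shallow host
read-depth profile and a microbial species count vector. The host profile
is too thin for variant-level analysis, so copy-number imbalance is
summarized at the scale of 1-Mb windows — large enough that a window
collects hundreds of reads at 0.05–1× coverage, small enough to resolve
arm-level and large focal events. The modeling task is binary: malignant
versus non-malignant, with the classifier consuming per-window Z scores,
species counts, or both.

Two facts shape the design. First, tumor DNA is diluted: at tumor fraction
$tf$ and copy number $cn$, expected window coverage is multiplied by
$(1-tf) + tf \cdot cn/2$, so a single-copy gain at $tf = 0.3$ moves
coverage by only 15%. Detecting that on top of depth, GC and batch
variation is the entire point of the normalization cascade. Second,
clinical labels are heterogeneous: a minority of samples carry definitive
diagnoses, many carry only suspicion. The pipeline therefore separates a
high-quality training set, a weakly labeled pool used solely through
pseudo-labeling, and an untouched evaluation set.

## The Z-score cascade and its assumptions

Each stage removes one nuisance source, and each assumes the previous
stages did their job:

1. **Counts-per-million normalization** removes library size. Assumes the
   profile *shape*, not total depth, carries signal — true once counts are
   per-window aggregates.
2. **Per-sample GC correction** divides by a local-regression fit of value
   against window GC (`loess`, span 0.3, quadratic, `surface = "direct"`
   so predictions are exact rather than interpolated), then rescales to
   preserve the sample median. Assumes GC bias is smooth and unimodal in
   GC — the standard observation for PCR-amplified short-read libraries.
   Mappability is handled by masking below 0.8 rather than weighting:
   low-mappability windows are few and individually unreliable, so
   down-weighting buys little over exclusion.
3. **Log2 ratio against the reference median** converts corrected coverage
   to a symmetric gain/loss scale. The per-window median (not mean) of the
   corrected reference is robust to the occasional aberrant reference
   sample. Windows with zero sample coverage are masked, not clamped — a
   zero at 500 expected reads is missingness, not a 2^-inf loss.
4. **PCA denoising** removes reference-shared background (depth gradients,
   batch): profiles are centered by the reference mean, projected onto the
   top *k* reference components, and the projection subtracted.
5. **Z scoring** standardizes by the per-window SD of the
   component-removed reference profiles, floored at `sigma_floor = 1e-4`
   so a degenerate (constant) reference window cannot produce infinite Z.
   Masked windows become Z = 0 ("no deviation") — neutral for tree
   splits, which is what consumes them.

The availability filter (window kept iff ≥ 25% of samples have ≥ 1 read,
both thresholds inclusive) runs on *raw* counts, so a window is dropped
for being unreliably covered, never for being biologically extreme.

### Choosing k: why not the usual eigenvalue heuristics

The number of components to remove is the one genuinely consequential free
parameter in the cascade. A Kaiser-type rule (keep eigenvalues above the
mean) fails here: with many more windows than reference samples, the noise
eigenvalue spectrum is spread by Marchenko–Pastur, a large fraction of
eigenvalues exceed the mean even for pure noise, and removing those
components steals real variance from the per-window SD. The symptom is
quiet but serious: $\sigma_b$ is underestimated, every Z inflates, and the
null tail $P(|Z|>3)$ roughly doubles — which would leak false copy-number
signal into every downstream model.

`k_components = "auto"` therefore uses permutation calibration (parallel
analysis): the observed eigenvalues are compared against the largest
eigenvalue obtained after independently permuting each window column of
the reference (three permutations, internally seeded so the fit is a pure
function of its input), and only components above that null edge are
removed, capped at 10. On a structureless reference this selects k ≈ 0 and
Z stays calibrated (the test suite checks `|mean| < 0.05`,
`SD ∈ [0.9, 1.1]`, and `P(|Z|>3) = 0.0027 ± 0.0015` on a 200-reference /
100-test null cohort); with genuine shared batch factors present the rule
recovers their rank. An explicit integer `k` bypasses the heuristic
entirely.

## Microbial features

Species detection uses a strict `> 2` reads rule — at BALF depths, one or
two assigned reads are as likely to be contamination, index hopping or
classifier misassignment as real organisms. Retention requires detection
in ≥ 10% of samples (inclusive), and feature values stay raw read counts:
the tree learners are scale-free, and normalizing sparse counts would
manufacture compositional artifacts. This is a documented limitation, not
an oversight — count features confound organism abundance with host-read
fraction, one plausible reason microbial features travel poorly across
cohorts. Shannon diversity is reported in natural log.

## Classifier harness

Three methods sit behind one interface. Baseline development uses
stratified five-fold CV over a small fixed grid (boosting: rounds
{50, 100} × depth {3, 6}; forest: mtry {½, 1, 2} × `floor(sqrt(p))`),
selected by mean out-of-fold AUROC; the winner is refit on all training
data. Extension refits skip CV and use fixed settings — boosting with 100
rounds, depth 6, learning rate 0.3, no subsampling; forest with 500 trees
and `mtry = floor(sqrt(p))`; plain binomial GLM — so extension training is
deterministic given a seed.

The GLM is deliberately fit by unpenalized maximum likelihood through a
pivoted QR (`glm.fit`), which drops aliased columns and warns when
p ≫ n makes the fit rank-deficient. That degeneracy is informative: the
linear baseline *should* collapse on 2,500-dimensional window features,
and replacing it with a tuned penalized model would change the question
the comparison asks. Aliased coefficients are treated as zero at
prediction time.

Decision threshold for confusion metrics is 0.5 unless overridden;
probability, not the hard label, feeds AUC.

## Pseudo-label extension

One round only: the default baseline model (boosted trees on CNV features)
scores the weak pool once, samples with probability strictly above the
threshold (default 0.8) join the training set labeled malignant, and every
method/feature combination refits on the same extended set. Three choices
deserve justification:

- **Only positives are promoted.** The weak pool is enriched for suspected
  malignancy; a confident "non-malignant" prediction on a suspected case
  is exactly the kind of prediction pseudo-labeling should not trust.
- **A single shared selection**, made by the default model rather than
  per-model selections, keeps the extended training sets identical across
  the comparison grid — otherwise "strategy" and "selection quality" are
  confounded.
- **No iteration.** Repeated self-training compounds selection bias; the
  framework measures whether weak data helps at all, which one round
  answers.

The simulator stores a hidden data-generating truth for weak samples
(their recorded "suspected" annotation is independently corrupted by
`weak_label_noise`), so pseudo-label precision is directly measurable; the
acceptance suite requires precision > 0.9 at threshold 0.8 under a
strong-signal cohort.

## Evaluation

Sensitivity, specificity, accuracy and Youden index at the decision
threshold; Mann–Whitney AUC with midrank tie handling (checked against an
exhaustive pair-count oracle in the tests). Confidence intervals are
stratified bootstrap percentile intervals (default 2,000 replicates,
seeded): resampling positives and negatives separately keeps every
replicate two-class, and the percentile method makes no normality or
variance assumption that the small, imbalanced evaluation sets here would
violate. The comparison table enforces a hard leakage check — any overlap
between a model's training ids and the evaluation ids is a fatal error,
not a warning.

Feature importance for interval mapping is the method's native measure
(gain, impurity decrease, |coefficient|). Note one behavioral asymmetry
the tests document: boosted trees concentrate gain on one member of a
correlated block of informative windows, while the forest's per-node
feature subsampling spreads impurity importance across the block — so
planted-segment recovery is assessed with the forest model.

## What the simulator does and does not emulate

`simulate_cohort()` draws per-window counts as negative binomial with mean
`mean_reads_per_bin` (default 500, matching ~0.025–0.05× coverage of a
1-Mb window with 50-bp reads) modulated by a unimodal GC curve
(`exp(-s (gc-0.45)^2)`), a low-rank multiplicative batch term
`exp(L F)`, and the admixture multiplier in malignant samples. Defaults:
NB size 500 (variance ≈ twice the mean at 500 reads — mild overdispersion
typical of window-aggregated shallow WGS), GC strength 1, two latent
factors of loading SD 0.05, tumor fractions 0.2–0.6, four 20-window
segments per malignant sample with copy numbers {0, 1, 3, 4}. Microbial
counts are sparse NB draws with per-species prevalence and lognormal
abundance; by default they are independent of the label, with an optional
abundance-shift knob for power studies.

What it does *not* emulate — and therefore what passing tests do not
demonstrate about real data: read-level artifacts (the simulation starts
at window counts), focal sub-window events, subclonal mixtures of multiple
tumor fractions, replication-timing and fragmentation coverage waves,
cross-sample contamination, and any realistic microbial community
structure (no taxon correlations, no contamination profile shared across a
sequencing run). The simulator establishes that the pipeline recovers what
its model says it should recover; transportability to clinical cohorts is
an empirical question the package cannot settle.

## Numerical and degenerate-input policy

- Coordinates are 0-based half-open (BED convention); reads are assigned
  to windows by leftmost position; boundary reads at a window start belong
  to that window.
- All-zero samples are excluded from normalization with a warning, never
  silently rescaled.
- Fewer than 10 usable windows, empty matrices, single-class labels and
  evaluation/training overlap raise classed errors
  (`cnvrisk_invalid_input`, `cnvrisk_schema_error`,
  `cnvrisk_leakage_error`); the CLI maps schema errors to exit code 2 and
  leakage to 3.
- Constant scores yield AUC 0.5 with a warning; all-zero importance yields
  an empty ranking with a warning, never an arbitrary ordering presented
  as meaningful.
- References below 30 samples warn about unstable per-window SDs but are
  permitted (minimum 2); the library default mirrors a 200-sample
  non-malignant baseline.
- CV ties on mean AUROC resolve to the first grid row, so tuning is
  deterministic.

## Problem sizes in the test and acceptance suites

The suites run cohorts of 150–300 labeled samples over 120–500 windows
with 80–100 weak samples — sizes chosen so every stochastic check has
comfortable Monte-Carlo margins (e.g., ~50,000 null Z values for the tail
check, evaluation sets of ~65 samples for the Youden-gap comparisons)
while the whole suite stays convenient to run routinely. The acceptance
script's Youden-gap margin of 0.2 for "combined does not beat CNV-only"
corresponds to about two standard errors of a Youden difference at that
evaluation size.

## Known limitations

- No segmentation or discrete CNV calling: windows are scored, not merged
  into events, because the classifier consumes window Z scores directly.
- The reference baseline is not aberration-masked; a contaminated
  "non-malignant" reference would inflate σ and mute sensitivity.
- Microbial counts are unnormalized by design (see above).
- Bootstrap CIs are percentile intervals; for metrics at the boundary
  (sensitivity 1.0) they degenerate to zero width.
- The GLM is a diagnostic baseline, not a usable classifier, at these
  dimensionalities.
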