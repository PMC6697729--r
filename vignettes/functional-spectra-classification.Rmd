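---
title: "Classifying molecular subtypes from functional spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying molecular subtypes from functional spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subspectra)
```

## The problem

Transcriptome-based subtyping systems (CMS in colorectal cancer, the
PAM50 intrinsic subtypes in breast cancer) assign tumours to molecular
classes from gene expression. Classifiers built directly on gene-level
signatures travel poorly: expression platforms annotate different gene
universes, batch effects shift and rescale individual genes, and most
signature classifiers need a whole cohort before they can score anyone,
which blocks clinical single-patient use. `subspectra` addresses all
three problems by changing the representation: each sample's expression
profile is replaced by a **functional spectrum** — a vector of gene-set
enrichment scores — and a feedforward neural network is trained on
spectra rather than genes. A pathway's enrichment score is driven by the
collective behaviour of its members, so losing a fraction of genes, or
distorting each gene by an affine batch effect, perturbs the spectrum far
less than it perturbs any individual signature gene.

## The enrichment statistic

For one sample, per-gene log2 fold changes `d` are computed against a
background signal and ranked in descending order (stable ties: input
order). For a gene set `C` with `|C|` of the `N` ranked genes, walk the
ranking from top to bottom and accumulate

* `+ |d_g| / sum(|d| over genes of C)` when gene `g` belongs to `C`,
* `- 1 / (N - |C|)` otherwise.

The enrichment score (ES) is the value of this running sum furthest from
zero, a signed quantity in `[-1, 1]`: positive when the set's genes
concentrate at the top of the ranking, negative at the bottom. On an
exact tie in absolute value between the maximum and minimum excursion the
earliest position wins — a documented determinism rule, since the
statistic itself does not order tied extrema. Genes of `C` that the
platform did not measure simply drop out of the walk; a set with fewer
than `min_overlap` measured members (default 1, i.e. only entirely absent
sets) receives ES = 0 so every spectrum keeps the full collection's
dimensionality, which the fixed-size network input requires.

Two degenerate inputs are refused rather than patched: a set covering
*every* ranked gene (the miss penalty divides by zero) and all-zero hit
weights (a sample identical to its background carries no information).

## Backgrounds: cohorts and single samples

In batch mode the background is the cohort's per-gene mean expression
(`batch_spectra(..., "cohort_mean")`). The choice is consistent with the
single-sample path, whose reference profile is also a cohort average; a
fixed reference profile can be supplied instead when spectra must be
comparable across batches.

A single sample has no cohort. The **single-sample predictor** rescales
the profile to a stored reference — the per-gene mean of the training
cohort — by ordinary least squares with intercept, `lm(sample ~
reference)` over the shared genes (at least 10 required), and uses the
regression **residuals** as fold changes. The regression direction is a
design choice: we regress the sample on the reference so the residuals
are the sample's deviation from its platform-adjusted expected
expression. Residuals are invariant to additive shifts of the sample and
scale jointly under positive scaling, so the ES *ranks* are unchanged by
affine platform distortion — the property that makes one-patient
classification workable across platforms. A sample that is exactly an
affine transform of the reference (all residuals below 1e-9) is refused
as carrying no signal.

## The network

The classifier is a fully connected multilayer perceptron with Tanh
hidden activations and a SoftMax output, default hidden layout
2000/500/120/30/10. Weights start from the uniform Xavier/Glorot scheme
(bound `sqrt(6/(fan_in+fan_out))`, the variant matched to Tanh), biases
at zero. Training minimises multiclass cross-entropy by mini-batch
SGD with momentum (defaults: learning rate 0.01, momentum 0.9, batch 64,
500 epochs) or AdaDelta (rho 0.95, epsilon 1e-6). Epoch count, batch
size and the absence of early stopping are engineering defaults, all
configurable. Spectra are not standardised before the network: ES values
already live in `[-1, 1]`. Everything is single-threaded and seeded —
initialisation and per-epoch shuffling draw from one RNG stream — so the
same seed, data and configuration reproduce bit-identical parameters.

The last hidden layer (10 units by default) yields the **deep
features**: a compressed, trainable representation of each sample.
`feature_set_correlation()` annotates each feature by the gene sets whose
enrichment scores correlate most strongly with it (by `|r|`, either
sign); `feature_cluster()` groups features by average-linkage clustering
of the distance `1 - |r|`, under which a feature and its negation are
identical; `average_silhouette_width()` quantifies within-subtype
compactness, and `pca_project()` gives deterministic two-dimensional
views (each component's largest-magnitude loading is made positive).

## Classification and the UNCLASSIFIED outcome

A sample is assigned the class with the largest posterior only when that
posterior strictly exceeds the threshold (default 0.5); otherwise the
result is `UNCLASSIFIED`, an explicit outcome rather than a forced call.
Evaluation reports per-class sensitivity `TP/(TP+FN)`, specificity
`TN/(TN+FP)` and balanced accuracy `(sens+spec)/2`, macro means, overall
accuracy, and the unclassified rate. Unclassified samples are excluded
from the sensitivity/specificity denominators (their rate is a separate
quantity); a class absent from the truth has undefined sensitivity and is
excluded from the macro means rather than imputed. Spectra are matched
to a model by gene-set *name*, and a model refuses spectra whose names
differ — misaligned columns would otherwise fail silently.

## What the synthetic cohorts emulate

No public tumour cohort ships with the package, so the test bed is a
generator whose signal structure is exactly what the spectrum transform
is built to detect: subtype identity expressed as coordinated shifts of
whole gene sets. Gene-level baselines are drawn from Uniform(4, 12) on
the log2 scale (the bulk of log2 microarray/RNA-seq intensity), noise is
Gaussian, and each class shifts the members of its two designated
20-gene sets by +2 log2 units — a strong but realistic pathway
activation. The default design (4 classes, 2000 genes, 200 samples, 100
sets) is deliberately compact; `make_platform_variant()` adds the two
cross-platform corruptions the method claims robustness to, random gene
loss and gene-wise affine distortion.

What the generator does **not** model: count noise (negative binomial,
library size), correlated gene networks, overlapping pathway membership,
unbalanced or ambiguous subtypes, and label noise. Passing tests
therefore demonstrate that the implementation recovers planted
pathway-level structure and honours its invariants — not that the
classifier reaches any particular accuracy on real tumours.

## Numerical and design choices

* Duplicate gene rows collapse to the highest-mean row (deterministic;
  the common microarray convention). Missing values are rejected at
  load, not imputed.
* MAD gene ranking omits the 1.4826 consistency constant — it rescales
  every gene alike and cannot change the ranking.
* TPM conversion applies `log2(x * 1e6 + 1)`; the +1 pseudocount maps
  zero abundance to zero.
* The null-control check compares holdout *overall accuracy* (and mean
  sensitivity) with chance 1/K: macro balanced accuracy has expectation
  0.5 for any truth-independent predictor, so it cannot serve as a
  chance-level statistic.
* Equal-weight limit: with all `|d|` equal the ES reduces to the classic
  unweighted KS running-sum statistic; at an exact `|max| = |min|` tie
  the sign is fixed by the earliest-position rule, and one-ulp rounding
  can differ between algebraically equal codings of the step size —
  tied instances are excluded from the equivalence check.
* Silhouette widths use Euclidean distance via `cluster::silhouette`
  (singleton classes get width 0); an O(n^2) double loop serves as the
  independent oracle in the tests.

## Problem sizes used by the tests and the acceptance script

The shipped end-to-end runs use the default synthetic design (200
samples, 2000 genes, 100 sets) with a reduced hidden layout
200/50/12/10, 250 epochs, batch 32, and a stratified 30% holdout; the
full 2000/500/120/30/10 architecture is exercised alongside (it trains
the same way, only slower). At these sizes holdout balanced accuracy is
1.0, no holdout sample is unclassified at threshold 0.5, single-sample
and batch predictions agree on 100% of holdout samples, halving the gene
universe costs no balanced accuracy, and deep-feature ASW (~0.9) clearly
exceeds raw top-gene ASW (~0.27); signal-free cohorts classify at chance.
`scripts/acceptance.R` recomputes all of these from scratch under any
seed.

## Limitations

The MLP is plain R matrix arithmetic: ample for spectra of a few
thousand sets, but not a GPU deep-learning stack, and collections the
size of all of MSigDB (~18k sets) make the spectrum transform the
dominant cost. The cohort-mean background means batch-mode spectra
depend (weakly) on cohort composition; use a fixed reference profile
when that matters. No regularisation, dropout or early stopping is
implemented — with thousands of input sets and small cohorts the network
can overfit, which the holdout-based experiment functions make visible
rather than prevent.
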