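---
title: "Integrating miRNA and mRNA differential expression in paired case-control designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating miRNA and mRNA differential expression in paired case-control designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimico)
```

## The analysis problem

Discordant-pair expression studies — monozygotic twins or sib pairs in which
one member carries a diagnosis and the other does not — control genetic
background to a degree unmatched by unrelated case-control cohorts, at the
price of tiny sample sizes (here, on the order of five pairs). `mimico`
implements an integrative pipeline for such designs: identify differentially
expressed (DE) miRNAs on two-color arrays, identify DE genes from paired mRNA
data, and ask which DE genes are plausibly *regulated* by the DE miRNAs. The
regulatory signature exploited is inverse correlation of group-average
changes: since miRNAs destabilize their target transcripts, an up-regulated
miRNA should have down-regulated conserved targets and vice versa.

The pipeline treats target predictions as an input: a table of
(miRNA, gene) records scored by a conservation probability, P-org — the
estimated probability that the apparent target-site conservation across an
orthologous 3'UTR group is chance. Computing such maps from sequence is out
of scope; records with P-org < 0.05 are considered credible.

## Model and procedure

**Two-color preprocessing.** Each array carries the sample in one fluor
channel and a common pooled reference in the other, each probe printed in
triplicate with a local background estimate per spot. The per-probe net
intensity is `mean(3 replicate intensities) − mean(3 replicate backgrounds)`
per channel. A probe is detectable when both net intensities are strictly
positive (the threshold is configurable); non-detectable probes propagate as
missing log2 ratios rather than being clipped, since a negative net intensity
carries no usable ratio information.

**Ratio-distribution normalization.** Within-array centering follows an
iterative trimmed-mean scheme: compute the mean m and SD s of the currently
included log2 ratios, exclude ratios outside m ± z·s with z the two-sided
normal quantile at the stated confidence (z ≈ 2.5758 at 99.00), and iterate
to a fixed point; the final trimmed mean is subtracted from *all* ratios.
The original image-analysis software that defined this step is no longer
documented, so the trim-to-fixed-point rule above is this package's concrete
definition, parameterized by the same confidence level. It is
shift-invariant and leaves a zero trimmed mean by construction, which is all
downstream steps rely on.

**Quantile normalization.** Across arrays, each column's rank-k value is
replaced by the mean of the k-th order statistics over columns. With missing
values, ranks are computed per column on the available values and the
reference distribution uses per-rank means over the columns that have data at
that rank; ties receive the mean of their tied positions' reference values.
This keeps the step total-order-preserving within every column and idempotent
(checked to 1e-12 in the tests). The alternative — interpolating each
column's quantiles onto a common grid, as `limma::normalizeQuantiles` does
under missingness — differs only in the NA case; on complete matrices the two
agree exactly and the test suite asserts this.

**Ordering.** Within-array centering precedes the across-array steps; the
detectability filter is applied before quantile normalization so that the
common distribution is estimated from detectable probes only.

**Pavlidis template matching (PTM).** Each probe's sample-level profile is
correlated with a per-sample template (case = 1, control = 0) and the Pearson
correlation r converted to a two-sided p-value through
`t = r·√(n−2)/√(1−r²)` on n−2 degrees of freedom. Missing values are handled
pairwise-complete, shrinking n. With a binary template PTM is algebraically
the pooled equal-variance two-sample t-test (the point-biserial identity);
the suite verifies agreement to 1e-10 over 1,000 random instances. The DE
threshold is strict p < 0.05: the method description of the original
analysis says "≤" while its results say "<", and the reported table's maximum
p of 4.86E-02 is consistent with either; strict comparison is the default,
with the comparator exposed (`strict = FALSE`).

**One-class t-test.** Pair-level mRNA log2(case/control) ratios are tested
row-wise against mean 0, two-sided, with *no* multiple-testing correction —
a deliberate choice to keep the putative-target pool large, at the cost of
false positives that the later inverse and magnitude filters must absorb.
Rows with fewer than two observed pairs are skipped with a warning.

**Integration.** After restricting the target map to P-org < 0.05 (strict),
every (DE miRNA, DE gene) record is annotated with both group-average log2
ratios. The inverse filter keeps strictly opposite signs; a gene average of
exactly 0 has no direction and is excluded (the source analysis is silent on
ties; excluding them is the conservative reading). The magnitude cutoff
|gene average| ≥ 0.4 (inclusive) is applied to the gene side only — the
original cutoff is described for the differentially expressed *genes* — with
an option to extend it to miRNAs, off by default. Overlap fractions are
reported over *distinct genes*, not (miRNA, gene) records, matching the
"of these genes" phrasing of the figures they mirror; exact fractions are
retained and integer percentages used for display.

**Class-separation diagnostics.** UPGMA (average-linkage) clustering on
Euclidean distance over samples, with pairwise-complete distances rescaled to
the full dimension and lexicographic column ordering for deterministic tie
breaks; 2-cluster K-means (10 seeded restarts, best within-cluster sum of
squares); column-centered PCA; and leave-one-out cross-validation of a linear
maximum-margin classifier (SVM, cost fixed at 1, no internal rescaling). The
original study named neither kernel nor validation scheme for its perfect
class prediction, so the package's claim is calibrated on synthetic data
only: under strongly planted effects the surrogate reproduces 100% accuracy,
which says nothing about the original arrays. Probe selection happens once,
before LOOCV, mirroring the original workflow; this optimistically biases
accuracy under weak signals (selection sees the held-out sample), and a
selection-inside-CV variant is the obvious extension for real analyses.

**Enrichment.** One-sided Fisher exact over-representation (hypergeometric
upper tail) of the final gene list against user-supplied GMT collections.
The universe defaults to the genes on the platform after presence filtering —
the population actually tested — not the genome. No correction is applied by
default, mirroring the uncorrected P < 0.05 convention of the proprietary
pathway tools this step replaces transparently; Benjamini-Hochberg is
available via `adjust = "BH"`. Proprietary knowledge-base p-values are not
reproducible and are not attempted.

## The synthetic-data generator

`simulateStudy()` emulates the structure the pipeline assumes:

* a paired design (default 5 case-control pairs);
* per-sample two-color spot tables with triplicate spots: log-normal
  reference intensities (median 1,000, sdlog 1 — only ratios matter
  downstream, so the intensity scale is a free choice), sample channel =
  reference × 2^(true ratio + noise), Gaussian replicate spread
  (`triplicateCv`, default 0.1) and exponential additive backgrounds
  (mean 100) recorded per spot;
* planted miRNA effects: 43 of 1,237 probes by default, magnitudes drawn
  from N(1.2, 0.15) truncated to ±3 SD — matching the magnitude range of the
  published 43-miRNA table (1.08–1.54, 20 down / 23 up) — signs half down by
  default and configurable;
* a target map of 60–120 targets per miRNA at desk scale
  (`paperScaleParams()` gives the full 600–1,200 range), with a configurable
  fraction of records below P-org 0.05 (default 0.5);
* responding targets: a `respondFraction` (default 0.2) of each planted
  miRNA's conserved targets, each responding gene assigned to one miRNA
  only, with gene effect `−0.25 ×` the miRNA effect — the 0.25 attenuation
  reflects the published example pairs, where gene-average magnitudes are
  roughly a quarter of the miRNA averages (e.g. 1.186 vs −0.298);
* a gene × pair mRNA matrix with per-cell Gaussian noise (SD 0.3) and 10%
  missing cells, uniform at random (the missingness pattern of real
  concordance tables is structured and unexplained; uniform is a neutral
  stand-in).

Every generator seeds the RNG from `params@seed` plus a fixed per-generator
offset, so one parameter object pins the whole study down exactly; the suite
asserts byte-identical regeneration.

What the generator does *not* emulate: sequence-level miRNA:UTR binding,
scanner artifacts, spatial or print-tip effects, dye bias, correlated
missingness, and family structure beyond pairing. Passing tests on this
generator therefore demonstrate the pipeline's statistical behaviour under
its stated model, not fidelity to any particular real dataset — in
particular, dataset-dependent published figures (the 1,237 detectable
probes, the identity of the 43 miRNAs, the 94-gene stringent list) require
the raw arrays and the original target-prediction release and are not
reproduction targets.

## Numerical choices and degenerate inputs

* Trimmed centering: all-identical included values (s = 0) subtract the
  common value and stop; a trim that would exclude everything falls back to
  the untrimmed mean.
* PTM: r is clamped to [−1, 1] before the t transform (|r| = 1 gives p = 0);
  constant rows are flagged with r undefined and p = 1; rows with fewer than
  3 usable values are flagged and given p = NA.
* One-class t: zero-variance rows give t = 0, p = 1 at mean 0 and p = 0
  otherwise.
* K-means with k equal to the sample count returns the trivial partition
  directly.
* Percentages display as integers (round-half-even, R's `round`); ratios
  display at 3 decimals; machine-precision values are always retained
  alongside.

## Problem sizes in the test suite

The packaged checks run at desk scale: 60–300 probe/gene simulations for
unit tests, the full 1,237-probe × 5-pair profile for the class-prediction
surrogate, 1,000 random instances for the PTM/t-test identity, an exhaustive
sweep of all hypergeometric margins with universes up to 25 against an exact
binomial-coefficient oracle, 20 seeds for the planted-recovery power check
(observed power well above the 80% bound at effect 1.2, noise 0.5, 5 pairs)
and 10,000 null probes for type-I control. These sizes were chosen so the
whole suite completes in well under a minute while keeping every binomial
or CLT tolerance at 3 standard errors.

## Known limitations

* The ratio-distribution normalization is a defined stand-in for an
  undocumented legacy procedure; on data normalized by the original software
  the centering may differ by a constant per array, which cancels in
  case-minus-control contrasts.
* With five pairs, the one-class t-test at uncorrected p < 0.05 admits many
  false-positive genes by design; the integration filters are the intended
  guard, and enrichment results should be read accordingly.
* Inverse correlation of group averages is a weak causal signature: it
  cannot distinguish direct targeting from co-regulation, and miRNA-mediated
  translational repression without transcript decay is invisible to it.
* The LOOCV-after-selection scheme mirrors the original workflow and is
  optimistic; use it as a separation diagnostic, not an error estimate.
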