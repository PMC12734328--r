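---
title: "Methods: the MAPK stress-transcriptomics pipeline"
author: "mapkstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the MAPK stress-transcriptomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkstress)
```

## The study design this package models

Three mitogen-activated protein kinases dominate stress signalling in the
entomopathogenic fungus *Beauveria bassiana*: Hog1 (osmotic stress), Slt2
(heat and cell-wall stress) and Mpk1 (oxidative stress). The experimental
design profiled by this package compares the wild type (WT) with the three
deletion mutants under four stress agents — 1 M sorbitol (osmotic), 16 µM
menadione (oxidative), 25 µg/mL Congo red (cell wall) and 32 °C heat — at
two exposure times, 0.5 h (acute) and 12 h (sustained). WT is sequenced
under all four stresses plus an unstressed time-0 baseline; each mutant is
sequenced only under its sensitive stress plus its own baseline. That
yields 18 libraries (`default_design()`), each the pool of three replicate
cultures mixed evenly before RNA extraction, so within-condition biological
variance is not observable in the data — a central constraint on every
downstream method choice.

## Expression preprocessing

Counts are filtered by zero pattern: a gene is kept when it has a zero
count in at most `max_zero_samples` libraries (default 12 of 18). All
later steps use the post-filter column sums as library sizes.

* **FPKM**: `count * 1e9 / (length_bp * library_size)`. Gene lengths enter
  only here; the simulator deliberately generates length-independent
  counts so the FPKM arithmetic is testable on its own.
* **log2 + quantile**: `log2(FPKM + 1)` followed by quantile normalization
  to the across-column mean of order statistics. The +1 pseudocount is
  applied at the log step, not inside FPKM. Ties: the default policy
  assigns tied values adjacent reference quantiles in stable row order,
  which keeps the sorted value multiset of every column *exactly*
  identical — the invariant the rest of the pipeline relies on. An
  alternative policy (`ties = "mean"`), in which a tie group shares the
  mean of its reference quantiles, is provided; it is equally
  deterministic but preserves the multiset identity only up to tie groups,
  which is why it is not the default.
* **logCLR**: per gene across samples, `p_j = (c_j + 1) / sum(c_j + 1)`,
  `ln p_j - mean(ln p)`. Natural log for the compositional transform, log2
  for fold changes. Because the across-sample profile of raw counts still
  carries sequencing depth, the co-expression compendium uses
  `logclr(x, tmm_scale = TRUE)`: counts are first divided by their
  TMM-scaled effective library size, then transformed. The order — TMM on
  counts, then logCLR — is recorded in the output attribute, since TMM is
  defined on counts, not on transformed values.
* **TMM**: the trimmed mean of M-values procedure (reference column by the
  75th-percentile rule; two-sided trims of 0.30 on M and 0.05 on A;
  precision-weighted mean; factors normalized to geometric mean 1). The
  implementation is in-package and is cross-checked in the test suite
  against both a literal step-by-step recomputation and
  `edgeR::calcNormFactors`.

## The mutant-responsiveness classifier

Per-strain fold changes are
`log2FC = log2((FPKM_stress + 1) / (FPKM_baseline + 1))` against the same
strain's unstressed time-0 library. Genes with `|log2FC| >= 2` are
differentially expressed; genes with `|log2FC| <= 0.5` are silent; both
boundaries inclusive.

The central screening rule labels a gene per mutant contrast:

* `up_in_mutant` — the WT responds downward (`fc_wt <= -2`) while the
  mutant stays silent (`fc_mut >= -0.5`): the gene is *relatively*
  upregulated in the mutant because the mutant fails to mount the WT's
  down-response.
* `down_in_mutant` — the mirror image (`fc_wt >= 2`, `fc_mut <= 0.5`).

Note the direction semantics: the label describes the mutant relative to
the stressed WT, not the mutant's own response. The silent bound is
one-sided by default (`silent_mode = "one_sided_as_printed"`), exactly as
the two screening inequalities are written; a `two_sided` mode
(`|fc_mut| <= 0.5`) is provided because parts of the narrative describe
silence as a symmetric band. The mode is recorded in each DEG table's
attributes, and the two modes differ only for genes whose mutant response
is large *in the same direction* as the screen, so published counts are
insensitive to the choice in the regimes that matter. With no replicates
in the pooled design there is no statistical test here by construction —
the classifier is a deterministic threshold rule, which is also why it can
be validated exactly against planted truth.

Set algebra on the resulting labels (`overlap_degs` for time-point
overlaps, `crosstalk_degs` for the three-mutant intersection,
`deg_summary` for count/percentage accounting) reproduces the arithmetic
of the study's reported counts and is exercised as such in the acceptance
suite.

## Co-expression

Two routes, as in the study:

* **k-means compendium** on TMM-scaled logCLR values: squared-Euclidean
  k-means over gene profiles, k-means++ seeding from a given seed feeding
  Lloyd iterations, 10 restarts, best inertia wins — deterministic for a
  fixed seed.
* **Weighted network**: Pearson correlation across the 18 samples,
  unsigned soft-thresholded adjacency `|r|^beta` (signed mode available),
  topological overlap
  `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
  average-linkage clustering of `1 - TOM`, a *static* cut at height 0.99,
  minimum module size 30, and iterative merging of modules whose
  eigengenes correlate above 0.75. The static cut plus merge is a
  deliberate simplification of dynamic tree-cut algorithms: it is fully
  specified, order-independent and testable, at the cost of some
  sensitivity to the cut height on marginal module structure. Surviving
  modules are named by the conventional color sequence in decreasing size
  order; unassigned genes are grey.

The unsigned network is the default because the module–trait view needs
both strong positive and strong negative correlations, which unsigned
module detection combined with signed trait correlation reproduces.

The soft threshold is the smallest power in 1..20 whose scale-free
topology fit reaches R² = 0.8 (linear fit of `log10 p(k)` versus
`log10 k` over 10 connectivity bins, a positive slope counting against the
fit); if none qualifies the best-fitting power is returned with a warning.
With only 18 samples the correlation noise floor is about 0.24, so
connectivity distributions are genuinely scale-free only when module sizes
are heterogeneous — the test fixtures therefore use graded block sizes
when they exercise power selection.

A module **eigengene** is the unit-norm first principal component of the
module's gene-standardized expression, sign-oriented to correlate
positively with the module's mean standardized profile. Module–trait
association correlates eigengenes with binary sample-trait indicators (one
per strain, stress level including non-stress, and time point); two-sided
p-values come from `t = r sqrt(n-2) / sqrt(1-r^2)` with n − 2 = 16 degrees
of freedom. At n = 18 the printed strongest non-stress correlations
(r = 0.78 and −0.73) correspond to p ≈ 1.3e-4 and 4.7e-4; agreement with
reported values is limited by the rounding of r to two digits, so the
acceptance suite checks consistency within a factor of two rather than
equality.

## Over-representation

One-sided hypergeometric upper-tail tests (equivalently Fisher exact,
greater) of a query set against GMT-style annotation maps. The universe is
the analyzed gene space — the genes surviving the zero-count filter — not
the whole genome. Benjamini–Hochberg adjustment is applied across all
terms of the map; both raw p and q are reported because published
enrichment thresholds do not state which was used. Terms with zero overlap
are dropped from the report after adjustment.

## Phenotype statistics

* **RGI** — relative growth inhibition from colony diameters,
  `(Dc - Ds) / (Ds - d) * 100` with plug diameter d = 5 mm, exactly as the
  formula is printed; since the convention elsewhere in the literature
  divides by the control growth `(Dc - d)`, that variant is computed
  behind `formula = "conventional"` and always labelled. The printed RGI
  values cannot adjudicate between the two because the underlying
  diameters are not published.
* **ECAR** — per well, the ordinary least-squares slope of fluorescence
  against time, by default over the 30–100 min window (after the 30-min
  dark equilibration), blank-corrected by the mean blank drift. The
  hexokinase-mediated ECAR is the measurement rate minus the
  2-deoxy-D-glucose control rate (2-DG competitively inhibits
  hexokinases). Signals stay in relative fluorescence units; no RFU-to-mpH
  calibration is attempted because the kit constants are not published.

## The simulator and what passing tests mean

`simulate_counts()` draws library counts as negative binomial around
`mu = library_size * baseline_share * 2^(planted effect + loading x latent factor)`.
Key choices:

* **Pooling**: `nb_dispersion` (default 0.05) is the *per-culture*
  biological dispersion; each library pools `n_pool = 3` cultures mixed
  evenly, and because the average of three Gamma(1/φ, φ) mixing factors is
  Gamma(3/φ, φ/3), pooled counts are exactly negative binomial with
  dispersion φ/3. This mirrors the study's pooled libraries and is what
  makes fold-change-threshold classification reliable: without pooling the
  one-sided silent band at ±0.5 would be crossed by chance about 14% of
  the time at φ = 0.05, versus about 3% with it.
* **Planted response**: 25 genes per stress × time combination (200
  total), WT effect ±3 log2 units, mutant effect exactly zero. Planted
  genes (responsive and block) are drawn from the expressed part of the
  abundance distribution (z ≥ −1.5): under the pseudocounted fold-change
  formula a gene below about 6 FPKM can never register a down-response of
  magnitude 3, so planting truth there would be uninformative censoring
  rather than a classifier challenge. Congo-red sets carry WT-response
  truth only, since no mutant is assayed under Congo red.
* **Co-expression blocks**: per-sample latent factors shared by block
  members, scaled by per-gene loadings drawn N(1, sd). The positive
  loading mean is required for k-means recoverability (zero-mean loadings
  split a block into anticorrelated halves that only unsigned networks
  reunite); factors are orthogonalized across blocks because independent
  length-18 factor vectors would correlate by chance at the ±0.24 level,
  blurring planted separations.
* **Scale**: gene lengths uniform on 500–4000 bp, library sizes uniform on
  2–3 million reads for the default 2000-gene genome (depth per gene
  comparable to 20 million reads over a ~9000-gene genome).

The simulator reproduces the count scale, the pooled design, planted
differential signal and correlation-block structure. It does **not**
emulate batch effects, length-coupled biases, on/off bimodality, or
isoform-level variation — so passing recovery tests demonstrates
correctness of the algorithms under the stated noise model, not robustness
to every artefact of real libraries.

Problem sizes were chosen to keep the suite fast while leaving the
statistics informative: classifier recovery runs at 2000 genes × 18
libraries (precision and recall over 150 planted gene-contrast pairs;
expected recall ≈ 0.97 under the noise analysis above), module recovery at
3 blocks of 100 genes inside a 1500-gene background, hypergeometric oracle
checks exhaustively cover every instance with a universe of at most 60
genes, and the null-enrichment calibration uses 2000 replicate random
queries.

## Numerical and degenerate-input conventions

* Quantile normalization of a single column is the identity (with a
  warning); zero-variance samples yield missing (not zero) correlations;
  zero-variance genes are an error in network construction, named in the
  message.
* TOM diagonals are set to 1; entries are provably in [0, 1].
* `p = 1` at r = 0 and p underflowing to 0 at |r| = 1 are both returned
  as-is.
* RGI with `Ds <= d` (stressed colony no larger than the plug) is an
  error, not a value; percent differences against a nonpositive reference
  rate are `NA`.
* All generators take explicit integer seeds and are bit-reproducible for
  a fixed configuration.

## Known limitations

* The static tree cut is less adaptive than dynamic hybrid cutting on
  nested module structure; the cut height and merge threshold are exposed
  in `network_params()`.
* With 18 samples, module–trait p-values below ~1e-5 are extrapolations of
  the t-model rather than resolvable quantities.
* The one-sided versus two-sided silent-band ambiguity is inherent to the
  screening rule as printed; both modes are implemented and recorded
  rather than resolved.
* Replicated (non-pooled) designs are outside the default configuration;
  the simulator's per-culture dispersion parameter is the hook for
  studying them.
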