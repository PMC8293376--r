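---
title: "Fiber-type proteomics with fibertyper: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber-type proteomics with fibertyper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibertyper)
```

This vignette is the package's account of the science it implements: the
models and procedures, the parameters that matter, what the synthetic
generator does and does not emulate, and the design decisions taken where
the methodology left genuine freedom.

## The analysis problem

Skeletal muscle fibers come in four canonical types — slow type I and fast
types IIa, IIx, IIb — each defined by its dominant myosin heavy chain
(MYH) isoform (MYH7, MYH2, MYH1, MYH4). Fiber-type-resolved proteomics
quantifies peptides in pools of isolated fibers and asks three questions:

1. How much of each protein does each fiber type carry, in absolute terms?
2. Which protein programs (glycolysis, respiratory chain, sarcomere, ...)
   distinguish the types?
3. Can a minimal peptide panel re-classify fibers without antibodies?

`fibertyper` answers them with, respectively, the iBAQ/aLFQ quantification
chain, the filter–impute–cluster–annotate profiling chain, and FiPSPi, a
random-forest recursive-feature-elimination panel selector.

## Absolute quantification

**Normalization.** Systematic, intensity-dependent differences between
samples are removed by cyclic LOESS on the log2 scale: each sample's
deviation M from the reference profile (the per-peptide row mean across
samples) is smoothed against that reference by `lowess` and subtracted,
cycling over samples for `iterations` rounds. Defaults are span 0.7 and 3
iterations — a standard, deterministic fast-cyclic variant; the routine's
scale (log2) and span are explicit configuration, since naming the method
does not fix them. Missing cells take no part in the fits and are returned
untouched; a sample sharing fewer than 10 observed peptides with the
reference is refused rather than extrapolated.

**iBAQ.** For protein $p$ in sample $s$,
$\mathrm{iBAQ}(p,s) = \sum_{\text{peptides of } p} x(i,s) \,/\, N_p$,
where $N_p$ counts the protein's fully tryptic peptides of observable
length. The digestion rule is: cleave C-terminal of K or R, not before P,
zero missed cleavages, length 6–30 (configurable). Missing peptide cells
are excluded from the sum rather than zero-filled — zero-filling would
deflate iBAQ for proteins near the detection limit. When no FASTA is
available, $N_p$ falls back to the number of distinct peptides observed
for $p$ anywhere in the data set; this is logged as an approximation
because it biases absolute (not relative, within-protein) comparisons.

**Per-sample aLFQ scaling.** Relative iBAQ values become absolute amounts
by proportional allocation of the known loaded mass $T$ (default 200 ng):
$q(p,s) = \mathrm{iBAQ}(p,s) / \sum_q \mathrm{iBAQ}(q,s) \times T$,
computed separately per sample so each sample's quantities sum exactly to
$T$. A `per_sample = FALSE` flag restores the unmodified global scaling
(one grand-total denominator) for comparison. Percentage values divide by
the per-sample total again, so they sum to 100 and are invariant to any
per-sample rescaling. These two conservation identities are structural and
are what `scripts/acceptance.R` recomputes.

## Profiling

**MYH calling.** Summing proteotypic-peptide intensities per isoform
within each labelled fiber-type group and taking the argmax reproduces the
gold-standard assignment. Only proteotypic peptides contribute: shared
peptides would leak intensity between isoforms. Ties report all maximizing
types rather than picking one, because hybrid fibers genuinely co-express
isoforms; a call is a summary, not a forced decision. The packaged worked
example (`myh_example()`) exercises this on realistic summed intensities.

**Filtering and imputation.** Rows quantified in at least 50 % of samples
are kept. Remaining missing values, which in MS data are predominantly
left-censored (below the detection limit), are drawn per sample column
from $N(\mu_s - 1.8\,\sigma_s,\ (0.3\,\sigma_s)^2)$ — a narrowed normal
downshifted below the observed distribution. Per-column moments are the
default because detection limits are sample-specific; a whole-matrix mode
exists by flag. Observed cells are never touched, and a fixed seed makes
the imputation reproducible bit for bit.

**Clustering.** The chain is: fiber-type group medians per protein
(medians resist the outliers typical of small fiber pools), row Z-scoring
(so clustering sees profile shape, not absolute level), k-means
pre-clustering with k = 300 capped at the row count (≤ 10 iterations,
deterministic k-means++ seeding — the initialization had to be chosen, and
k-means++ under a supplied seed is reproducible and scale-free), then
Euclidean average-linkage hierarchical clustering of the pre-cluster
centroids. The tree is cut into `n_final = 4` clusters by default; the cut
count is explicit configuration, since reducing 300 pre-clusters to a
handful of profiles admits many conventions. Every protein lands in
exactly one cluster; `annotate_percentages()` then tabulates a
user-supplied protein → category map per cluster as count / cluster size
(reported to 2 decimals). Note the table computes that ratio exactly; it
is the caller's responsibility that categories are single-valued per
protein (unmapped proteins pool into "Other").

**PCA.** `pca_loadings()` returns sample scores and per-protein loadings
of the first two components, with loadings ranked by absolute magnitude so
the strongest separators can be read off. It can be run on samples (n =
56 scale) or on group summaries; the choice is the caller's.

## FiPSPi panel selection

**Elimination.** Starting from all peptides, each round (i) estimates the
current panel's accuracy with a random-forest classifier under repeated
stratified k-fold cross-validation, (ii) computes permutation importances
from a forest fit on the full training data, and (iii) removes the
`ceiling(0.2 × current)` least-important peptides (at least one, never
crossing `min_panel`). The geometry (drop 20 % per round) keeps the
number of rounds logarithmic in the peptide count, which is what makes
~1,000+-peptide inputs desk-scale.

**Selection.** The selected panel is the smallest in the trace whose
accuracy is within 0.5 percentage points of the trace maximum — the
parsimony rule that turns a plateauing trace into a minimal panel; ties
prefer the smaller panel, then lexicographic order. Accuracy defaults:
5 folds × 2 repeats during elimination (a per-round ranking signal),
5 × 10 for the final panel estimate. Cross-validation was chosen over
out-of-bag error as the default estimator because it matches "held-out
accuracy" as usually reported and is classifier-agnostic; an OOB reading
is available from the fitted forest. Forest defaults: 500 trees, √p
features per split, no depth limit, seeded and single-threaded so results
are reproducible and invariant to sample/peptide ordering (inputs are
canonicalized by name before fitting).

**Decision rule.** The selected panel (designed for the two-peptide case)
is distilled into a CART-style tree: greedy Gini splits with each
threshold at the midpoint between the two class-boundary-adjacent training
values. On separable training data all terminal nodes are pure; degenerate
inputs (identical samples with different labels) yield a reported impure
leaf, not an error. The tree is the human-readable, instrument-portable
form of the panel.

**Confirmation.** `confirm_panel()` matches panel peptides by sequence in
an external labelled data set, excludes classes with fewer than
`min_class_n = 4` samples (below that, per-class accuracy is
statistically meaningless — the default encodes the smallest class size
worth evaluating), Z-scores each panel peptide within each data set to
absorb platform-level location/scale differences (isolation technique and
MS method differ between laboratories; Z-scoring is an explicit,
configurable harmonization, not a claim about any particular study's
procedure), and reports overall and per-class accuracy.

## The synthetic generator

`simulate_fibers()` emulates the statistical structure the analysis
assumes, at the design scale of a four-type, 14-samples-per-type (56
fiber) experiment:

* ~260 proteins with 2–8 peptides each (~1,300 peptides, of the order of
  1,000 quantified proteins in real fiber pools), baseline log2 abundance
  uniform on [18, 30], peptide-level ionization offsets, within-type
  noise sd 0.4 log2 — log2-normal intensities exported on the linear
  scale, matching the log-normal behaviour of MS intensities.
* Four MYH-like proteins with coarse cross-contamination profiles (the
  type-I isoform also present at ~20 % of peak in IIa and near-zero in
  IIb; the IIx isoform leaking into all fast types), fixed rather than
  fitted: downstream code needs the qualitative dominance structure, not
  a calibrated mixture.
* Five slow and five fast marker proteins with monotone log2 gradients
  along the physiological order I → IIa → IIx → IIb (±1.5 log2 across the
  range).
* Left-censored missingness: cell deleted with probability
  $\Phi(c \cdot (\theta - x))$ on log2 intensity $x$, censoring strength
  $c = 1$ per log2 unit, threshold $\theta$ solved so the expected
  missing fraction hits the 20 % target.
* Optionally a planted two-peptide panel at separation 4 log2 units:
  peptide `TINEVENQVLTR` takes three levels across IIa/IIx/IIb but cannot
  split I from IIa; peptide `IAEQELLDASER` splits I from everything else.
  Jointly, and only jointly, the pair resolves all four types — the
  structure a minimal real panel exhibits.

Within-type biological variance and peptides-per-protein counts are
realistic stand-ins, not estimates from any data set. The generator does
**not** simulate chromatographic drift, charge states, fragment-level DIA
signals, shared-peptide protein inference, correlated co-regulation among
background proteins, or batch effects. Tests passing on this generator
therefore demonstrate the pipeline's correctness and its behaviour under
the assumed structure (log-normal signal, left censoring, class-balanced
design) — they do not certify performance on real instrument data, where
harder missingness, correlation and label noise apply.

## Numerical choices and degenerate inputs

* Zeros entering log2 normalization are treated as missing, never −∞.
* iBAQ for a protein with no observed peptide in a sample is missing, not
  zero; aLFQ denominators use observed proteins only.
* An all-missing sample is an error naming the sample, as is a sample
  with fewer than 2 observed values at imputation, and a constant matrix
  in PCA or Z-scoring.
* k-means is capped at the row count, in which case pre-clustering is the
  identity and the method reduces to plain average-linkage clustering.
* RFE canonicalizes row/column order by name, so accuracy estimates are
  invariant to input ordering under a fixed seed; stratified folds refuse
  classes smaller than the fold count instead of silently unstratifying.
* Decision-tree splits that cannot reduce impurity (identical inputs,
  conflicting labels) terminate in an impure leaf that the report marks
  as such.

## Problem sizes used by the checks

The packaged tests run the generator at its defaults (56 samples, ~1,300
peptides) for the quantification and profiling chains; panel-recovery
checks use the planted pair among the generator's 250+ background (noise)
peptides over 20 seeds, with 5 × 2 cross-validation inside the
elimination and 5 × 10 for the final panel estimate; the imputation
moment check draws 10⁵ imputed cells. These are the package's chosen
verification scales; all complete on a laptop-class single core in a few
minutes.

## Known limitations

* The theoretical-count fallback (observed distinct peptides) compresses
  absolute differences between well- and poorly-digested proteins;
  supply FASTA-derived counts for genuinely absolute values.
* Permutation importance is diluted among strongly correlated peptides;
  on data with many redundant markers RFE legitimately selects any of
  several equivalent panels, so exact panel identity is only meaningful
  when the alternatives are uninformative.
* The decision tree is built for 1–3-peptide panels by design; larger
  panels should be classified by the forest (`predict(fit,
  method = "forest")`).
* `confirm_panel()`'s per-data-set Z-scoring assumes the external class
  mixture is not wildly skewed; with a single dominant class,
  standardization itself shifts decision boundaries.
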