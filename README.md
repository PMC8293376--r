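# fibertyper

Skeletal muscle is a mosaic of fiber types — slow oxidative type I and fast
type IIa, IIx and IIb fibers, each defined by its dominant myosin heavy
chain (MYH) isoform (MYH7, MYH2, MYH1 and MYH4 respectively). Proteomic
profiling of isolated fibers (e.g. laser-microdissected, DIA-quantified
single fiber pools) yields peptide-level intensity tables from which fiber
types can be characterized and, ultimately, re-classified from a handful of
discriminative peptides.

`fibertyper` implements that analysis end to end for peptide × sample
intensity data:

* **Absolute quantification** — cyclic LOESS normalization of log2 peptide
  intensities; iBAQ per protein, `iBAQ_p = Σ(peptide intensities of p) /
  N_p` with `N_p` the count of fully tryptic peptides of observable length
  (6–30 residues, cleavage after K/R except before P); per-sample aLFQ
  scaling `q(p,s) = iBAQ(p,s) / Σ_q iBAQ(q,s) × T` with `T = 200 ng` so
  every sample carries the loaded protein mass; and percentage values
  summing to 100 per sample.
* **Fiber-type profiling** — MYH isoform calling from summed proteotypic
  peptide intensities; slow/fast sarcomeric marker tables; the
  filter (≥ 50 % valid values) → downshifted-normal imputation
  (`N(μ_s − 1.8 σ_s, (0.3 σ_s)²)` per sample) → fiber-type group medians →
  row Z-score → k-means pre-clustering (300 centers, ≤ 10 iterations) →
  Euclidean average-linkage hierarchical clustering chain; PCA with ranked
  loadings; cluster × annotation-category percentage tables.
* **FiPSPi panel selection** — random-forest recursive feature elimination
  over peptides: each round estimates the current panel's accuracy by
  repeated stratified cross-validation and discards the 20 % least
  important peptides; the smallest panel within 0.5 accuracy points of the
  trace maximum is selected, scored, and distilled into a threshold
  decision tree (CART/Gini, midpoint thresholds). A confirmation routine
  applies the panel to an independent labelled data set after per-data-set
  standardization, excluding classes with fewer than 4 samples.
* **Synthetic data** — a generator that emulates the statistical structure
  of a 4 × 14-sample fiber-type experiment (MYH isoform dominance with
  realistic cross-contamination, monotone slow/fast marker gradients,
  log-normal intensities, left-censored missingness, optionally a planted
  two-peptide panel), so the whole pipeline is testable without any
  download.

## Worked example

Simulate a 56-fiber experiment, quantify it absolutely, and call fiber
types from the MYH proteotypic peptides:

```r
library(fibertyper)

sim <- simulate_fibers(sim_config(seed = 1, plant_panel = TRUE))
sim$matrix
#> peptide_matrix: 1316 peptides x 56 samples
#>   proteins: 266; proteotypic peptides: 1196
#>   missing cells: 20.0%
#>   fiber types: I (n=14), IIa (n=14), IIb (n=14), IIx (n=14)

quant <- quantify_proteins(sim$matrix, total_ng = 200)
range(colSums(quant$quantity_ng, na.rm = TRUE))
#> [1] 200 200        # every sample carries exactly the loaded 200 ng

ex <- myh_example()   # packaged worked example: summed proteotypic sums
myh_fiber_call(ex$matrix, ex$isoform_map)
#> MYH isoform fiber-type call (summed proteotypic peptide intensity)
#>           I    IIa    IIb    IIx
#> MYH1  45.77  65.77  74.48 353.09
#> MYH2 312.83 747.39  29.01  51.04
#> MYH4  12.76  15.17 675.78 148.09
#> MYH7 681.76 138.65   0.12   0.26
#>   MYH1 -> type IIx
#>   MYH2 -> type IIa
#>   MYH4 -> type IIb
#>   MYH7 -> type I
```

Each isoform is maximal in its characteristic fiber type; the summed
intensities also show the expected cross-contamination (MYH7 present in
type IIa, MYH4 nearly exclusive to IIb).

Select a discriminative peptide panel from the planted pair hidden among
1252 uninformative background peptides:

```r
cls   <- sim$truth$true_protein_class[sim$matrix$peptide_to_protein]
noise <- names(sim$matrix$peptide_to_protein)[!is.na(cls) & cls == "background"]
ints  <- sim$matrix$intensities[c(noise, sim$truth$planted_panel_peptides), ]
X     <- t(impute_downshift(log2(ints), seed = 1))

fit <- fipspi(X, sim$truth$fiber_type_of_sample, seed = 1)
fit
#> FiPSPi discriminative peptide panel
#> Selected panel (2 peptides): IAEQELLDASER, TINEVENQVLTR
#> Cross-validated accuracy: 100.00%

summary(fit)   # elimination trace (1252 -> 1 peptides) and the rule:
#>   decision rule:
#>     if IAEQELLDASER <= 24.01:
#>       if TINEVENQVLTR <= 24.02:
#>         -> type IIa  [I:0 IIa:14 IIb:0 IIx:0; pure]
#>       else:
#>         if TINEVENQVLTR <= 28.02:
#>           -> type IIx  [I:0 IIa:0 IIb:0 IIx:14; pure]
#>         else:
#>           -> type IIb  [I:0 IIa:0 IIb:14 IIx:0; pure]
#>     else:
#>       -> type I  [I:14 IIa:0 IIb:0 IIx:0; pure]
```

The two-peptide panel separates all four fiber types: the myosin-1-like
peptide splits type I from the rest, the alpha-actinin-3-like peptide
resolves IIa / IIx / IIb — neither suffices alone, jointly they give every
terminal node of the decision tree a single class. `confirm_panel()`
re-applies such a panel to an independent data set (matching peptides by
sequence, standardizing per data set, excluding classes with < 4 samples)
and reports overall and per-class accuracy.

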