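Package: fibertyper
Title: Fiber-Type Proteomics: Absolute Quantification, Profiling and
    Discriminative Peptide Panel Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for skeletal muscle fiber-type proteomics from
    peptide-level intensity tables. Implements cyclic LOESS normalization of
    peptide intensities, iBAQ-based absolute protein quantification with
    per-sample scaling to a fixed total protein amount, fiber-type profiling
    (myosin heavy chain isoform calling from proteotypic peptides, slow/fast
    marker tables, valid-value filtering, downshifted-normal imputation,
    k-means pre-clustered hierarchical clustering, PCA, cluster annotation
    tables), and FiPSPi: random-forest recursive feature elimination that
    selects a minimal discriminative peptide panel, builds a threshold
    decision tree over it, and confirms the panel on independent data sets.
    Includes a synthetic fiber-type data generator emulating the statistical
    structure of laser-microdissected DIA proteomics experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ranger
Suggests:
    testthat (>= 3.0.0),
    limma,
    randomForest,
    rpart,
    Biostrings,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
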