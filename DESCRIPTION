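Package: guidekit
Title: CRISPR Cas9/Cas12a Guide Design, Off-Target Enumeration and
    Efficiency Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of CRISPR Cas9 and Cas12a
    targeting. Enumerates PAM-constrained target sites and
    mismatch-tolerant potential off-targets in arbitrary genomes,
    summarises GUIDE-seq-style off-target read-count tables, quantifies
    editing-outcome mutational landscapes (indel spectra,
    deletion/insertion statistics, SNV positional hotspots), encodes
    guide sequences as positional and global nucleotide/dinucleotide
    features, infers per-guide efficiency from pooled knockout-screen
    read counts with gene-essentiality and chromatin-accessibility
    filters, and fits Random Forest models for guide-efficiency
    regression and SNV-outcome classification with cross-validation,
    out-of-bag error, ROC/AUC and percentile-rank diagnostics. A
    synthetic-data generator with planted ground truth supports testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    randomForest,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
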