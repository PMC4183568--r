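Package: TRFLPbias
Title: Bias Testing for Quantitative TRFLP Analysis of Arbuscular
    Mycorrhizal Fungal Communities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts terminal restriction fragments (TRFs), including
    partial-digest pseudo-TRFs, from fluorescently end-labelled amplicon
    sequences by in silico restriction digestion; constructs artificial
    community templates of known composition (equal-abundance, broken-stick
    and near-equal two-genotype designs) and their theoretical TRFLP
    profiles; simulates observed electropherogram peak tables with
    empirically calibrated measurement biases (TRF drift, peak splitting,
    under-digestion, multiplicative area noise, detection thresholds);
    processes peak tables with standard filtering, binning, noise-exclusion
    and peak-pooling rules; and quantifies predicted-versus-observed
    agreement with covariance PCA, Bray-Curtis and Euclidean distances,
    Mantel permutation tests and recovery of Margalef and Simpson
    diversity indices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Sequencing, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
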