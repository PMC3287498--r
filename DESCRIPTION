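Package: deltaDS
Title: Disorder-Score Changes of Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how single nucleotide variants alter the predicted
    intrinsic disorder tendency of proteins. Maps coding variants onto
    protein sequences, scores per-residue disorder with a pluggable
    predictor (a builtin window-averaged propensity model or external
    per-residue score files), computes the disorder-score difference
    between minor and major alleles (delta DS), summarises the
    sequence-context dependence of delta DS across isoforms and unrelated
    proteins, stratifies variants by minor allele frequency to probe
    purifying selection, intersects high-impact variants with trait answer
    sheets, and generates seeded synthetic exome-like cohorts with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
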