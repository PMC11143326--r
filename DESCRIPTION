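Package: concordTF
Title: Transcription-Factor Prioritization from Concordant Chromatin and
    Expression Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates differential RNA-seq and ATAC-seq results across three
    physiological conditions (fed, fasted, leptin-treated) to prioritize
    candidate transcription factors from cis-regulatory evidence. Differential
    genes and open-chromatin peaks are classified with configurable log2
    fold-change, FDR and CPM thresholds; direction-concordant peaks are
    assigned to genes within a +/-200 kb window of the transcription start
    site; peak sequences are scanned with position weight matrices and tested
    for motif enrichment with an optimal-score-threshold one-tailed Fisher
    exact test against six background sets (AME-style), carried in log space
    so arbitrarily small p-values survive; motifs are then prioritized by a
    >=5-of-6 background consensus rule, representative -log2(p) scores, summed
    condition-pair scores and a four-set exclusivity classification. A
    self-contained negative-binomial simulator with planted motif instances
    generates fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
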