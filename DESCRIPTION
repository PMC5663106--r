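Package: clipxl
Title: Crosslink-Site Calling and Target Integration for Plant iCLIP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies in vivo targets of RNA-binding proteins from iCLIP
    (individual-nucleotide-resolution crosslinking and immunoprecipitation)
    sequencing data. Implements truncation-site extraction with UMI-based PCR
    deduplication, per-region crosslink-site calling via a permutation false
    discovery rate on a window-height statistic with rerun-stability filtering,
    replicate consensus and control-library subtraction, pentamer Z-score motif
    enrichment around binding sites, and downstream target integration with
    RIP-seq enrichment, differential-expression and percent-spliced-in (PSI)
    splicing analyses. A deterministic synthetic-data generator with planted
    ground truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    Rsamtools,
    GenomicAlignments,
    jsonlite
Config/testthat/edition: 3
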