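Package: srnapipe
Title: Small RNA Classification, Novel miRNA Discovery and Target Prediction
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for plant small RNA sequencing libraries:
    collapsing raw reads into unique-sequence count tables, partitioning reads
    into annotation categories (rRNA, tRNA, snRNA, snoRNA, siRNA, exon, intron,
    known miRNA), quantifying conserved miRNAs and their star species by exact
    matching, discovering novel miRNAs from genome-mapped read clusters using
    hairpin folding and the minimal folding free energy index (MFEI), predicting
    miRNA targets with positional mismatch rules and a duplex MFE-ratio
    criterion, and scanning foreign genomes for conserved miRNA loci via
    inverted-repeat detection. Secondary-structure and duplex energies are
    computed with the ViennaRNA command-line programs. A synthetic-data module
    generates genomes with planted pre-miRNA hairpins, annotations and read
    libraries with full ground truth so every stage is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: ViennaRNA (RNAfold, RNAduplex on PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
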