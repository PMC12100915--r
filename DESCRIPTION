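Package: cfFrag
Title: Fragmentomic Feature Extraction for Cell-Free DNA Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extraction of fragmentomic features from paired-end sequencing
    of cell-free DNA (cfDNA). Reconstructs individual cfDNA molecules from
    aligned read pairs with quality control and coordinate curation tailored
    to cfDNA (no proper-pair filtering, explicit handling of sequence-through
    read pairs), and derives fragment-length distributions, fragment end
    motifs, mutation-overlap annotations of read pairs against a priori
    variant loci (concordant/single-read/discordant overlap), stratified
    96-context single-base-substitution profiles, simplified binned copy
    number states, and descriptive alignment-file metrics. Includes a
    synthetic paired-end alignment generator with exhaustive ground truth so
    every feature caller can be verified without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ggplot2,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomeInfoDb,
    rlang
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, Coverage, CopyNumberVariation, SNP, QualityControl
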