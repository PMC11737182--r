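Package: ccspolish
Title: Consensus Polishing and Base-Quality Recalibration for PacBio CCS Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Polishes PacBio circular consensus sequencing (CCS/HiFi) reads
    using a partial-order alignment (POA) of each read with its subreads, and
    recalibrates per-base Phred quality scores with a small supervised model.
    Alternative ("parallel") bases supported by the subreads are recovered by
    cutting the topologically ranked POA graph in front of each consensus base
    and tallying the weights of crossing edges; consensus bases outvoted by
    their parallel bases, or substituted or deleted by the heaviest-path POA
    consensus, are corrected. Per-base features (sequence context, original
    quality, parallel-base counts, subread kinetics and signal-to-noise) feed
    a feed-forward calibration network whose output converts to a Phred score.
    Includes a synthetic-molecule simulator with full ground truth, empirical
    quality validation (reliability binning, maximum validated Q), and BAM,
    FASTA, FASTQ and VCF interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'poa.R'
    'graphcut.R'
    'polish.R'
    'mlp.R'
    'qualmodel.R'
    'simdata.R'
    'validate.R'
    'io.R'
    'pipeline.R'
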