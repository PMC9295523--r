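Package: pprscout
Title: Discovery, Classification and RNA Target Prediction for
    Pentatricopeptide Repeat Proteins
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for identifying pentatricopeptide
    repeat (PPR) proteins in transcriptome assemblies and predicting their
    plastid RNA targets. Extracts open reading frames from transcripts,
    resolves per-residue motif hits into tandem PPR arrays, applies
    score-based filters, classifies sequences into the P and PLS subfamilies
    and the PLS/E1/E2/E+/DYW classes, grades DYW deaminase domain completeness
    by position-weight-matrix scanning with exact p-values, selects best
    ortholog hits and infers chloroplast localization, compiles the PPR
    amino-acid code into degenerate nucleotide patterns and searches an
    annotated plastid gene set for candidate binding sites, and quantifies
    relative expression from qRT-PCR Ct tables by the 2^-ddCt method. A
    synthetic-data generator with full ground-truth records makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, SequenceMatching, MotifAnnotation, qPCR
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'orf.R'
    'hits.R'
    'classify.R'
    'pwm.R'
    'ortholog.R'
    'targets.R'
    'qpcr.R'
    'synthetic.R'
    'pipeline.R'
    'pprscout-package.R'
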