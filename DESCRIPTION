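Package: IPNevolve
Title: Multi-Region Exome Evolution Analysis of Pulmonary Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing genomic evolution across the histologic
    spectrum of early lung adenocarcinoma (atypical adenomatous hyperplasia,
    adenocarcinoma in situ, minimally invasive and invasive adenocarcinoma)
    from multi-region exome variant tables. Implements the somatic variant
    filter cascade with FFPE artifact quality control, 96-channel mutational
    signature deconstruction and APOBEC TCW enrichment, coverage-based copy
    number segmentation and a folded-BAF allelic imbalance caller, cancer
    cell fraction estimation with interval-based clonal/subclonal
    classification, multi-region phylogenetics (Hamming distance, neighbor
    joining, Wagner parsimony), the Brock nodule malignancy equation, and
    stage-comparison statistics, together with a fully parameterised
    synthetic multi-region cohort simulator with clone-tree ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'channels.R'
    'clonality.R'
    'cnv.R'
    'filters.R'
    'io.R'
    'phylogeny.R'
    'pipeline.R'
    'signatures.R'
    'simulate.R'
    'stats.R'
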