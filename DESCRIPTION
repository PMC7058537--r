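Package: tadsv
Title: TAD Boundary Disruption Analysis of Cancer Structural Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how somatic structural variants (SVs) disrupt
    topologically associating domains (TADs). Calls TAD boundaries from binned
    Hi-C contact matrices via insulation scores, builds cross-cell-type
    consensus boundaries, classifies SVs as boundary-affecting, measures
    enrichment against boundary-shuffle null models, annotates inter-boundary
    domains by chromatin-state composition (k-means, five classes), relates
    boundary disruption to flanking-gene expression fold changes with
    copy-number and distance filters, and detects TAD fusions in rearranged
    contact maps through distance-decay scaling statistics. A synthetic-data
    module generates every pipeline input with known ground truth so the full
    analysis is exercisable and testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: HiC, StructuralVariation, Epigenetics, GeneExpression, Software
RoxygenNote: 7.3.3
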