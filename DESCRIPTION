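Package: introscan
Title: Simulation-Trained Deep Learning Scans for Interspecific Introgression
Version: 0.1.0
Authors@R: person("introscan", "developers", role = c("aut", "cre"),
    email = "introscan@example.org")
Description: Localizes interspecific introgression in two-population phased
    SNP data with a simulation-trained convolutional classifier. Provides
    coalescent simulation of labelled introgression scenarios under
    two-population demographic models with mass-migration pulses, encoding of
    phased haplotype alignments into binary window tensors, a residual
    convolutional network discriminator implemented natively in R, a
    threshold-based window caller with neighbor relaxation and merging,
    evaluation under sequencing-error models, site and window level variant
    filters, a truth-annotated synthetic cohort generator, and downstream
    genomic-landscape statistics (nucleotide diversity, telomere distance,
    gene overlap, random-window nulls).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    data.table,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
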