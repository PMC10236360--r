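Package: celfeer
Title: Read-Resolution Cell Type Deconvolution of Cell-Free DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the cell type composition of cell-free DNA from
    bisulfite sequencing data at the resolution of individual reads. Each
    read is summarised by its average methylation, discretised to five bins,
    and a categorical/multinomial mixture model is fitted by
    expectation-maximization jointly with reference methylomes, including
    support for cell types absent from the reference. The package also
    provides the beta-value (CpG count) EM baseline and a non-negative
    least squares baseline, hypomethylation-based marker region discovery
    in 500 bp windows, read-level input processing, and the simulation
    designs used to benchmark the models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    data.table,
    pracma,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
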