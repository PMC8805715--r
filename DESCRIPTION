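Package: arcc
Title: Accessible-Region Chromosome Conformation Capture Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processing and statistical analysis of accessible-region
    conformation capture (ARC-C) data: classification of paired-end
    alignments into informative ligation pairs, fixed-width and
    regulatory-element-anchored genome binning, sparse contact matrices
    with Knight-Ruiz balancing and distance-decay normalization,
    visibility-corrected binomial calling of significant interactions,
    aggregated contact analysis over binding sites and chromatin domains
    with matched permutation nulls, differential aggregate analysis
    between genotypes, expression correlation of linked promoters, and a
    seeded simulator that plants loops, domains and compartments for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
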