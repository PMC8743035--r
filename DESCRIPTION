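Package: apespectra
Title: Compartmentalized Mutation Spectrum Analysis for Multi-Species Variant Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ascertaining triplet (and 7-mer) mutation spectra from
    multi-species polymorphism panels and comparing them across genomic
    compartments. Implements parsimony-based ancestral allele polarization
    with a site-filter cascade (multi-genus segregation, recurrent mutation,
    singleton, derived-allele-frequency, N-context, and Hardy-Weinberg
    excess-heterozygosity filters), per-individual and randomized spectrum
    sampling that removes covariance due to shared drift, trinucleotide and
    7-mer content normalization of mutation rates between compartments,
    PCA and non-negative matrix factorization of spectrum matrices,
    compartment log-odds heatmaps with content-corrected variants, a
    multinomial likelihood test of spectrum fit, and a length-preserving
    interval bootstrap for compartment enrichment nulls. A synthetic panel
    generator with known trans- and cis-acting signatures makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    vcfR,
    jsonlite,
    cluster,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
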