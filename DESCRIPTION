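Package: t2tkit
Title: Telomere, Centromere and Inversion Analysis for Complete Genome
    Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for telomere-to-telomere plant
    genome assemblies. Detects terminal telomere repeats and centromeric
    satellite arrays, builds satellite monomer consensus and divergence
    summaries, delineates centromeres and calls centromere repositioning
    between syntenic genomes, detects chromosomal inversions from syntenic
    gene anchors and defines breakpoint flanks, genotypes inversions across
    resequenced populations from read-coverage breadth and inversion-region
    PCA, computes sliding-window nucleotide diversity and Weir-Cockerham
    F_ST, tests repeat-class enrichment at inversion breakpoints by
    length-matched permutation, and summarises alignment-based assembly
    quality (edit-distance error rate, improper-pair rate, N50, coverage
    breadth). A synthetic-data module simulates genomes, populations,
    coverage tracks and alignment summaries with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
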