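Package: ampliSTR
Title: Sequencing-Based Microsatellite Genotyping and Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genotypes microsatellite (short tandem repeat) loci from
    amplicon sequencing reads and analyses the resulting diploid genotypes.
    Reads carrying inline site and colony barcodes are demultiplexed,
    quality-trimmed, collapsed into depth-annotated unique sequences and
    passed through length, depth and prevalence filters; alleles are called
    with a half-maximum-depth rule, multi-allele colonies are resolved by
    depth or at random, and tandem repeats are separated from their flanks so
    genotypes can be encoded by fragment length or by full sequence identity.
    Downstream analyses cover diversity indices (Nei-Chesser estimators,
    Hedrick's G'ST, Jost's D), Weir-Cockerham AMOVA F-statistics with
    permutation tests and Meirmans' standardized F'ST, Monte-Carlo exact
    tests of differentiation, rarefied allelic richness, heterozygosity-excess
    bottleneck tests under IAM and TPM mutation models with a mode-shift
    check, and covariance PCA of individuals and populations. A coalescent
    amplicon-read simulator with known truth makes every stage verifiable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
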