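Package: introscan
Title: Haplotype-Similarity Scans for Recent Introgression from Phased SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects recent introgression between populations from phased,
    imputed SNP genotypes by comparing window-wise haplotype-count similarity
    of a recipient population against a wild-ancestor proxy and a putative
    donor.  The core statistic is the difference of two Pearson chi-square
    values on distinct-haplotype count tables (delta chi-square), with
    empirical p-values from a label-permutation null, control-population
    exclusion of shared-ancestry false positives, and region-level summaries
    (genome fraction introgressed, cross-population sharing, Wald-Wolfowitz
    runs test for genomic clustering, gene-density correlation).  Companion
    analyses include intra-population diversity indices (proportion of
    polymorphic loci, runs of homozygosity, haplotype diversity), an XP-EHH
    cross-population selection scan, the four-taxon D-statistic with block
    jackknife, and identity-by-descent sharing summaries.  A forward
    Wright-Fisher simulator with migration, selection and donor-ancestry
    tract tracking, plus a fast haplotype-mosaic generator, provide synthetic
    data with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
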