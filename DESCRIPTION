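Package: asmqtl
Title: Allele-Specific-Methylation-Aware meQTL Mapping in Pedigreed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps cis-methylation quantitative trait loci (meQTL) from
    bisulfite sequencing read counts using an overdispersed binomial mixed
    model that exploits allele-specific methylation in heterozygotes, with a
    pedigree-derived relatedness random effect. Includes bisulfite-aware
    genotype calling from pileups with a wildcard strategy for C/T ambiguity,
    CpG and SNP quality filters, permutation-based empirical false discovery
    rate control, per-pair variance decomposition, cis-eQTL mapping with a
    linear mixed model on latent-factor-adjusted expression, meQTL-eQTL
    integration, genomic-annotation enrichment tests, and a synthetic-data
    generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
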