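Package: introscan
Title: Selection-Signature and Introgression Scans for Admixed Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting selection signatures and introgression in a
    composite (admixed) population and its two parental populations from phased
    SNP genotypes. Implements a per-site Weir & Cockerham (1984) Fst scan with
    top-quantile outlier calling, a relative identity-by-descent (rIBD)
    introgression statistic computed over fixed genomic bins with z-score
    significance and region linking, gene mapping with configurable flanks,
    hypergeometric gene-set enrichment, and a Balding-Nichols admixture
    simulator with planted introgression tracts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
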