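Package: equidiv
Title: Genomic and Pedigree Diversity Analysis for Horse Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for SNP-array based genetic diversity analysis of
    livestock populations, developed around native horse breeds. Reads and
    writes PLINK text and binary genotype files, applies array quality
    control, computes observed and expected heterozygosity, detects runs
    of homozygosity (ROH) with a sliding-window scan, derives genomic
    inbreeding coefficients (F_ROH) by genome, chromosome and length
    class, calls ROH islands as candidate selection signatures, estimates
    historical effective population size from linkage disequilibrium
    decay, and computes pedigree inbreeding, generation equivalents and
    coancestry-rate effective population size. A gene-dropping and
    Wright-Fisher simulator with recorded identity-by-descent ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
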