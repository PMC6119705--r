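Package: xylink
Title: Sex-Linkage Diagnosis and Sex-Chromosome Diversity from
    Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing nascent XY sex-chromosome systems from
    diploid microsatellite genotypes: detection of male-specific (private)
    and translocation-specific alleles, X/Y haplotype phasing from private
    male alleles, per-chromosome-class gene diversity under the stepwise
    mutation model and its comparison with the neutral 4:3:1
    autosome:X:Y expectation, Weir-Cockerham F-statistics with permutation
    tests, Hardy-Weinberg and linkage-disequilibrium exact tests, Mantel
    tests of isolation by distance, and a forward-time Wright-Fisher
    simulator of sex-linked microsatellite data with
    reciprocal-translocation polymorphism for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
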