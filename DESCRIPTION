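Package: fhapminer
Title: Family-Based Haplotype Association Mining in Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Family-based association testing and fine mapping of disease
    loci from pedigree SNP data under a zero-recombination assumption.
    Haplotype configurations are inferred exactly for loop-free pedigrees
    with complete genotypes by solving a linear system of inheritance
    variables over GF(2); each founder haplotype receives a phenotype score
    accumulating the trait deviations of its carriers; founder haplotypes
    pooled across families are then clustered around each marker with a
    position-weighted similarity measure and clusters are tested for trait
    association with a t-type Q score.  Includes a single-locus
    transmission disequilibrium test (TDT) baseline, a pedigree simulator
    with penetrance-model phenotypes and ascertainment, and a study runner
    for type-I error, power and mapping-precision experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
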