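Package: ctpp
Title: Design, Simulation and Validation of PCR-CTPP SNP Genotyping Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for polymerase chain reaction with confronting two-pair
    primers (PCR-CTPP), a gel-based single-tube SNP genotyping method in
    which two allele-specific primers meet 3'-to-3' on the polymorphic
    base. The package enumerates and ranks candidate four-primer assays
    under the CTPP geometric constraints, scores primers by
    nearest-neighbor (Breslauer) melting temperature, predicts
    genotype-specific electrophoresis band patterns, simulates
    allele-specific amplification on diploid templates, calls genotypes
    from observed band sizes, and provides population-genetic quality
    control: allele frequencies, Hardy-Weinberg equilibrium chi-square
    tests, call rates and inter-platform concordance. Ready-made assays
    for the warfarin pharmacogenetic variants VKORC1 G-1639A (rs9923231)
    and CYP2C9*3 (rs1057910) are bundled, together with a synthetic-data
    generator so that every component can be exercised without external
    downloads. A command-line interface exposes the main operations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
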