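Package: donormix
Title: Donor-Derived Cell-Free DNA Fraction from SNP Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotyping-free estimation of the minor (donor) contribution in a
    two-contributor DNA mixture, as arises when monitoring transplant recipients
    through donor-derived cell-free DNA. Reads biallelic SNP panel definitions
    (BED or VCF), derives quality-filtered per-base read counts from text
    pileups or counts tables, selects autosomal loci homozygous in the major
    (recipient) contributor, and fits a three-component Gaussian mixture with
    fixed 1:2:1 weights and 1:2 mean and standard-deviation constraints to the
    per-locus minor-allele fractions by expectation-maximization. Includes a
    two-contributor read simulator that reproduces a genomic-DNA titration
    experiment (0 to 8 percent donor) for validation, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
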