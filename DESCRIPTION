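Package: dropquant
Title: Allele-Specific Droplet Digital PCR Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of allele-specific droplet digital PCR
    (ddPCR) experiments. Provides a seeded generator of synthetic two-channel
    droplet amplitude data with Poisson template partitioning, amplitude
    thresholding and droplet classification, Poisson-corrected absolute
    concentration estimation with confidence intervals, wild-type/mutant
    fractional abundance with propagated error, transcripts per diploid
    genome, transgene copy-number estimation with allelic partitioning,
    siRNA knockdown quantification, allele-specific expression fractions
    from per-SNP read counts, and a reproducible end-to-end pipeline with
    file-based input/output.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Encoding: UTF-8
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
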