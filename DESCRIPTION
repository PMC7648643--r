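Package: paleokin
Title: Pseudo-Haploid Ancient-DNA Kinship, f-Statistics and Enamel Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale reanalysis of low-coverage ancient-DNA kinship
    and tooth-enamel chemometry. Implements EIGENSTRAT (ASCII) genotype I/O,
    pedigree gene-dropping simulation of pseudo-haploid genotypes with
    missingness, error and contamination, outgroup-f3 and f4 statistics with
    weighted block-jackknife standard errors, pairwise SNP mismatch-rate
    relatedness estimation with degree-of-relatedness classification,
    X/Y read-ratio genetic sexing, and a LA-ICP-MS line-scan reduction stack
    (gas-blank subtraction, limit-of-detection censoring, Ca-normalised
    isotope ratios, one-point calibration, region-of-interest statistics,
    post-neonatal-line enamel layer thickness, crown-formation timing and
    collagen C:N quality control) together with a phantom line-scan generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
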