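Package: polyadapt
Title: Detecting Selection on Polygenic Traits from Allele-Frequency Change
    and Genome-Wide Marker Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a composite test for selection on polygenic traits
    that combines per-marker allele-frequency change between two time points
    with genome-wide estimates of allele-substitution effects, evaluated
    against a linkage-disequilibrium-aware permutation null.  Includes
    ridge-regression BLUP (REML) and BayesC marker-effect estimation,
    effective-marker-number estimation by eigenvalue decomposition (simpleM)
    or LD decay, readers for delimited, VCF and PLINK .raw genotypes, and a
    forward-in-time Wright-Fisher simulator of divergent truncation
    selection used for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
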