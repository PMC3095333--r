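Package: apcevol
Title: Comparative Evolution of the Plant Anaphase-Promoting Complex
Version: 0.1.0
Authors@R: person("APC", "Toolkit", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for studying duplication and divergence of
    anaphase-promoting complex (APC/C) subunits and their activators in plant
    genomes. Provides affine-gap global and local protein alignment with
    EMBOSS-style identity and similarity percentages, detection of 34-residue
    tetratricopeptide repeat (TPR) units with internal-duplication score
    matrices and block calling, Poisson-corrected distances with
    neighbor-joining trees, bootstrap supports and low-support condensation,
    Nei-Gojobori Ka/Ks estimation for coding-sequence pairs, a surrogate-null
    Z-score test for promoter cis-element over-representation, and seeded
    generators of synthetic sequence data with machine-readable truth records
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    Biostrings,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
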