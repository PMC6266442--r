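Package: phagekit
Title: Annotation and Phenotype Analysis Toolkit for Lytic Phage Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for the desk-side characterization of newly isolated
    lytic bacteriophages. Implements Shine-Dalgarno-anchored open reading
    frame calling on phage genomes (six-frame scan, configurable ribosome
    binding site matching, minimum-length and start-codon filters),
    theoretical protein descriptors (average-mass molecular weight and
    Bjellqvist-style isoelectric point), comparative proteomics using the
    smallest-protein percent-identity statistic with shared-protein counts
    at identity cutoffs, host-range spot-test scoring over serial dilution
    ladders, and one-step growth-curve analysis (burst size, latent period,
    ANOVA with Tukey HSD across temperatures). Ships seeded synthetic-data
    generators for phage-like genomes, diverged proteomes, spot-test
    matrices and one-step growth titer series so that every stage of the
    pipeline can be exercised against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
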