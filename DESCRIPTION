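Package: stoichbuffer
Title: Dosage Compensation Analysis for Protein-Complex Stoichiometry Buffering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies protein-level dosage compensation under gene
    copy-number perturbation in budding yeast. Provides densitometry
    fold-change statistics for Western blots (background subtraction,
    loading-control normalization, dilution-series linearity checks,
    cycloheximide-chase half-lives), plasmid copy-number estimation from
    genetic tug-of-war (gTOW) qPCR, screen classification of compensated
    genes with exact one-tailed Mann-Whitney and chi-square statistics, a
    mass-action two-pool heterodimer assembly-degradation model with
    steady-state fold-change predictions under copy-number perturbations,
    a ribosome-profiling stage computing translational-efficiency fold
    changes with A-site offset counting rules, and seeded synthetic-data
    generators so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
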