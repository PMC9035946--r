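Package: immunotox
Title: Agent-Based Immune System Simulation of Chemical Immunotoxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale agent-based simulator of the human immune system
    with a chemical immunotoxicity layer. Lymphocyte specificity is encoded
    as a bit-string shape space with Hamming-distance complementarity;
    cells move by Brownian diffusion on a hexagonal or cubic lattice and
    interact through per-site randomized Bernoulli schedules. Haematopoiesis
    follows a mean-reverting Ornstein-Uhlenbeck process and T cells undergo
    two-stage thymic selection. A mechanism-of-action map applies Hill-type
    suppression of cytokine secretion, B-cell homeostasis, thymic output and
    mast-cell growth as a function of serum chemical concentration (PFOA or
    PFOS), enabling in silico trials on virtual-patient cohorts: paired-seed
    exposed versus unexposed contrasts, quartile analyses, exposure-response
    correlation, fold-change effects, calibration and benchmark-dose search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
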