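Package: forcespec
Title: Single-Molecule Force Spectroscopy Kinetics from AFM Force-Distance Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscopy (AFM) single-molecule
    force spectroscopy of receptor-ligand (e.g. antibody-receptor) bonds on
    living cells. Detects rupture events in force-distance curves, computes
    binding probabilities, fits worm-like-chain elasticity to assign per-event
    loading rates, estimates Bell-Evans dissociation parameters (koff, barrier
    width) by maximum likelihood, reduces two-bond (bivalent) dissociation via
    an uncorrelated Markov model, estimates association kinetics (kon) from
    dwell-time-dependent binding probabilities with an effective-concentration
    model for the tip-tethered ligand, and assembles equilibrium dissociation
    constants into per-condition kinetic summaries. Includes a Monte-Carlo
    force-curve generator with ground-truth labels for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mclust,
    deSolve,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    ggplot2
Config/testthat/edition: 3
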