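Package: soltemper
Title: Simulated Solute Tempering with a Toy Molecular-Dynamics Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expanded-ensemble enhanced-sampling engines for simulated
    tempering (ST) and simulated solute tempering (SST1, SST2), together
    with a pairwise REST2 swap criterion, exponentially spaced temperature
    ladders with an off-minimum reference rung, on-the-fly and averaged
    per-rung weight estimation, and a seeded BAOAB Langevin integrator on
    analytically tractable solute/solvent toy potentials. Includes
    post-processing tools: effective solute temperature, hysteresis
    fold/unfold state classification and transition counting, folded-fraction
    stability curves, four-parameter logistic melting-temperature fits,
    omega-dihedral cis/trans classification, and Kabsch backbone RMSD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
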