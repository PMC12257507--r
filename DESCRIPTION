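Package: npcorona
Title: Protein-Nanoparticle Interaction Geometry, One-Site ITC Fitting, and
    CD Secondary-Structure Deconvolution
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reusable pipeline for the quantitative characterisation of
    protein adsorption onto functionalised nanoparticles. Reads protein
    crystal structures (PDB) under an explicit atom-selection policy,
    builds simplified random-atom nanoparticle models, and computes
    structural observables (unaligned RMSD under Gaussian coordinate
    perturbation, radius of gyration, minimum interatomic distance) with
    replicated, seeded analyses. Forward-models, blank-corrects and fits
    single-site isothermal titration calorimetry (ITC) binding isotherms
    with displacement correction and derives the entropic term. Estimates
    alpha-helix/beta-sheet/random-coil composition from circular dichroism
    (CD) spectra by simplex-constrained least squares against a packaged
    reference basis. Ships seeded synthetic-data generators (geometric
    point clouds, thermograms, CD titration series) for validation and
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
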