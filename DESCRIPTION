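Package: connatlas
Title: Atlas-Based Structural Connectomes and Network-Based Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds fractional-anisotropy structural connectomes by projecting
    scalar diffusion maps in a common stereotactic space onto a probabilistic
    white-matter bundle atlas (population presence and voxel occupancy
    consistency filters, bundle-mean edge weights), and identifies
    clinical-score-associated subnetworks with Network-Based Statistics:
    edge-wise general-linear-model contrast t-tests, suprathreshold connected
    components, and family-wise-error-corrected component p-values from a
    Freedman-Lane permutation null of maximal component size. Includes minimal
    diffusion-tensor machinery (ordinary least-squares tensor fit, FA maps,
    motion/outlier quality-control screening), cohort descriptive statistics,
    BrainNet Viewer export, and a synthetic-data generator (toy atlas, FA
    phantoms with planted subnetwork effects, diffusion-weighted signals from
    known tensors, cohort tables) so the full pipeline is testable without
    patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
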