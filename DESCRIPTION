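Package: mrsforge
Title: Forward Simulation of In Vivo-Like Proton MR Spectroscopy Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, batch-capable forward physics simulator for single-voxel
    proton magnetic resonance spectroscopy (MRS). Builds spectra as linear
    combinations of metabolite basis functions with Voigt lineshapes, simulated
    linear B0 field inhomogeneity over the voxel, bounded-random-walk baseline
    and residual-water nuisance signals, SNR-defined Gaussian noise, zero- and
    first-order phase offsets, eddy-current artifacts, and multi-coil or
    multi-average transient synthesis with sensitivities and drifts. Every
    simulated spectrum is paired with the complete ground-truth parameter
    record needed to re-create it exactly. Datasets export to a structured
    JSON container and to NIfTI-MRS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    RNifti,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
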