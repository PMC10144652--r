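Package: pmmcd
Title: Perturbed Matrix Method Post-Processing of MD Trajectories for
    Electronic Circular Dichroism Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing workflow for computing electronic circular
    dichroism (ECD) and UV absorption spectra of solvated chromophores from
    molecular dynamics trajectories by the Perturbed Matrix Method (PMM).
    Builds a perturbed electronic Hamiltonian per trajectory frame from a
    precomputed unperturbed excited-state basis and the electrostatic
    potential and field of the environment point charges, diagonalizes it,
    and evaluates perturbed transition dipoles and rotational strengths.
    Includes essential-dynamics conformational analysis (mass-weighted
    superposition, covariance eigendecomposition, essential-plane
    free-energy landscapes, basin detection and reference-configuration
    extraction, hydroxymethyl rotamer classification), binned
    Gaussian-broadened spectrum assembly, probability-weighted conformer
    and anomer mixing, and synthetic fixture generators that exercise the
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
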