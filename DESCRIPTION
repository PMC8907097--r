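Package: saltgist
Title: Grid Inhomogeneous Solvation Theory for Salt-Water Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially resolved solvation energy and entropy maps from
    molecular-dynamics-style trajectories of a rigid solute in a salt-water
    mixture, following grid inhomogeneous solvation theory (GIST) extended to
    multi-species solvents. Implements voxelized solute-solvent and
    solvent-solvent energies with per-species bulk referencing by ordinary
    least squares, first-order nearest-neighbor translational, orientational
    and six-dimensional entropies for water and monoatomic ions, second-order
    (three-body) entropies from one-dimensional conditional radial
    distribution functions with and without the Kirkwood superposition
    approximation, reference-density recomputation from the bulk-like region,
    and Setschenow (salting-out) constants fitted across a salt-concentration
    series. Includes deterministic synthetic-trajectory generators (ideal gas,
    Metropolis Monte Carlo fluid, Gaussian clouds) that exercise every stage
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
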