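Package: voamd
Title: Solvent-Aware Vibrational Optical Activity Band-Shapes from
    Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns molecular-dynamics trajectories of flexible,
    hydrogen-bonding solutes into conformer- and solvent-aware
    vibrational optical activity band-shapes.  Computes ring-puckering
    pseudorotation and Cremer-Pople phases and torsional collective
    variables from multi-model XYZ or PDB trajectories, detects
    geometric hydrogen bonds and monomer/dimer association states,
    clusters frames with a periodic-aware k-medoids algorithm and
    exports medoid structures with solvation shells, and assembles
    IR/VCD/Raman/ROA spectra from per-structure stick spectra by
    Lorentzian broadening, Boltzmann and cluster-population weighting,
    and monomer-dimer equilibrium mixing.  Includes synthetic fixture
    generators with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
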