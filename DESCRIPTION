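Package: gamdfrag
Title: Multicopy Fragment Simulation Preparation and GaMD Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fragment-based binding-site mapping with multicopy
    molecular dynamics under a Gaussian accelerated (GaMD) boost. Builds
    multicopy simulation systems (principal-axis alignment, solvent-box
    tiling, clash pruning, an anti-aggregation repulsive Lennard-Jones term
    on one central atom per ligand copy), computes the GaMD boost-potential
    mathematics and the atom-count based equilibration schedule, and runs a
    complete per-ligand trajectory analysis: residence time, intermolecular
    nonbonded energies, MM/GBSA end-point binding free energies under the
    one-trajectory approximation, solvent exposure of the ligand, hydrogen
    bond occupancies, Jaccard clustering of residue contact sets into
    binding sites, and a consensus vote that selects the most favorable
    site. Ships a synthetic-fixture generator producing multicopy
    trajectories with programmed binding events and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
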