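Package: duplexmd
Title: Trajectory Analysis of Protein-Bound miRNA:mRNA Duplex Opening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular dynamics trajectories of
    protein-RNA complexes, centred on the question of how RNA-binding
    domains (a KH domain and the Argonaute PAZ domain) open a
    microRNA:mRNA duplex. Provides multi-model PDB trajectory input and
    output, Kabsch superposition with RMSD, RMSF and radius-of-gyration
    descriptors, a three-class residue-nucleotide contact census
    (hydrogen bond, hydrophobic, electrostatic) with trajectory occupancy
    filtering, per-base-pair opening traces and opening-order detection,
    two-dimensional pseudo-free-energy landscapes from histograms, and
    single-exponential fitting of native-contact decay kinetics. A
    deterministic synthetic structure and trajectory generator supplies
    idealized duplex systems with programmed strand-opening schedules for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
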