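Package: dyadmd
Title: Interaction Networks, Flexibility and Groove Geometry from
    Protein-DNA Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for molecular dynamics trajectories of
    protein-DNA complexes, built around the analysis of base-flipping reader
    domains bound to modified CpG dyads. Detects hydrogen bonds (distance and
    donor-hydrogen-acceptor angle criteria) and salt bridges (heavy-atom
    distance between oppositely charged groups) frame by frame, aggregates
    the resulting contact time series into occupancy-pruned weighted
    interaction networks, computes superposition-based RMSD/RMSF profiles
    with replica quality control, measures DNA minor and major groove widths
    by the cross-strand phosphate-distance construction of El Hassan and
    Calladine, and fits 1:1 binding isotherms to titration data. Ships a
    synthetic-data module (ideal B-form duplexes, trajectories with planted
    contacts at known occupancies, harmonic ensembles, divergent replica
    sets, noisy binding curves) so every stage of the pipeline can be
    validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
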