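Package: cgfold
Title: Contact-Guided Coarse-Grained Protein Structure Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs coarse-grained (C-alpha/C-beta) three-dimensional
    protein models from residue-residue contacts, non-contacts, and
    three-state secondary structure.  Contacts are derived from native
    structures at parameterized C-beta distance thresholds or read from
    ranked contact predictions in CASP RR format, translated into
    flat-bottom distance and pseudo-dihedral restraints, and embedded by
    triangle-inequality bound smoothing followed by gradient minimization
    with mirror-image resolution and a two-stage refinement protocol.
    Includes TM-score, GDT-TS and RMSD model evaluation, synthetic
    protein-like structure generators for benchmarking, and an experiment
    runner that sweeps contact thresholds, sequence-separation filters,
    secondary-structure and non-contact restraint conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
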