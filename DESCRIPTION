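Package: cryomap
Title: Cryo-EM Density Map Interpretation: Unmodeled Ligand Density, Rigid-Body Fitting and Conformational Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for interpreting single-particle cryo-EM density maps of
    flexible membrane transporters. Implements equal-volume map thresholding,
    detection of connected components of density not accounted for by a fitted
    atomic model, a four-criterion screen for candidate ligand densities
    (visibility at the protein display level, rod shape, drug-sized volume,
    absence of serious clashes), rigid-body ligand fitting scored by real-space
    correlation against a resolution-matched simulated ligand map with 180-degree
    flip disambiguation, Fourier shell correlation with resolution read-out,
    voxel-rule binding-pocket volumes, center-of-mass domain separations, and
    matched-atom RMSD with iterative distance pruning. A synthetic scene
    generator produces ground-truthed two-domain transporter maps with
    sub-stoichiometric ligand, noise and an optional micelle annulus, so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ChemmineR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
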