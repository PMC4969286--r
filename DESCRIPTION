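Package: tesplan
Title: Reciprocity-Based Targeting and Dosimetry for Transcranial Electrical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planning toolkit for multi-electrode transcranial electrical
    stimulation (TES/tDCS/tPCS). Builds synthetic volume-conductor head
    phantoms with literature tissue conductivities, solves the quasi-static
    current-flow equation by a finite-difference method on the voxel grid,
    constructs electrode-by-patch lead-field matrices through the
    reciprocity principle, parcels cortical surface meshes into
    approximately 1 cm2 dipole patches, derives safety-constrained
    source/sink electrode montages for a cortical target, constructs
    matched sham montages, computes protocol dosimetry (injection time,
    total charge, current density), and analyses motor-evoked-potential
    after-effects (trimmed averaging, baseline normalisation, paired
    one-tailed t-tests, exact binomial goodness-of-fit) on synthetic
    cohorts. An analytic concentric-sphere Legendre-series solver is
    included as an independent oracle for the numerical forward model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
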