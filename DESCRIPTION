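Package: hpstwin
Title: Automated Construction of His-Purkinje System Models for Cardiac Digital Twins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage construction of His-Purkinje system (HPS) models on
    biventricular geometries addressed through universal ventricular
    coordinates (UVC). A phenomenological fascicle-based model (timed
    disc-shaped earliest activation sites embedded in a fast-conducting
    sub-endocardial layer) can be replaced automatically by a topologically
    realistic Purkinje model: a His bundle laid out from UVC bifurcation
    points, five recombinant fractal networks grown on the sub-endocardial
    surface, stochastic Purkinje-ventricular junction (PVJ) placement, and
    ray-traced transmural extension of the junctions into the wall.
    Activation of the coupled network-myocardium domain is computed with a
    graph eikonal solver supporting orthodromic/antidromic network
    propagation and asymmetric anterograde/retrograde PVJ delays, and
    12-lead pseudo-ECGs are derived by infinite-conductor dipole summation
    of an action-potential template. Ships an idealized synthetic
    biventricular geometry generator with analytic UVCs so the full
    workflow runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    Matrix,
    methods,
    deSolve,
    signal,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
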