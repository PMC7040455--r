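Package: voxlight
Title: Voxel-Based Monte Carlo Light Transport with Smoothed Boundary Normals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo simulation of light transport in turbid media on a
    regular voxel grid, with accurate handling of curved and oblique
    refractive-index-mismatched boundaries. Boundary orientation is estimated
    by a precomputed surface-normal field: per-medium binary maps are filtered
    with the 3x3x3 Sobel-Feldman operator, smoothed by a discrete-cosine
    penalized least-squares smoother, mask-aggregated and normalized; at run
    time the photon loop can use the voxel face normal, the stored surface
    normal, or a same-medium-masked trilinear interpolation of neighboring
    normals when evaluating Fresnel reflection and Snell refraction. Includes
    phantom generators (slab, sphere, biconvex lens), an analytic ray-tracing
    oracle for spheres and spherical lenses, fluence and escape-record
    containers with raw-binary/JSON and CSV serialization, and percent-change
    comparison maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
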