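Package: voroshell
Title: Voronoi-Polyhedron Characterization of Solvation Shells in Periodic
    Molecular Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs the Voronoi polyhedron of a tagged solute site in
    periodic cubic molecular configurations by half-space clipping with
    periodic images, and derives metric and topological descriptors of the
    solvation shell: face count (solvation number), volume, surface area,
    cage radius, face-weighted radius and asphericity.  Provides the
    one-dimensional baseline (solute-solvent radial distribution function,
    first-peak features and running coordination number), a descriptive
    statistics layer for box-and-whisker and violin summaries, synthetic
    configuration generators (perfect lattices, Poisson gas, Metropolis
    soft-sphere liquid), extended-XYZ input/output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
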