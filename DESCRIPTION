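Package: memshape
Title: Membrane Mechanics of Closed Vesicle Shapes with Curved Nanodomains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling closed lipid-membrane shapes governed by
    curvature elasticity. Implements the tangent-angle Fourier
    parameterization of axisymmetric vesicles with constrained minimization
    of Helfrich, deviatoric two-component, BAR-domain, membrane-skeleton
    shear and non-local (area-difference) bending energies; an analytic
    self-assembly theory for curved membrane nanodomains including the
    critical aggregation concentration; a mapping from rigid cone-like
    inclusion geometry to effective nanodomain elastic parameters; and a
    dynamically triangulated Metropolis Monte-Carlo simulator of vesicles
    carrying curved nanodomains with direct attraction and active normal
    forces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
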