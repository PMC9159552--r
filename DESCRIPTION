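Package: vertexrheo
Title: Linear Viscoelasticity of the Two-Dimensional Vertex Model for
    Epithelial Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the linear rheology of the
    two-dimensional vertex model of confluent epithelial monolayers. Builds
    periodic hexagonal and disordered (random sequential addition + periodic
    Voronoi) tilings, evolves them with overdamped dynamics under small
    oscillatory shear or biaxial deformation, measures complex dynamic moduli
    by block Fourier analysis with a steady-state criterion, fits spring-
    dashpot constitutive models (standard linear solid, Burgers, generalized
    Maxwell) to the measured modulus curves, evaluates the analytic
    quasistatic, affine-shear and bulk modulus limits, and locates the
    solid-fluid rigidity transition from the spectrum of the energy Hessian,
    including its shift under uniaxial pre-deformation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
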