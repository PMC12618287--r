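Package: veinfit
Title: Four-Fiber-Family Hyperelastic Characterization of Venous Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constitutive characterization of venous tissue from uniaxial
    strip tension tests. Implements the incompressible four-fiber-family
    exponential strain energy density function (a Holzapfel-Gasser-Ogden
    type model with circumferential, longitudinal and two symmetric
    diagonal fiber families over a neo-Hookean matrix), analytic first
    Piola-Kirchhoff stresses, the uniaxial strip boundary-value problem
    with the transverse stretch determined by a zero-transverse-stress
    condition, construction of per-donor representative stress-stretch
    curves from repeated specimens, constrained global least-squares
    identification of the eight constitutive parameters, extraction of
    initial and tangent Young's moduli, and a synthetic virtual-experiment
    generator for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lhs,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
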