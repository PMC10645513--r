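Package: cytospread
Title: Cortex-Driven Cytoplasmic Flows and Nuclear Spreading in Elongated Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical models of boundary-driven Stokes flow inside a prolate
    spheroidal cell and the cytoplasmic transport it generates. Provides the
    exact Gegenbauer-series streamfunction solution for an arbitrary
    axisymmetric tangential slip velocity on the cell cortex, a long-wavelength
    (lubrication) flow solution for general elongated cell shapes, a passive
    tracer simulator for nuclear transport in rescaled time with
    kernel-density and strip-count measures of axial spreading homogeneity,
    and a fully analytical one-dimensional reduced transport model solved by
    the method of characteristics. Includes the Drosophila embryo cortical
    slip profile and tools to locate the cortical forcing that spreads nuclei
    most uniformly along the anterior-posterior axis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
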