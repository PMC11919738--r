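Package: vippgeom
Title: Geometry of Vipp1 Helical Lattices, Membrane Spirals and Rings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the lattice geometry of ESCRT-III-like Vipp1 polymers.
    Translates refined helical symmetry parameters (rise and twist) into
    n-start helix families, Bessel orders, pitches and layer lines; unrolls
    helical lattices and density maps into their geometrically equivalent 2D
    planar lattices; generates physically parameterized synthetic AFM height
    images of membrane-bound sheets, spiral filaments and rings with ground
    truth; measures ridge periodicity, object morphometrics and filament
    growth rates from such images; fits Archimedean and exponential spirals;
    and evaluates the inter-ridge spacing bounds that set the minimum planar
    curvature of a filament and decide when central rings must tilt out of
    the membrane plane.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    EBImage,
    withr,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
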