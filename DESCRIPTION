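Package: shapejam
Title: Cell-Shape Statistics and Glassy Dynamics of Confluent Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative study of shape-driven jamming in
    confluent cell monolayers and their synthetic mimics. Implements the
    one-parameter k-gamma and mean-field aspect-ratio distributions, their
    maximum-likelihood fits, the universal linear scaling between the mean
    and standard deviation of the cell aspect ratio, glassy-dynamics
    observables on cell-center trajectories (mean-squared displacement,
    self-intermediate scattering function, structural relaxation and
    cage-rearrangement times, fast/slow mobility subsets, periodic Voronoi
    areas and adjacency), a thermal vertex model of a confluent tissue with
    T1 topology changes and a frozen-cluster protocol, and seeded synthetic
    generators (chiral active Brownian trajectories, distribution samplers,
    polygon ensembles with prescribed aspect ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    igraph,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
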