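Package: supercoilr
Title: Coarse-Grained Langevin Dynamics of Supercoiling-Driven DNA Unknotting and Decatenation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Torsionally constrained bead-spring model of double-stranded DNA with
    active swivels (gyrase), passive swivels (nicks), single-stranded gaps and
    topoisomerase III style strand passage. Provides a Langevin-dynamics integrator
    with rigid periaxial torsional frames, builders for knotted and catenated
    starting configurations, and a polymer-topology toolkit (writhe, twist, linking
    number, Alexander-determinant knot detection, knot-core localization,
    persistence length, rotational diffusion and time-unit calibration).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
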