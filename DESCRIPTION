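Package: articmorph
Title: Articular Surface Morphometry for Tarsometatarsal Joint Bone Meshes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative morphometry of articular surfaces on triangulated
    bone meshes, built around the first and second tarsometatarsal joints.
    Provides mesh reading and writing (STL, PLY, OBJ) with validity checks,
    discrete principal and Gaussian curvature estimation by local polynomial
    height fits, automatic extraction of articular surfaces as connected
    low-curvature regions bounded by high curvature, automatic anatomic
    coordinate frames for cuneiform- and metatarsal-like bones, size and
    width-profile measurements in anatomic frames, a curvature-similarity
    statistic for opposing joint surfaces, a cohort statistics battery
    (paired and one-sample t-tests, three-way ANOVA with Games-Howell post
    hoc), and a synthetic phantom generator with analytic ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    car,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
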