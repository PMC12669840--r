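Package: billmorph
Title: Bill Shape Dimorphism and Stabbing Biomechanics in Hermit Hummingbirds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying sexual dimorphism and stabbing biomechanics of
    hummingbird bills. Generates parametric synthetic bill geometries (curved,
    tapered, bilaterally symmetric surfaces with a thin keratin shell over a
    bone core), converts labeled contour curves into fixed-landmark plus
    sliding-semilandmark configurations, performs generalized Procrustes
    analysis with semilandmark sliding, bilateral symmetry decomposition and
    principal component analysis of shape, computes univariate bill descriptors
    (arc:chord curvature, arc length, outer surface area, tip sharpness ratio,
    included angle), runs Procrustes ANOVA with permutation and rank-based
    tests, and evaluates stabbing performance with a linear-static tetrahedral
    finite-element solver (von Mises stress summaries, strain energy,
    eigenvalue buckling) under comparative force scaling protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
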