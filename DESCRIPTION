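Package: optcat
Title: Optional Polya Tree Density Estimation for Factor Variables with
    Many Categories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonparametric Bayesian estimation of the joint probability
    distribution of multivariate unordered factor variables with tens to
    hundreds of categories, such as diagnosis codes or gene identifiers.
    The sample space is recursively bisected by an optional Polya tree
    whose candidate splits are guided by local marginal populations, so
    that only one split per variable has to be scored at each region.
    Posterior inference extends the tree to individual combination cells
    through uniform Dirichlet allocations and supports posterior-mean,
    posterior-mode and sampled distributions. The package includes a
    limited-lookahead tree construction for large spaces, baseline
    estimators (cell-wise maximum likelihood, Aitchison-Aitken categorical
    kernel smoothing, random-partition trees), simulation generators with
    known truth tables, root-sum-square-error benchmarking, and extraction
    of co-occurrence networks from terminal regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
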