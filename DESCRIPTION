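Package: latticePeaks
Title: Stochastic Lattice Simulation of Recombining Populations on Rugged
    Fitness Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An agent-based simulator of haploid populations evolving on an
    n-by-n lattice under tunable recombination and spatially restricted
    ("local") versus panmictic ("global") reproduction. Genotypes are binary
    haplotypes on rugged, multi-peaked survival landscapes; the engine
    implements per-update death/birth dynamics with neighborhood-constrained
    parent selection, single-donor-switch recombination and per-locus
    mutation. Tracking utilities derive discovery and establishment times,
    recombination- versus mutation-origin creation counts and mean relative
    fitness from event logs. An experiment layer runs factorial designs with
    replicate management, percentile-bootstrap confidence intervals,
    ratio-of-means comparisons and Manly-style raw-data permutation tests
    for factorial interactions, reproducing peak-jumping at spatial sutures
    between suboptimal-peak clusters and the protection of nascent peak
    genotypes inside monotypic cluster centers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
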