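Package: opinionmedia
Title: Bounded-Confidence Opinion Dynamics with Algorithmic Bias and Mass Media
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of continuous opinion dynamics under
    bounded confidence, extending the Deffuant-Weisbuch model with a
    distance-decaying partner-selection kernel (modelling recommender-system
    filtering) and stubborn mass-media agents that broadcast fixed opinions.
    Provides a compiled simulation core with cluster-equilibrium and
    opinion-change stopping rules, mean-field and network topologies with
    homogeneous or per-agent confidence bounds, gap-threshold cluster
    detection, the cluster participation ratio, media-cluster occupancy,
    opinion entropy, echo-chamber statistics, scenario sweeps over media
    landscapes, synthetic polarized-network fixtures, and a hashtag-based
    leaning-ingestion pipeline for constructing initial opinions from
    annotated social-media tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
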