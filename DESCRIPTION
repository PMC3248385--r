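Package: correlognet
Title: Correlog and Anti-Correlog Gene Networks from Phylogenetic Profiles
Version: 0.1.0
Authors@R: person("Correlognet", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers direct gene-gene associations from binary phylogenetic
    profiles (gene-by-species presence/absence matrices) using
    shrinkage-regularized partial correlation under a graphical Gaussian
    model. Positive partial correlations mark correlogs (genes that
    preferentially co-occur across genomes) and negative ones mark
    anti-correlogs. The package builds the maximum relatedness subnetwork
    (MRS), decomposes it into correlog groups, and provides the
    accompanying statistical machinery: analytic expectations for the
    number of distinct groups hit by a gene set, permutation nulls for
    functional coherence and category overlap, stratified pair-set
    comparisons against interaction networks, and phylum-dispersion
    regression. A synthetic planted-module generator makes every stage
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
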