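Package: ginyield
Title: Descriptor-Guided Pre-Training of Graph Isomorphism Networks for
    Chemical Reaction Yield Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pre-trains a graph isomorphism network (GIN) molecule encoder on
    a pre-text task in which every molecule is pseudo-labelled with the
    leading principal-component scores of its 2D molecular descriptors, the
    squared prediction error of each score being weighted by the
    corresponding PCA eigenvalue.  The pre-trained encoder initialises a
    chemical-reaction-yield regression model that encodes every reactant and
    the product of a reaction, outputs a predictive mean and variance, is
    fine-tuned with a mixed homoscedastic/heteroscedastic loss, and is
    evaluated with Monte-Carlo-dropout inference.  Includes SMILES
    featurization into node/edge-attributed molecular graphs (via Open
    Babel), a native 2D descriptor engine, dataset loaders and split
    protocols for high-throughput-experimentation yield benchmarks, and a
    synthetic molecule/reaction generator so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
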