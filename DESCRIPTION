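Package: leafcutter
Title: Agent-Based Simulation of Task Partitioning in Leaf-Cutter Ant Foraging
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based model of leaf-cutter ant colonies foraging on a tree,
    in which two heritable behavioural probabilities -- the tendency to drop
    leaves from the treetop and the tendency to pick up dropped leaves from a
    ground cache -- generate self-organised task partitioning through
    stigmergy. Provides the grid-world colony simulation, replicate sweeps of
    the two probabilities to build interpolated fitness landscapes for
    terrestrial, intermediate and arboreal environments (tree heights 1, 10
    and 20), and haploid two-locus evolutionary simulations of colony
    populations on those landscapes, together with CSV export, a command-line
    interface and reproducibility manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
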