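Package: pmapr
Title: Network-Based Phenotype Mapping of Drug Response Networks
Version: 0.1.0
Authors@R: person("pmapr", "developers", email = "pmapr@example.org",
    role = c("aut", "cre"))
Description: Infers drug response networks (DRNs) from basal gene expression,
    per-sample EC50 drug sensitivity and a protein-protein interaction (PPI)
    network. Samples are ranked by EC50 and extreme tails define sensitive and
    resistant phenotypes per drug and population group; template matching
    against the binary phenotype identifies phenotypic differentially
    expressed genes (PDEGs); graph mining on the PPI network discovers first-
    and second-tier PDEG-interacting genes (N1, N2), whose occurrence
    frequencies across PDEG-N1 pairs yield phenotypic frequency (PF) scores
    that predict the directionality of drug-response change under knockdown.
    Includes hypergeometric over-representation and pre-ranked gene set
    enrichment analyses, a consistency classifier for knockdown screens, a
    fully synthetic data generator with planted ground truth, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
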