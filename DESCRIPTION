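Package: cftrmapkit
Title: Evidence-Curated Multi-Layer Interactome Maps in SBGN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building and analysing two-layer molecular
    interaction maps of the kind used to describe the CFTR protein
    lifecycle. Provides literature-evidence curation rules (acceptance of
    an interactor requires at least two independent small-scale
    experiments in human cells, or two reviews from different research
    groups), cell-polarity provenance flags, generation of SBGN Process
    Description core maps and automatically laid out SBGN Activity Flow
    coarse submaps with SBGN-ML serialization, integration of the
    manually curated and high-throughput data layers, protein-protein
    interaction network topology (degree distribution, power-law
    assessment, betweenness centrality, hubs, Louvain communities), and
    hypergeometric over-representation analysis of GMT gene sets with
    Benjamini-Hochberg correction. A deterministic synthetic-fixture
    generator and a packaged CFTR-style fixture make every analysis
    reproducible offline.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    igraph,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
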