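Package: netFingerprint
Title: Network Fingerprints for Annotated Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes a query biological network as a spectrum-like
    vector of similarities to a reference set of well-studied basic networks
    (the "network fingerprint"). Each coordinate combines functional and
    topological evidence: the query and a reference network are merged by
    gene name, node pairs are weighted with Resnik semantic similarity
    derived from Gene Ontology annotations, nodes are grouped by affinity
    propagation clustering on the semantically weighted adjacency, a
    cluster-wise bidirectional best-match score is averaged into a raw
    similarity, and the raw score is standardized against a null
    distribution obtained from degree-preserving (Maslov-Sneppen) network
    rewiring. Includes readers and writers for OBO ontologies, GAF
    annotations, edge-list, GraphML and KGML-subset network files, grouped
    reference-set management, and a synthetic-fixture generator with planted
    structure for fully offline testing.
License: GPL (>= 2)
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'apcluster.R'
    'fingerprint.R'
    'merge.R'
    'netio.R'
    'ontology.R'
    'randomize.R'
    'synthfix.R'
    'utils.R'
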