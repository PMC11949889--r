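Package: sckanr
Title: Neuron Population Connectivity Knowledge Graphs for the Autonomic
    Nervous System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model, serialize, and query region-to-region neural connectivity
    knowledge for the peripheral and autonomic nervous system at the neuron
    population level ("population N at A projects to B via C"). Populations
    carry locational phenotypes (soma, dendrite, axon, terminals), autonomic
    subdivision, circuit role, species and sex annotations, an ordered
    partial-order tree encoding the axonal course, and synaptic forward
    connections. The package reads and writes two Turtle dialects (nested
    OWL equivalent-class axioms with RDF-list projection paths, and the
    flattened shortcut-relation "simple" dialect), materializes the shortcut
    triples and adjacency edges, provides transitive-closure services over
    partonomy and subclass hierarchies, and implements the standard
    competency queries (end-organ termination, nerve routing, perturbation
    impact, pre/post-ganglionic innervation circuits) together with
    phenotype summary tables, CSV and Graphviz DOT export, a seeded
    synthetic-graph generator with a ground-truth ledger, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
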