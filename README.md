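# sckanr

Neuron-population connectivity knowledge graphs for the peripheral and
autonomic nervous system, in R.

## The problem

Knowledge about autonomic nervous system (ANS) connectivity — which spinal
segments or brainstem nuclei project to which ganglia and end organs, and
through which nerves — is scattered across the literature and across
expert-built circuit models. Connectivity knowledge bases such as SCKAN
distill it into a uniform, machine-readable statement: **neuron population
N at A projects to B via C**, where *A* is the set of regions holding the
somata, *B* the axon (or sensory) terminals, and *C* the axon course,
including nerves. Each population additionally carries its ANS subdivision
(sympathetic / parasympathetic / enteric, pre- or post-ganglionic),
circuit and functional roles, species and sex observations, provenance,
and a *partial-order tree* recording the ordered, possibly branching
sequence of structures its axons traverse. Synaptic circuits arise from
*forward connections* between first-order (CNS → ganglion) and
second-order (ganglion → end organ) populations; the synapse locations
are the shared structures where the former terminates and the latter
originates.

`sckanr` is a library and command-line tool for working with this
representation. It is aimed at neuroinformaticians and knowledge engineers
who need to build, validate, exchange, and query such graphs without a
triple-store deployment. It provides:

- an in-memory data model with validation (`neuron_population()`,
  `anatomical_entity()`, `po_tree()`, `validate_population()`);
- readers/writers for the two Turtle dialects in circulation: the full
  OWL axiom form (equivalent-class intersections of `someValuesFrom`
  restrictions, each location wrapped in a nested part-of restriction;
  closed-world sex via an explicit complement of the opposite sex;
  `neuronPartialOrder` RDF collections for the axonal course) and the
  flattened *simple* shortcut form (`hasSomaLocation`,
  `hasAxonTerminalLocation`, `hasConnectedLocation`, ...) that makes
  queries tractable (`read_ttl()`/`write_ttl()`,
  `read_simple_ttl()`/`write_simple_ttl()`, `to_simple_graph()`);
- transitive-closure services over partonomy, subclass, and supplies-to
  hierarchies (`kg_ancestors()`, `resolve_label()`, `is_nerve_like()`);
- the four standard competency queries: connections terminating in an
  organ (`connections_terminating_in()`), connections traveling through a
  nerve or its branches (`connections_via()`), structures affected by
  perturbing a structure (`affected_by_perturbation()`), and the full
  pre/post-ganglionic innervation circuit of an end organ with synapse
  detection (`innervation_circuit()`), plus phenotype summary tables
  (`phenotype_summary()`);
- a seeded synthetic-graph generator with a ground-truth ledger
  (`generate_graph()`), bundled worked-example circuits
  (`load_fixture()`), CSV/JSON/DOT export, and a CLI
  (`inst/scripts/sckan-cli`).

## Worked example

The bundled `prostate` fixture encodes the canonical worked example: a
sympathetic pre-ganglionic population from L2–L5 lumbar spinal cord to the
inferior mesenteric ganglion via the lumbar splanchnic nerve, observed in
male dogs, forward-connected to a second population.

```r
library(sckanr)

g <- load_fixture("prostate")
p24 <- g$populations[["prostate:24"]]
p24
#> <neuron_population> prostate:24
#>   L2-L5 spinal cord to inferior mesenteric ganglion via lumbar splanchic nerve
#>   soma                    UBERON:0006447, UBERON:0006449, UBERON:0006450, UBERON:0006451
#>   axon                    UBERON:0018683
#>   axon_terminal           UBERON:0005453
#>   ANS phenotype: Sympathetic Pre-Ganglionic phenotype
#>   sex-specific: male
#>   forward connections: prostate:25

# flatten the branching axonal course into adjacency edges
partial_order_to_adjacency(p24$path, p24$id)
#>             from             to  population
#> 1 UBERON:0006447 UBERON:0018683 prostate:24
#> 2 UBERON:0018683 UBERON:0005453 prostate:24
#> 3 UBERON:0006450 UBERON:0018683 prostate:24
#> 4 UBERON:0006449 UBERON:0018683 prostate:24
#> 5 UBERON:0006451 UBERON:0018683 prostate:24
```

Five edges: the four segmental branches converge on the lumbar splanchnic
nerve, which leads to the ganglion. What would an electrode at that
ganglion perturb?

```r
affected_by_perturbation(g, "inferior mesenteric ganglion")
#>            curie                            label
#> 1 UBERON:0006450 L2 segment of lumbar spinal cord
#> 2 UBERON:0006449 L3 segment of lumbar spinal cord
#> 3 UBERON:0006451 L4 segment of lumbar spinal cord
#> 4 UBERON:0006447 L5 segment of lumbar spinal cord
#> 5 UBERON:0018683          lumbar splanchnic nerve
```

Circuit queries trace forward connections. On the `femrep` fixture (the
sympathetic innervation circuit of the ovary in the female rat):

```r
f <- load_fixture("femrep")
rows <- innervation_circuit(f, "ovary", "Sympathetic Post-Ganglionic phenotype")
unique(rows$population)
#> [1] "femrep:36"   "femrep:37"   "femrep:40-1"
unique(rows$v2_label[rows$is_synapse])
#> [1] "T12 paravertebral sympathetic chain ganglion"
#> [2] "T13 paravertebral sympathetic chain ganglion"
#> [3] "L1 paravertebral sympathetic chain ganglion"
```

One preganglionic and two postganglionic populations; the synapses sit on
the three paravertebral-chain structures where `femrep:36` terminates and
both postganglionics originate.

From the shell:

```sh
Rscript inst/scripts/sckan-cli query cq3 \
  --input inst/extdata/prostate.ttl \
  --structure "inferior mesenteric ganglion" --out affected.csv
Rscript inst/scripts/sckan-cli export dot --input inst/extdata/femrep.ttl \
  --organ ovary --phenotype "Sympathetic Post-Ganglionic phenotype" \
  --out circuit.dot
```

## Scope notes

The package models connectivity, not biophysics: branching vs. distinct
subpopulations is deliberately not distinguished, dendritic synaptic
circuitry is out of scope, and laterality is carried in labels and alert
notes rather than logical axioms. See the methods vignette
(`vignettes/connectivity-model.Rmd`) for the full account of the model,
its assumptions, and its numerical and design choices.
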