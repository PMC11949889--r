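---
title: "The neuron-population connectivity model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The neuron-population connectivity model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sckanr)
```

## The model

`sckanr` represents peripheral-nervous-system connectivity at the level of
*neuron populations*: theoretical groupings of neurons that share
phenotypic properties and subserve one region-to-region connection,
"population *N* at *A* projects to *B* via *C*". The model is neuronal
rather than regional: each population assigns anatomical locations to
individual neuronal segments — soma, dendrite, axon segments, axon
terminal, axon sensory terminal (the peripheral process of
pseudo-monopolar sensory connections) — so that an axon traversing many
structures and several nerves can be traced segment by segment.

Key modeling assumptions, which the implementation enforces or
deliberately leaves open:

- **At least one origin and one destination.** A population must have a
  non-empty soma location set and a non-empty union of axon-terminal and
  sensory-terminal locations. These are hard validation errors
  (`MISSING_ORIGIN`, `MISSING_DESTINATION`). The single tolerated
  exception is a *stub*: a population that exists only as the target of
  another population's forward connection, with no locations yet; stubs
  serialize with just their identity metadata.
- **Multiple origins are one population, not several.** A population with
  somata in four spinal segments is one distributed population; whether
  targets are reached by branching axons or distinct subpopulations is
  not modeled, so the package records no branching-vs-subpopulation
  distinction.
- **Sex is closed-world.** If a sex is asserted, the serialized axiom set
  carries an explicit negation (`owl:complementOf`) of the opposite sex,
  and a query filtered to the opposite sex never returns the population.
  If no sex is asserted, the connection is assumed to exist in both
  sexes.
- **Species is open-world.** Taxon assertions record where a connection
  has been *observed*; an empty taxon set means "observed in some mammal,
  species unspecified" and matches only the "unassigned" filter, never a
  named-species filter — absence of evidence is not negation.
- **Laterality is lexical.** Left/right differences live in entity labels
  (e.g. "left ovary") and free-text alert notes, not in logical axioms.
- **Forward connections are directed.** The pre-to-post link is not
  reciprocal; predecessor lookup during circuit queries uses an inverted
  index built on the fly, and no inverse triples are asserted.

### Partial orders and adjacency

The axonal course is an ordered, possibly branching tree
(`po_tree()`) whose root is the distinguished literal `"blank"`; root
children begin at soma locations and leaves are terminals. The tree
serializes as a nested RDF collection under `ilxtr:neuronPartialOrder`.
Flattening parent→child pairs (excluding the root) yields the adjacency
edges used by circuit queries and DOT export; structures shared across
branches — e.g. one nerve entered from four spinal segments — are merged
by CURIE, so repeated pairs deduplicate. A path node absent from every
location set is a *warning* (`PATH_LOCATION_MISMATCH`), not an error: the
partial order and the location sets are parallel encodings with no stated
mutual-consistency rule, and hard-failing would reject plausibly curated
content. Validation reports are data, never conditions: callers decide
whether warnings block.

### Two dialects

The OWL dialect expresses each population as an `owl:equivalentClass`
intersection: a base class marker (`ilxtr:NeuronSparcNlp` for
literature-extracted content, `ilxtr:NeuronApinatSimple` for
expert-model content) followed by `owl:someValuesFrom` restrictions, each
*locational* restriction nesting a part-of restriction around the
location CURIE. The simple dialect flattens each axiom to one shortcut
triple per fact (`hasSomaLocation`, `hasAxonTerminalLocation`, ...),
adds `hasConnectedLocation` for every location of every role, and carries
the derived adjacency edges. Materialization (`to_simple_graph()`) is
idempotent, and the same origin/destination listing must be extractable
from either dialect's raw triples — a property the test suite checks
against pattern-matching extractors independent of the readers.

Design choices where the dialect left room:

- *Sex negation rendering.* The negation is serialized as
  `owl:complementOf` wrapping the opposite-sex restriction — the standard
  RDF mapping of a Manchester-syntax `not (...)` — and the reader accepts
  only that form. In the simple dialect, which has no published negation
  form, we emit a dedicated `ilxtr:excludedBiologicalSex` triple so
  closed-world filtering stays expressible with flat triples.
- *Edge-annotated adjacency.* Store-specific edge-property syntax
  (`hasNextNode {isConnectedBy ...}`) is replaced by reified edge records
  (`ilxtr:PathEdge` blank nodes with source, target, and owning
  population), portable across plain-RDF backends.
- *`hasConnectedLocation` is asserted,* not derived at query time, so
  perturbation queries work on any conforming store without inference.
- *Property IRIs not printed anywhere public* (the axon-to-sensory course
  on the OWL side; circuit role and functional circuit role) use
  documented placeholder names in the `ilxtr` namespace
  (`hasAxonToSensoryTerminalIn`, `hasCircuitRolePhenotype`,
  `hasFunctionalCircuitRolePhenotype`). The shortcut-side names are the
  published ones. `hasNeuronalPhenotype` is treated as the shortcut of
  `hasAnatomicalSystemPhenotype`.
- *Canonical serialization order* — populations by id; within an axiom:
  taxon, sex, phenotypes, locations in role order then CURIE, forward
  connections — makes the writer byte-stable, so identical graphs always
  produce identical documents (exploited by the determinism tests and by
  content hashing in the CLI logs).
- *Citations* are typed literals (`DOI:`/`PMID:`/`ISBN:`/`ORCID:` tags)
  under a single `ilxtr:reference` predicate.

### The Turtle layer

No Turtle parser exists in this package's R dependency tier, so the
package implements the subset the dialects need natively: prefix
declarations, prefixed names (including empty local parts like
`partOf:`), IRIs, string literals, blank-node property lists, RDF
collections, comments, and predicate-object lists. Collections and blank
nodes expand to flat triples over generated `_:b<n>` identifiers. The
subset excludes language tags, numeric literals, and `@base`. The test
suite cross-checks the writer's output against an independent RDF parser
(Python `rdflib`), asserting identical triple counts after collection
expansion.

## Queries

All four competency queries run on the simple form (an OWL-dialect graph
is materialized transparently) and mirror the published SPARQL patterns:

1. **End-organ termination**: terminals scoped by the *part-of* closure
   of the organ; the `via` column restricted to nerve-like structures
   (subclass closure reaching "nerve", "nerve plexus", or "nerve fiber")
   unless relaxed, in which case the result is a superset.
2. **Nerve routing**: axon-course locations scoped by the *subclass ∪
   part-of* closure, so branch nerves match their trunk.
3. **Perturbation impact**: union, over populations touching the
   structure in any role, of all their other connected locations; the
   structure itself excluded.
4. **Innervation circuit**: target populations by exact ANS phenotype
   label whose final terminal reaches the organ via *part-of ∪
   supplies-to* closure; the circuit closes over reflexive-transitive
   forward-connection predecessors; a node is a synapse when it is an
   axon-terminal location of its population and a soma location of a
   directly forward-connected population.

Closures are *reflexive* (SPARQL `*` semantics: a structure is in its own
closure), and although raw entity edges are validated acyclic, closure
computation is visited-set-guarded so corrupt inputs cannot hang. Label
resolution is exact lowercase-folded equality over labels and synonyms —
no stemming or fuzzy matching — mirroring the `LCase(...) = ...` filters
of the published queries. Result ordering follows the queries' `ORDER BY`
clauses with CURIE-lexicographic tie-breaks, so CSV exports are stable
across runs.

The phenotype summary exposes both coarse ANS buckets (sympathetic /
parasympathetic / enteric, the form used in release-level content
tables) and exact stage-qualified labels (the form circuit queries
filter on); species counts are non-exclusive, since one connection can
be observed in several taxa.

## The synthetic generator

`generate_graph()` builds worlds with the structural features of a real
connectivity release: an organ partonomy of configurable depth, a nerve
hierarchy in which roughly 30% of nerves are branches (part-of a trunk),
ganglia, spinal segments, populations with 1–2 origins routed via a nerve
to organ parts, and planted pre/post-ganglionic circuits whose synapse
ganglion and dedicated target organ are recorded in a ground-truth
ledger. The ledger also records each via nerve's trunk closure, because a
population routed via a branch is — correctly — returned by a query on
the trunk.

Default proportions are fixed once, chosen to mirror a mature autonomic
release's phenotype mix: 45% sympathetic, 26% parasympathetic, 1%
enteric, 24% female-specific, 9% male-specific, 70% species-annotated.
Default problem size is 80 entities, 30 populations, 3 circuits,
partonomy depth 2 — small enough that a fifty-world property test runs in
seconds, large enough that every query path (branch nerves, multi-part
organs, distractor populations) is exercised. Circuit organs are disjoint
from distractor organs so the ledger predicts circuit-query results
exactly; distractor populations otherwise draw phenotypes freely.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: skewed real-world degree distributions (a vagus
nerve touched by dozens of populations), partonomy gaps and synonym
noise in community ontologies, curation errors, multi-species axiom
updates over time, and dendrite-bearing populations. Tests against
generated worlds demonstrate correctness of the machinery, not coverage
of curatorial pathology.

Determinism: all generator randomness is driven by the config seed
through an isolated RNG scope that restores the caller's random stream;
identical `(config, seed)` yields byte-identical serializations.

## Bundled circuits

Three in-memory circuits ship as OWL-dialect Turtle under `inst/extdata/`
(written by the package's own canonical writer, and verified byte-equal
to it by the test suite):

- `prostate` — the lumbar-splanchnic worked example (four somata L2–L5,
  one nerve, one ganglion, forward-connection stub), using the published
  UBERON identifiers.
- `femrep` — the ovarian sympathetic circuit: preganglionic somata in
  T9–T10, terminals at *three* paravertebral-chain locations (the
  description says "three locations (T12-L1)" and the printed word
  governs, though segmental naming could suggest more), two
  postganglionic populations to left and right ovary via the ovarian
  nerve plexus, all female-rat-specific. Identifiers for structures whose
  published IDs are not reproduced here are minted in an ILX-style
  namespace and are synthetic, non-authoritative.
- `salivary` — a parasympathetic chain testing strict order preservation:
  facial nerve, then greater petrosal nerve, then vidian nerve.

Two toys (`bladder_toy`, `vagus_toy`) are built in code for planted-truth
query tests: six of ten populations terminating in bladder parts, and
vagus-branch routing with a nodose-ganglion synonym.

## Numerical and degenerate-input choices

- Empty graphs are legal everywhere: queries return zero-row frames with
  stable column sets; summaries return zero counts.
- An organ label that resolves to several CURIEs scopes the query to any
  of them; an unresolvable label is an error (queries), never a silent
  empty result.
- Unknown CURIEs referenced by populations go to an `unresolved` registry
  (`kg_unresolved()`) surfaced by validation as warnings; closures treat
  them as leaves.
- `sample()`-style length-1 surprises and empty-range loops in the
  generator are guarded explicitly; generated worlds always pass hard
  validation before they are returned.
- The release-scale benchmark (published query counts of the pinned
  public release) requires a one-time download of that release's
  simple-dialect Turtle into `tests/testthat/sckan-release/`; the file is
  far larger than this package may bundle, so the corresponding
  acceptance test reports a failure when the file is absent rather than
  silently passing.

## Known limitations

Dendritic circuitry and molecular/morphological phenotype dimensions are
out of scope; the OWL reader accepts only this package's dialect (not
arbitrary third-party ontologies); the simple dialect does not carry the
partial-order *tree* (only its derived adjacency edges), so an
OWL→simple→OWL trip is lossy by design; and no confidence or
probabilistic annotations are modeled.
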