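#' Bundled connectivity fixtures
#'
#' Five small knowledge graphs used throughout the documentation and test
#' suite:
#'
#' * `prostate` -- the canonical worked example: population `prostate:24`
#'   ("L2-L5 spinal cord to inferior mesenteric ganglion via lumbar
#'   splanchnic nerve", sympathetic pre-ganglionic, male dog) with its
#'   branching partial order, plus the `prostate:25` forward-connection
#'   stub. Anatomical UBERON identifiers are the published ones.
#' * `femrep` -- the sympathetic innervation circuit of the ovary in the
#'   female rat: preganglionic `femrep:36` (T9-T10 somata, via the white
#'   communicating rami of T9-T10, terminating in three paravertebral
#'   sympathetic chain locations) forward-connected to postganglionic
#'   `femrep:37` (left ovary) and `femrep:40-1` (right ovary), both
#'   routed via the ovarian nerve plexus.
#' * `salivary` -- a parasympathetic preganglionic population from the
#'   superior salivatory nucleus to the pterygopalatine ganglion via the
#'   facial nerve, then the greater petrosal nerve, then the vidian
#'   nerve, in that order.
#' * `bladder_toy` -- ten populations, six of which terminate in parts of
#'   the urinary bladder via nerve routes, four distractors targeting the
#'   urethra.
#' * `vagus_toy` -- populations routed via the vagus nerve or its
#'   branches (including one via the superior laryngeal nerve, a part of
#'   the vagus hierarchy) plus an excluded pelvic route; includes the
#'   nodose ganglion synonym.
#'
#' `prostate`, `femrep`, and `salivary` are shipped as OWL-dialect Turtle
#' under `inst/extdata/` and parsed on load; the toys are built in code.
#' Minted `ILX:`-style identifiers for structures whose published IDs are
#' not reproduced here are synthetic and non-authoritative.
#'
#' @param name one of `"prostate"`, `"femrep"`, `"salivary"`,
#'   `"bladder_toy"`, `"vagus_toy"`.
#' @return a `sckan_graph` (OWL dialect).
#' @export
#' @examples
#' g <- load_fixture("prostate")
#' g$populations[["prostate:24"]]
load_fixture <- function(name = c("prostate", "femrep", "salivary",
                                  "bladder_toy", "vagus_toy")) {
  name <- match.arg(name)
  if (name %in% c("prostate", "femrep", "salivary")) {
    path <- system.file("extdata", paste0(name, ".ttl"), package = "sckanr")
    if (!nzchar(path)) stop("bundled fixture not found: ", name)
    return(kg_from_owl(path))
  }
  switch(name,
         bladder_toy = fixture_bladder_toy(),
         vagus_toy = fixture_vagus_toy())
}

# Base anatomical classes shared by fixtures and the generator.
base_entities <- function() {
  list(
    anatomical_entity("UBERON:0001021", "nerve"),
    anatomical_entity("UBERON:0001816", "nerve plexus",
                      subclass_of = "UBERON:0001021"),
    anatomical_entity("UBERON:0006134", "nerve fiber"),
    anatomical_entity("UBERON:0000045", "ganglion")
  )
}

TAXON_LABELS <- c("NCBITaxon:9615" = "Canis familiaris",
                  "NCBITaxon:10116" = "Rattus norvegicus",
                  "NCBITaxon:9606" = "Homo sapiens",
                  "NCBITaxon:10090" = "Mus musculus")

# In-code constructors for the three Turtle-shipped fixtures; used to
# (re)generate inst/extdata and exercised by the round-trip tests.
fixture_prostate <- function() {
  ents <- c(base_entities(), list(
    anatomical_entity("UBERON:0006450", "L2 segment of lumbar spinal cord"),
    anatomical_entity("UBERON:0006449", "L3 segment of lumbar spinal cord"),
    anatomical_entity("UBERON:0006451", "L4 segment of lumbar spinal cord"),
    anatomical_entity("UBERON:0006447", "L5 segment of lumbar spinal cord"),
    anatomical_entity("UBERON:0018683", "lumbar splanchnic nerve",
                      subclass_of = "UBERON:0001021"),
    anatomical_entity("UBERON:0005453", "inferior mesenteric ganglion",
                      subclass_of = "UBERON:0000045"),
    anatomical_entity("UBERON:0002367", "prostate gland")
  ))
  lsn <- "UBERON:0018683"; img <- "UBERON:0005453"
  p24 <- neuron_population(
    id = "prostate:24",
    label = "neuron type prostate 24",
    pref_label = paste("L2-L5 spinal cord to inferior mesenteric ganglion",
                       "via lumbar splanchic nerve"),
    locations = list(
      soma = c("UBERON:0006450", "UBERON:0006449", "UBERON:0006451",
               "UBERON:0006447"),
      axon = lsn,
      axon_terminal = img),
    path = po_tree("blank",
      po_tree("UBERON:0006447", po_tree(lsn, po_tree(img))),
      po_tree("UBERON:0006450", po_tree(lsn)),
      po_tree("UBERON:0006449", po_tree(lsn)),
      po_tree("UBERON:0006451", po_tree(lsn))),
    ans = ans_phenotype("sympathetic", "pre_ganglionic"),
    species = "NCBITaxon:9615", sex = "male",
    forward_connections = "prostate:25",
    prov = provenance(citations = "PMID:10473279", source_kind = "literature")
  )
  # forward-connection stub: identity only, no locations yet
  p25 <- neuron_population(
    id = "prostate:25",
    label = "neuron type prostate 25",
    pref_label = "neuron type prostate 25",
    prov = provenance(source_kind = "literature")
  )
  g <- kg_new(entities = ents, populations = list(p24, p25), dialect = "owl")
  g$labels <- TAXON_LABELS["NCBITaxon:9615"]
  g
}

fixture_femrep <- function() {
  chain <- c("ILX:0793005", "ILX:0793006", "ILX:0793007")
  plexus <- "ILX:0793008"
  ents <- c(base_entities(), list(
    anatomical_entity("ILX:0793001", "T9 segment of thoracic spinal cord"),
    anatomical_entity("ILX:0793002", "T10 segment of thoracic spinal cord"),
    anatomical_entity("ILX:0793003", "white ramus communicans of T9",
                      subclass_of = "UBERON:0001021"),
    anatomical_entity("ILX:0793004", "white ramus communicans of T10",
                      subclass_of = "UBERON:0001021"),
    anatomical_entity("ILX:0793005",
                      "T12 paravertebral sympathetic chain ganglion",
                      subclass_of = "UBERON:0000045"),
    anatomical_entity("ILX:0793006",
                      "T13 paravertebral sympathetic chain ganglion",
                      subclass_of = "UBERON:0000045"),
    anatomical_entity("ILX:0793007",
                      "L1 paravertebral sympathetic chain ganglion",
                      subclass_of = "UBERON:0000045"),
    anatomical_entity("ILX:0793008", "ovarian nerve plexus",
                      subclass_of = "UBERON:0001816",
                      supplies_to = "UBERON:0000992"),
    anatomical_entity("UBERON:0000992", "ovary"),
    anatomical_entity("UBERON:0002119", "left ovary",
                      part_of = "UBERON:0000992"),
    anatomical_entity("UBERON:0002118", "right ovary",
                      part_of = "UBERON:0000992")
  ))
  chain_subtrees <- function(first_child) {
    lapply(chain, function(cg) po_tree(cg))
  }
  f36 <- neuron_population(
    id = "femrep:36",
    label = "neuron type femrep 36",
    pref_label = paste("T9-T10 spinal cord to T12-L1 paravertebral",
                       "sympathetic chain via white communicating rami of",
                       "T9-10"),
    locations = list(
      soma = c("ILX:0793001", "ILX:0793002"),
      axon = c("ILX:0793003", "ILX:0793004"),
      axon_terminal = chain),
    path = po_tree("blank",
      po_tree("ILX:0793001",
              do.call(po_tree, c(list("ILX:0793003"), chain_subtrees()))),
      po_tree("ILX:0793002",
              do.call(po_tree, c(list("ILX:0793004"), chain_subtrees())))),
    ans = ans_phenotype("sympathetic", "pre_ganglionic"),
    species = "NCBITaxon:10116", sex = "female",
    forward_connections = c("femrep:37", "femrep:40-1"),
    prov = provenance(citations = "PMID:10861526",
                      source_kind = "literature")
  )
  post <- function(id, n, ovary_side) {
    neuron_population(
      id = id, label = paste("neuron type femrep", n),
      pref_label = paste("T12-L1 paravertebral sympathetic chain to",
                         entity_label_raw(ents, ovary_side),
                         "via ovarian nerve plexus"),
      locations = list(soma = chain, axon = plexus,
                       axon_terminal = ovary_side),
      path = do.call(po_tree, c(list("blank"), lapply(chain, function(cg) {
        if (cg == chain[1L]) {
          po_tree(cg, po_tree(plexus, po_tree(ovary_side)))
        } else {
          po_tree(cg, po_tree(plexus))
        }
      }))),
      ans = ans_phenotype("sympathetic", "post_ganglionic"),
      species = "NCBITaxon:10116", sex = "female",
      prov = provenance(citations = "PMID:10861526",
                        source_kind = "literature")
    )
  }
  g <- kg_new(entities = ents,
              populations = list(f36,
                                 post("femrep:37", 37, "UBERON:0002119"),
                                 post("femrep:40-1", "40-1", "UBERON:0002118")),
              dialect = "owl")
  g$labels <- TAXON_LABELS["NCBITaxon:10116"]
  g
}

entity_label_raw <- function(ents, curie) {
  for (e in ents) if (e$curie == curie) return(e$label)
  curie
}

fixture_salivary <- function() {
  ents <- c(base_entities(), list(
    anatomical_entity("ILX:0793101", "superior salivatory nucleus"),
    anatomical_entity("UBERON:0001647", "facial nerve",
                      subclass_of = "UBERON:0001021"),
    anatomical_entity("ILX:0793102", "greater petrosal nerve",
                      subclass_of = "UBERON:0001021",
                      part_of = "UBERON:0001647"),
    anatomical_entity("ILX:0793103", "vidian nerve",
                      synonyms = "nerve of pterygoid canal",
                      subclass_of = "UBERON:0001021"),
    anatomical_entity("ILX:0793104", "pterygopalatine ganglion",
                      subclass_of = "UBERON:0000045")
  ))
  pop <- neuron_population(
    id = "salivary:1",
    label = "neuron type salivary 1",
    pref_label = paste("superior salivatory nucleus to pterygopalatine",
                       "ganglion via facial nerve, greater petrosal nerve",
                       "and vidian nerve"),
    locations = list(
      soma = "ILX:0793101",
      axon = c("UBERON:0001647", "ILX:0793102", "ILX:0793103"),
      axon_terminal = "ILX:0793104"),
    path = po_tree("blank",
      po_tree("ILX:0793101",
        po_tree("UBERON:0001647",
          po_tree("ILX:0793102",
            po_tree("ILX:0793103",
              po_tree("ILX:0793104")))))),
    ans = ans_phenotype("parasympathetic", "pre_ganglionic"),
    prov = provenance(source_kind = "expert_model")
  )
  kg_new(entities = ents, populations = list(pop), dialect = "owl")
}

fixture_bladder_toy <- function() {
  ents <- c(base_entities(), list(
    anatomical_entity("UBERON:0001255", "urinary bladder"),
    anatomical_entity("UBERON:0001258", "neck of urinary bladder",
                      part_of = "UBERON:0001255"),
    anatomical_entity("ILX:0793201", "dome of urinary bladder",
                      part_of = "UBERON:0001255"),
    anatomical_entity("ILX:0793202", "bladder nerve",
                      subclass_of = "UBERON:0001021"),
    anatomical_entity("UBERON:0018675", "pelvic splanchnic nerve",
                      subclass_of = "UBERON:0001021"),
    anatomical_entity("UBERON:0005303", "hypogastric nerve",
                      subclass_of = "UBERON:0001021"),
    anatomical_entity("ILX:0793206", "pudendal nerve",
                      subclass_of = "UBERON:0001021"),
    anatomical_entity("ILX:0793203", "S1 spinal cord segment"),
    anatomical_entity("ILX:0793204", "L6 spinal cord segment"),
    anatomical_entity("ILX:0793205", "major pelvic ganglion",
                      subclass_of = "UBERON:0000045"),
    anatomical_entity("UBERON:0000057", "urethra"),
    anatomical_entity("ILX:0793207", "pelvic urethra",
                      part_of = "UBERON:0000057")
  ))
  mk <- function(i, soma, via, term) {
    neuron_population(
      id = paste0("synkb:bladder-", i),
      label = paste("toy bladder population", i),
      locations = list(soma = soma, axon = via, axon_terminal = term),
      path = po_tree("blank", po_tree(soma[1L],
                                      po_tree(via, po_tree(term)))),
      ans = ans_phenotype("parasympathetic", "post_ganglionic"),
      prov = provenance(source_kind = "expert_model"))
  }
  bladder_parts <- c("UBERON:0001258", "ILX:0793201")
  vias <- c("ILX:0793202", "UBERON:0018675", "UBERON:0005303")
  somata <- c("ILX:0793203", "ILX:0793204", "ILX:0793205")
  pops <- lapply(1:6, function(i) {
    mk(i, somata[(i - 1L) %% 3L + 1L], vias[(i - 1L) %% 3L + 1L],
       bladder_parts[(i - 1L) %% 2L + 1L])
  })
  distract <- lapply(7:10, function(i) {
    neuron_population(
      id = paste0("synkb:urethra-", i),
      label = paste("toy urethra population", i),
      locations = list(soma = somata[(i - 1L) %% 3L + 1L],
                       axon = "ILX:0793206",
                       axon_terminal = "ILX:0793207"),
      path = po_tree("blank", po_tree(somata[(i - 1L) %% 3L + 1L],
        po_tree("ILX:0793206", po_tree("ILX:0793207")))),
      ans = ans_phenotype("sympathetic", "post_ganglionic"),
      prov = provenance(source_kind = "expert_model"))
  })
  kg_new(entities = ents, populations = c(pops, distract), dialect = "owl")
}

fixture_vagus_toy <- function() {
  ents <- c(base_entities(), list(
    anatomical_entity("UBERON:0001759", "vagus nerve",
                      subclass_of = "UBERON:0001021"),
    anatomical_entity("ILX:0793301", "superior laryngeal nerve",
                      subclass_of = "UBERON:0001021",
                      part_of = "UBERON:0001759"),
    anatomical_entity("ILX:0793302", "inferior vagus X ganglion",
                      synonyms = "nodose ganglion",
                      subclass_of = "UBERON:0000045"),
    anatomical_entity("UBERON:0018675", "pelvic splanchnic nerve",
                      subclass_of = "UBERON:0001021"),
    anatomical_entity("UBERON:0001043", "esophagus"),
    anatomical_entity("UBERON:0000948", "heart"),
    anatomical_entity("UBERON:0001255", "urinary bladder"),
    anatomical_entity("ILX:0793304", "dorsal motor nucleus of vagus nerve"),
    anatomical_entity("ILX:0793204", "L6 spinal cord segment")
  ))
  pops <- list(
    neuron_population(
      id = "synkb:vagus-1", label = "toy nodose sensory population",
      locations = list(soma = "ILX:0793302", axon = "UBERON:0001759",
                       sensory_terminal = "UBERON:0001043"),
      path = po_tree("blank", po_tree("ILX:0793302",
        po_tree("UBERON:0001759", po_tree("UBERON:0001043")))),
      circuit_role = "sensory",
      prov = provenance(source_kind = "literature")),
    neuron_population(
      id = "synkb:vagus-2", label = "toy laryngeal motor population",
      locations = list(soma = "ILX:0793304", axon = "ILX:0793301",
                       axon_terminal = "UBERON:0000948"),
      path = po_tree("blank", po_tree("ILX:0793304",
        po_tree("ILX:0793301", po_tree("UBERON:0000948")))),
      ans = ans_phenotype("parasympathetic", "pre_ganglionic"),
      prov = provenance(source_kind = "literature")),
    neuron_population(
      id = "synkb:pelvic-1", label = "toy pelvic population",
      locations = list(soma = "ILX:0793204", axon = "UBERON:0018675",
                       axon_terminal = "UBERON:0001255"),
      path = po_tree("blank", po_tree("ILX:0793204",
        po_tree("UBERON:0018675", po_tree("UBERON:0001255")))),
      ans = ans_phenotype("parasympathetic", "pre_ganglionic"),
      prov = provenance(source_kind = "literature"))
  )
  kg_new(entities = ents, populations = pops, dialect = "owl")
}
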