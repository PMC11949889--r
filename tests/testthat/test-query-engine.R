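test_that("end-organ query recovers exactly the planted bladder populations", {
  g <- load_fixture("bladder_toy")
  rows <- connections_terminating_in(g, "urinary bladder")
  expect_setequal(unique(rows$population), paste0("synkb:bladder-", 1:6))
  # partonomy scoping: a population ending in the bladder neck counts
  expect_true("UBERON:0001258" %in% rows$destination)
  # via locations are all nerve-like
  expect_true(all(vapply(unique(rows$via), is_nerve_like, logical(1),
                         graph = g)))
  # no incident populations -> empty result, not an error
  expect_equal(nrow(connections_terminating_in(g, "nerve fiber")), 0L)
  expect_error(connections_terminating_in(g, "no such organ"),
               "cannot resolve")
})

test_that("relaxing the nerve-via requirement only adds rows", {
  g <- load_fixture("bladder_toy")
  strict <- connections_terminating_in(g, "urinary bladder", TRUE)
  loose <- connections_terminating_in(g, "urinary bladder", FALSE)
  key <- function(df) do.call(paste, df[c("population", "origin",
                                          "destination", "via")])
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("nerve routing includes branches and excludes other nerves", {
  g <- load_fixture("vagus_toy")
  rows <- connections_via(g, "vagus nerve")
  expect_true("synkb:vagus-2" %in% rows$population)  # via superior laryngeal
  expect_true("synkb:vagus-1" %in% rows$population)  # via the trunk itself
  expect_false("synkb:pelvic-1" %in% rows$population)
  # sensory terminals count as destinations
  expect_true("UBERON:0001043" %in%
                rows$destination[rows$population == "synkb:vagus-1"])
})

test_that("perturbation of the worked-example ganglion affects 5 structures", {
  g <- load_fixture("prostate")
  aff <- affected_by_perturbation(g, "inferior mesenteric ganglion")
  expect_equal(nrow(aff), 5L)
  expect_setequal(aff$curie, c("UBERON:0006450", "UBERON:0006449",
                               "UBERON:0006451", "UBERON:0006447",
                               "UBERON:0018683"))
  # a structure no population touches
  expect_equal(nrow(affected_by_perturbation(g, "prostate gland")), 0L)
})

test_that("perturbation unions across populations sharing the structure", {
  shared <- "ILX:0700010"
  g <- kg_new(
    entities = lapply(sprintf("ILX:07000%02d", 10:14), function(cu)
      anatomical_entity(cu, paste("structure", cu))),
    populations = list(
      neuron_population("synkb:a", locations = list(
        soma = "ILX:0700011", axon_terminal = shared)),
      neuron_population("synkb:b", locations = list(
        soma = shared, axon = "ILX:0700012",
        axon_terminal = "ILX:0700013"))))
  aff <- affected_by_perturbation(g, paste("structure", shared))
  expect_setequal(aff$curie,
                  c("ILX:0700011", "ILX:0700012", "ILX:0700013"))
})

test_that("perturbation impact is symmetric", {
  set.seed(801)
  gl <- generate_graph(generator_config(seed = 801, n_populations = 10,
                                        n_entities = 40))
  g <- gl$graph
  locs <- unique(unlist(lapply(g$populations,
                               sckanr:::pop_all_locations)))
  for (a in sample(locs, min(6L, length(locs)))) {
    for (b in affected_by_perturbation(g, g$entities[[a]]$label)$curie) {
      back <- affected_by_perturbation(g, g$entities[[b]]$label)$curie
      expect_true(a %in% back)
    }
  }
})

test_that("the ovarian circuit returns 1 pre, 2 post, 3 synapse locations", {
  g <- load_fixture("femrep")
  rows <- innervation_circuit(g, "ovary", "Sympathetic Post-Ganglionic phenotype")
  expect_setequal(unique(rows$population),
                  c("femrep:36", "femrep:37", "femrep:40-1"))
  syn <- unique(rows$v2[rows$is_synapse])
  expect_setequal(syn, c("ILX:0793005", "ILX:0793006", "ILX:0793007"))
  # synapses sit only on preganglionic terminals that are also somata of
  # the forward-connected postganglionic populations
  expect_true(all(rows$population[rows$is_synapse] == "femrep:36"))
  expect_true(all(rows$v2_role[rows$is_synapse] == "axon_terminal"))
  # the phenotype token form is accepted too
  rows2 <- innervation_circuit(g, "ovary",
                               ans_phenotype("sympathetic", "post_ganglionic"))
  expect_equal(rows, rows2)
  expect_error(innervation_circuit(g, "ovary", "Adrenergic phenotype"),
               "unknown ANS phenotype")
})

test_that("a population with no inbound forward connection has no synapse flags", {
  g <- load_fixture("bladder_toy")
  rows <- innervation_circuit(g, "urethra",
                              "Sympathetic Post-Ganglionic phenotype")
  expect_true(nrow(rows) > 0L)
  expect_false(any(rows$is_synapse))
})

test_that("forward-connection traversal is transitive over planted tiers", {
  ents <- c(
    lapply(sprintf("ILX:07001%02d", 1:6), function(cu)
      anatomical_entity(cu, paste("tier structure", cu))),
    list(anatomical_entity("ILX:0700107", "target organ"),
         anatomical_entity("ILX:0700108", "organ part",
                           part_of = "ILX:0700107")))
  tier <- function(id, soma, term, fwd = character(), ans_stage) {
    neuron_population(
      id, locations = list(soma = soma, axon_terminal = term),
      path = po_tree("blank", po_tree(soma, po_tree(term))),
      ans = ans_phenotype("sympathetic", ans_stage),
      forward_connections = fwd)
  }
  g <- kg_new(entities = ents, populations = list(
    tier("synkb:t1", "ILX:0700101", "ILX:0700102", "synkb:t2",
         "pre_ganglionic"),
    tier("synkb:t2", "ILX:0700102", "ILX:0700103", "synkb:t3",
         "pre_ganglionic"),
    tier("synkb:t3", "ILX:0700103", "ILX:0700108", ans_stage = "post_ganglionic")))
  rows <- innervation_circuit(g, "target organ",
                              "Sympathetic Post-Ganglionic phenotype")
  expect_setequal(unique(rows$population), c("synkb:t1", "synkb:t2", "synkb:t3"))
  expect_setequal(unique(rows$v2[rows$is_synapse]),
                  c("ILX:0700102", "ILX:0700103"))
})

test_that("supplies-to closure scopes the end organ when partonomy does not", {
  g <- load_fixture("femrep")
  # replace the ovaries' part-of edges with supplies-to edges: the circuit
  # must still be found (CQ4 scopes via part-of OR supplies-to) ...
  for (cu in c("UBERON:0002119", "UBERON:0002118")) {
    e <- g$entities[[cu]]
    g <- kg_add_entity(g, anatomical_entity(cu, e$label,
                                            supplies_to = "UBERON:0000992"))
  }
  rows <- innervation_circuit(g, "ovary", "Sympathetic Post-Ganglionic phenotype")
  expect_setequal(unique(rows$population),
                  c("femrep:36", "femrep:37", "femrep:40-1"))
  # ... but the plain end-organ query (part-of only) no longer matches
  expect_equal(nrow(connections_terminating_in(g, "ovary")), 0L)
})

test_that("queries agree between materialized and directly loaded dialects", {
  for (nm in c("prostate", "femrep", "bladder_toy")) {
    g <- load_fixture(nm)
    s_direct <- read_simple_ttl(write_simple_ttl(to_simple_graph(g)))
    probes <- list(
      function(x) connections_terminating_in(x, "urinary bladder"),
      function(x) affected_by_perturbation(x, "inferior mesenteric ganglion"),
      function(x) innervation_circuit(x, "ovary",
                                      "Sympathetic Post-Ganglionic phenotype"))
    labs <- vapply(g$entities, `[[`, character(1), "label")
    for (probe in probes) {
      a <- tryCatch(probe(g), error = function(e) e$message)
      b <- tryCatch(probe(s_direct), error = function(e) e$message)
      expect_equal(a, b)
    }
  }
})

test_that("sex filtering is closed-world, species filtering open-world", {
  set.seed(802)
  for (seed in c(810, 811)) {
    gl <- generate_graph(generator_config(seed = seed))
    g <- gl$graph
    males <- filter_populations(g, sex = "male")
    females <- filter_populations(g, sex = "female")
    for (p in g$populations) {
      if (identical(p$sex, "female")) {
        expect_false(p$id %in% names(males))
        expect_true(p$id %in% names(females))
      } else if (identical(p$sex, "male")) {
        expect_false(p$id %in% names(females))
      } else {
        # no sex axiom: present in both sexes
        expect_true(p$id %in% names(males) && p$id %in% names(females))
      }
      if (length(p$species) == 0L) {
        expect_true(p$id %in% names(filter_populations(g, species = "unassigned")))
        expect_false(p$id %in%
                       names(filter_populations(g, species = "NCBITaxon:10116")))
      } else {
        expect_false(p$id %in% names(filter_populations(g, species = "unassigned")))
      }
    }
    # label-based species lookup matches CURIE-based
    expect_equal(names(filter_populations(g, species = "Rattus norvegicus")),
                 names(filter_populations(g, species = "NCBITaxon:10116")))
  }
})

test_that("the phenotype summary counts what the populations assert", {
  g <- load_fixture("prostate")
  tab <- phenotype_summary(g)
  exact <- tab[tab$dimension == "ANS phenotype (exact)", ]
  expect_equal(exact$count[exact$value == "Sympathetic Pre-Ganglionic phenotype"], 1L)
  expect_equal(tab$count[tab$dimension == "ANS phenotype" &
                           tab$value == "Sympathetic"], 1L)
  expect_equal(tab$count[tab$dimension == "Sex" & tab$value == "Male"], 1L)
  expect_equal(tab$count[tab$dimension == "Species" &
                           tab$value == "Canis familiaris"], 1L)
  # the location-less stub counts nowhere in locational phenotypes
  expect_equal(tab$count[tab$dimension == "Locational phenotype" &
                           tab$value == "Soma location"], 1L)

  empty <- phenotype_summary(kg_new())
  expect_true(all(empty$count == 0L))
})

test_that("summary fractions track the generator configuration", {
  cfg <- generator_config(n_populations = 200, n_entities = 150,
                          sex_fractions = c(female = 0.3, male = 0),
                          n_circuits = 0, seed = 803)
  gl <- generate_graph(cfg)
  tab <- phenotype_summary(gl$graph)
  fem <- tab$count[tab$dimension == "Sex" & tab$value == "Female"]
  # binomial sampling error around 60 of 200
  expect_true(abs(fem - 60) < 4 * sqrt(200 * 0.3 * 0.7))
  expect_equal(tab$count[tab$dimension == "Sex" & tab$value == "Male"], 0L)

  none <- generate_graph(generator_config(sex_fractions = c(female = 0,
                                                            male = 0),
                                          seed = 804))
  t2 <- phenotype_summary(none$graph)
  expect_true(all(t2$count[t2$dimension == "Sex"] == 0L))
})
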