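test_that("adjacency derivation matches the hand enumeration", {
  g <- load_fixture("prostate")
  adj <- partial_order_to_adjacency(g$populations[["prostate:24"]]$path,
                                    "prostate:24")
  lsn <- "UBERON:0018683"; img <- "UBERON:0005453"
  want <- data.frame(
    from = c("UBERON:0006447", lsn, "UBERON:0006450", "UBERON:0006449",
             "UBERON:0006451"),
    to = c(lsn, img, lsn, lsn, lsn),
    population = "prostate:24", stringsAsFactors = FALSE)
  rownames(adj) <- NULL
  expect_equal(adj, want)
  expect_equal(nrow(adj), 5L)
})

test_that("degenerate trees give the expected edge lists", {
  chain <- po_tree("blank", po_tree("ILX:0700001",
    po_tree("ILX:0700002", po_tree("ILX:0700003"))))
  adj <- partial_order_to_adjacency(chain, "synkb:p")
  expect_equal(adj$from, c("ILX:0700001", "ILX:0700002"))
  expect_equal(adj$to, c("ILX:0700002", "ILX:0700003"))

  single <- po_tree("blank", po_tree("ILX:0700001"))
  expect_equal(nrow(partial_order_to_adjacency(single, "synkb:p")), 0L)
  expect_equal(nrow(partial_order_to_adjacency(NULL, "synkb:p")), 0L)
})

test_that("shortcut materialization emits the documented triples", {
  g <- load_fixture("prostate")
  s <- to_simple_graph(g)
  tt <- s$triples
  p24 <- tt[tt$s == "prostate:24", ]
  expect_equal(sum(p24$p == "ilxtr:hasSomaLocation"), 4L)
  expect_equal(sum(p24$p == "ilxtr:hasAxonLocation"), 1L)
  expect_equal(sum(p24$p == "ilxtr:hasAxonTerminalLocation"), 1L)
  expect_equal(sum(p24$p == "ilxtr:hasForwardConnection"), 1L)
  expect_equal(sum(p24$p == "ilxtr:hasConnectedLocation"), 6L)
  # closed-world sex: the negated sex is materialized explicitly
  expect_equal(p24$o[p24$p == "ilxtr:hasBiologicalSex"], "PATO:0000384")
  expect_equal(p24$o[p24$p == "ilxtr:excludedBiologicalSex"], "PATO:0000383")
  expect_equal(p24$o[p24$p == "ilxtr:hasNeuronalPhenotype"],
               "ilxtr:SympatheticPreGanglionicPhenotype")
  # base marker becomes a plain subclass triple
  expect_equal(p24$o[p24$p == "rdfs:subClassOf"], "ilxtr:NeuronSparcNlp")
})

test_that("materialization is idempotent and flags path-less populations", {
  g <- load_fixture("prostate")
  s1 <- to_simple_graph(g)
  s2 <- to_simple_graph(s1)
  expect_equal(s1$triples, s2$triples)
  expect_equal(s1$adjacency, s2$adjacency)
  expect_equal(attr(s1, "no_partial_order"), "prostate:25")

  empty <- to_simple_graph(kg_new())
  expect_equal(nrow(empty$triples), 0L)
  expect_equal(nrow(empty$adjacency), 0L)
})

test_that("adjacency endpoints always come from the owning population's tree", {
  set.seed(601)
  for (rep in 1:5) {
    gl <- generate_graph(generator_config(seed = 600 + rep))
    s <- to_simple_graph(gl$graph)
    for (id in unique(s$adjacency$population)) {
      nodes <- tree_nodes(s$populations[[id]]$path)
      e <- s$adjacency[s$adjacency$population == id, ]
      expect_true(all(c(e$from, e$to) %in% nodes))
    }
  }
})

test_that("axiom-pattern and shortcut-pattern queries agree", {
  # the same origin/destination listing must come out of the nested OWL
  # pattern and the flat shortcut pattern
  for (rep in 1:10) {
    gl <- generate_graph(generator_config(seed = 700 + rep,
                                          n_populations = 12,
                                          n_entities = 40))
    g <- gl$graph
    txt <- write_ttl(unname(g$populations), unname(g$entities),
                     labels = g$labels)
    expect_equal(owl_origin_dest_pairs(txt),
                 simple_origin_dest_pairs(to_simple_graph(g)))
  }
})

test_that("the simple dialect round-trips through Turtle", {
  g <- load_fixture("femrep")
  s <- to_simple_graph(g)
  r <- read_simple_ttl(write_simple_ttl(s))
  expect_equal(r$populations, lapply(s$populations, null_path))
  a1 <- s$adjacency[order(s$adjacency$population, s$adjacency$from,
                          s$adjacency$to), ]
  a2 <- r$adjacency[order(r$adjacency$population, r$adjacency$from,
                          r$adjacency$to), ]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
  expect_equal(r$entities, s$entities)
})
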