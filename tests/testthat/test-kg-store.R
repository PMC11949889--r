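chain_graph <- function() {
  kg_new(entities = list(
    anatomical_entity("ILX:0700001", "a", part_of = "ILX:0700002"),
    anatomical_entity("ILX:0700002", "b", part_of = "ILX:0700003"),
    anatomical_entity("ILX:0700003", "c")))
}

test_that("ancestors is the reflexive-transitive closure", {
  g <- chain_graph()
  expect_equal(kg_ancestors(g, "ILX:0700001", "part_of"),
               sort(c("ILX:0700001", "ILX:0700002", "ILX:0700003")))
  # zero-length path: start always included
  expect_true("ILX:0700003" %in% kg_ancestors(g, "ILX:0700003", "part_of"))
  expect_error(kg_ancestors(g, "ILX:0700001", "touches"), "unknown relation")
})

test_that("partonomy scoping finds the bladder from its neck", {
  g <- load_fixture("bladder_toy")
  anc <- kg_ancestors(g, "UBERON:0001258", "part_of")
  expect_true("UBERON:0001255" %in% anc)
})

test_that("closure agrees with a brute-force oracle on random graphs", {
  set.seed(401)
  for (rep in 1:8) {
    n <- sample(20:200, 1L)
    pool <- mint_pool(n)
    ents <- lapply(seq_len(n), function(i) {
      # forward edges only (to higher indices): guaranteed acyclic
      parents <- if (i < n) {
        sample(pool[(i + 1L):n], min(n - i, sample.int(3L, 1L) - 1L))
      } else character()
      k <- length(parents)
      anatomical_entity(pool[i], paste("node", i),
                        part_of = if (k) parents[seq_len(ceiling(k / 2))]
                                  else character(),
                        subclass_of = if (k > 1) parents[(ceiling(k / 2) + 1):k]
                                      else character())
    })
    g <- kg_new(entities = ents)
    for (start in sample(pool, 5L)) {
      for (rels in list("part_of", "subclass_of",
                        c("part_of", "subclass_of"))) {
        expect_equal(kg_ancestors(g, start, rels),
                     bfs_ancestors_oracle(g, start, rels))
      }
    }
  }
})

test_that("adding edges never shrinks a closure", {
  set.seed(402)
  pool <- mint_pool(30)
  ents <- lapply(seq_len(30), function(i) {
    parent <- if (i < 30 && runif(1) < 0.5) pool[i + 1L] else character()
    anatomical_entity(pool[i], paste("node", i), part_of = parent)
  })
  g <- kg_new(entities = ents)
  before <- lapply(pool, function(s) kg_ancestors(g, s, "part_of"))
  # add one more edge from a leaf-ish node to a random target
  e <- g$entities[[pool[5]]]
  g2 <- kg_add_entity(g, anatomical_entity(
    e$curie, e$label, part_of = union(e$part_of, pool[25])))
  after <- lapply(pool, function(s) kg_ancestors(g2, s, "part_of"))
  for (k in seq_along(pool)) {
    expect_true(all(before[[k]] %in% after[[k]]))
  }
})

test_that("closure terminates on cyclic (corrupt) edge sets", {
  g <- kg_new(entities = list(
    anatomical_entity("ILX:0700001", "a", part_of = "ILX:0700002"),
    anatomical_entity("ILX:0700002", "b", part_of = "ILX:0700001")))
  expect_setequal(kg_ancestors(g, "ILX:0700001", "part_of"),
                  c("ILX:0700001", "ILX:0700002"))
})

test_that("labels and synonyms resolve case-insensitively and exactly", {
  g <- load_fixture("vagus_toy")
  cu <- resolve_label(g, "inferior vagus X ganglion")
  expect_equal(resolve_label(g, "nodose ganglion"), cu)
  expect_equal(resolve_label(g, "NODOSE GANGLION"), cu)
  expect_equal(resolve_label(g, "VaGuS NeRvE"),
               resolve_label(g, "vagus nerve"))
  expect_equal(resolve_label(g, "no-such-structure"), character())
  # exact equality, not substring matching
  expect_equal(resolve_label(g, "vagus"), character())
})

test_that("nerve-likeness follows the subclass closure", {
  g <- load_fixture("prostate")
  expect_true(is_nerve_like(g, "UBERON:0018683"))   # lumbar splanchnic nerve
  expect_false(is_nerve_like(g, "UBERON:0005453"))  # inferior mesenteric ganglion
  f <- load_fixture("femrep")
  expect_true(is_nerve_like(f, "ILX:0793008"))      # ovarian nerve plexus
  expect_error(is_nerve_like(g, "ILX:0999999"), "unknown CURIE")
})

test_that("unresolved location CURIEs are surfaced", {
  g <- load_fixture("prostate")
  expect_equal(kg_unresolved(g), character())
  p <- neuron_population(
    id = "synkb:u1",
    locations = list(soma = "ILX:0799997", axon_terminal = "UBERON:0005453"))
  g2 <- kg_add_population(g, p)
  expect_equal(kg_unresolved(g2), "ILX:0799997")
})
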