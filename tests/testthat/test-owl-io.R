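test_that("the worked axiom example serializes with the expected restrictions", {
  g <- load_fixture("prostate")
  txt <- write_ttl(unname(g$populations), unname(g$entities),
                   labels = g$labels)
  expect_equal(lengths(regmatches(txt, gregexpr("ilxtr:hasSomaLocatedIn", txt))), 4L)
  expect_equal(lengths(regmatches(txt, gregexpr("ilxtr:hasAxonLocatedIn", txt))), 1L)
  expect_equal(lengths(regmatches(txt, gregexpr("ilxtr:hasAxonPresynapticElementIn", txt))), 1L)
  expect_equal(lengths(regmatches(txt, gregexpr("ilxtr:hasForwardConnectionPhenotype", txt))), 1L)
  # male-specific: male restriction plus the female complement
  expect_match(txt, "owl:someValuesFrom PATO:0000384")
  expect_match(txt, "owl:complementOf")
  expect_match(txt, "owl:someValuesFrom PATO:0000383")
})

test_that("every location filler sits inside exactly one nested part-of restriction", {
  g <- load_fixture("femrep")
  txt <- write_ttl(unname(g$populations), unname(g$entities))
  tt <- ttl_parse(txt)$triples
  role_props <- role_properties()$owl_property
  loc_restr <- tt$s[tt$p == "owl:onProperty" & tt$o %in% role_props]
  for (b in loc_restr) {
    filler <- tt$o[tt$s == b & tt$p == "owl:someValuesFrom"]
    expect_true(startsWith(filler, "_:"))
    expect_equal(tt$o[tt$s == filler & tt$p == "owl:onProperty"], "partOf:")
  }
  n_loc <- sum(lengths(lapply(g$populations, pop_all_locations)))
  expect_gt(length(loc_restr), 0L)
})

test_that("species-unspecified populations emit no taxon restriction", {
  g <- load_fixture("salivary")   # open world: no species assertion
  txt <- write_ttl(unname(g$populations), unname(g$entities))
  expect_false(grepl("hasInstanceInTaxon", txt))
  r <- read_ttl(txt)
  expect_equal(r$populations[["salivary:1"]]$species, character())
})

test_that("read is the inverse of write on the bundled circuits", {
  for (nm in c("prostate", "femrep", "salivary")) {
    g <- load_fixture(nm)
    txt <- write_ttl(unname(g$populations), unname(g$entities),
                     labels = g$labels)
    r <- read_ttl(txt)
    expect_equal(r$populations, g$populations)
    expect_equal(r$entities, g$entities)
  }
})

test_that("random populations survive a round trip field-for-field", {
  set.seed(501)
  pool <- mint_pool(40)
  pops <- lapply(1:25, random_population, curie_pool = pool)
  txt <- write_ttl(pops)
  r <- read_ttl(txt)
  byid <- stats::setNames(pops, vapply(pops, `[[`, character(1), "id"))
  expect_equal(r$populations, byid[sort(names(byid))])
})

test_that("the writer is byte-stable", {
  g <- load_fixture("femrep")
  t1 <- write_ttl(unname(g$populations), unname(g$entities), labels = g$labels)
  t2 <- write_ttl(unname(rev(g$populations)), unname(g$entities),
                  labels = g$labels)
  expect_identical(t1, t2)   # input order must not matter
})

test_that("dialect violations are reported, tolerated ones warned", {
  # missing base marker names the population
  doc <- c(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix ilxtr: <http://uri.interlex.org/tgbugs/uris/readable/> .",
    "@prefix synkb: <http://example.org/sckanr/synthetic/> .",
    "synkb:bad a owl:Class ;",
    "  owl:equivalentClass [ a owl:Class ; owl:intersectionOf (",
    "    [ a owl:Restriction ; owl:onProperty ilxtr:hasSomaLocatedIn ;",
    "      owl:someValuesFrom [ a owl:Restriction ; owl:onProperty partOf: ;",
    "        owl:someValuesFrom ILX:0700001 ] ] ) ] .")
  expect_error(read_ttl(doc), "synkb:bad.*base class marker")

  # soma restriction without the nested part-of wrapper: warn, still capture
  doc2 <- c(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix ilxtr: <http://uri.interlex.org/tgbugs/uris/readable/> .",
    "@prefix synkb: <http://example.org/sckanr/synthetic/> .",
    "synkb:flat a owl:Class ;",
    "  owl:equivalentClass [ a owl:Class ; owl:intersectionOf (",
    "    ilxtr:NeuronSparcNlp",
    "    [ a owl:Restriction ; owl:onProperty ilxtr:hasSomaLocatedIn ;",
    "      owl:someValuesFrom ILX:0700001 ]",
    "    [ a owl:Restriction ; owl:onProperty ilxtr:hasAxonPresynapticElementIn ;",
    "      owl:someValuesFrom [ a owl:Restriction ; owl:onProperty partOf: ;",
    "        owl:someValuesFrom ILX:0700002 ] ] ) ] .")
  expect_warning(r <- read_ttl(doc2), "lacks the nested part-of wrapper")
  expect_equal(r$populations[["synkb:flat"]]$locations$soma, "ILX:0700001")
})

test_that("invalid populations are refused with their report", {
  bad <- neuron_population("synkb:inv",
                           locations = list(soma = "ILX:0700001"),
                           path = po_tree("blank", po_tree("ILX:0700001")))
  expect_error(write_ttl(list(bad)), "MISSING_DESTINATION|no axon terminal")
})

test_that("the partial order reads back exactly as printed", {
  g <- load_fixture("prostate")
  path <- g$populations[["prostate:24"]]$path
  expect_equal(path$node, "blank")
  expect_length(path$children, 4L)
  # first branch is L5 -> lumbar splanchnic nerve -> inferior mesenteric ganglion
  expect_equal(path$children[[1]]$node, "UBERON:0006447")
  expect_equal(path$children[[1]]$children[[1]]$node, "UBERON:0018683")
  expect_equal(path$children[[1]]$children[[1]]$children[[1]]$node,
               "UBERON:0005453")
  expect_equal(vapply(path$children[-1], `[[`, character(1), "node"),
               c("UBERON:0006450", "UBERON:0006449", "UBERON:0006451"))
})
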