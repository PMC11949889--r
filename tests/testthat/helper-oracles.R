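# Independent oracles and small builders used across the suite.

# Brute-force reflexive-transitive ancestors: repeated single-step edge
# scans until fixpoint, no indexing -- deliberately naive.
bfs_ancestors_oracle <- function(graph, start, relations) {
  edges_from <- function(cu) {
    e <- graph$entities[[cu]]
    if (is.null(e)) return(character())
    unique(unlist(e[relations], use.names = FALSE))
  }
  seen <- start
  repeat {
    nxt <- unique(unlist(lapply(seen, edges_from), use.names = FALSE))
    new <- setdiff(nxt, seen)
    if (length(new) == 0L) break
    seen <- c(seen, new)
  }
  sort(seen)
}

# Listing-3-style origin/destination extraction: pattern-match the raw OWL
# triples (equivalentClass -> intersectionOf -> restriction -> nested
# part-of filler), walking rdf:first/rdf:rest by hand. Independent of
# read_ttl.
owl_origin_dest_pairs <- function(ttl_text) {
  tt <- ttl_parse(ttl_text)$triples
  obj1 <- function(s, p) {
    o <- tt$o[tt$s == s & tt$p == p]
    if (length(o)) o[1L] else NA_character_
  }
  walk_list <- function(head) {
    items <- character()
    while (!identical(head, "rdf:nil")) {
      items <- c(items, obj1(head, "rdf:first"))
      head <- obj1(head, "rdf:rest")
    }
    items
  }
  soma_prop <- "ilxtr:hasSomaLocatedIn"
  term_props <- c("ilxtr:hasAxonPresynapticElementIn",
                  "ilxtr:hasAxonSensorySubcellularElementIn")
  res <- list()
  for (s in unique(tt$s[tt$p == "owl:equivalentClass"])) {
    if (startsWith(s, "_:")) next
    inter <- obj1(obj1(s, "owl:equivalentClass"), "owl:intersectionOf")
    if (is.na(inter)) next
    origins <- character(); dests <- character()
    for (m in walk_list(inter)) {
      if (!startsWith(m, "_:")) next
      prop <- obj1(m, "owl:onProperty")
      if (is.na(prop)) next
      filler <- obj1(m, "owl:someValuesFrom")
      if (startsWith(filler, "_:")) {
        filler <- obj1(filler, "owl:someValuesFrom")
      }
      if (prop == soma_prop) origins <- c(origins, filler)
      if (prop %in% term_props) dests <- c(dests, filler)
    }
    if (length(origins) && length(dests)) {
      res[[s]] <- expand.grid(population = s, origin = origins,
                              destination = dests,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(list(data.frame(population = character(),
                                          origin = character(),
                                          destination = character())),
                          unname(res)))
  out <- out[order(out$population, out$origin, out$destination), ]
  rownames(out) <- NULL
  attr(out, "out.attrs") <- NULL
  data.frame(out, stringsAsFactors = FALSE)
}

# Listing-4-style extraction from the flat shortcut triples.
simple_origin_dest_pairs <- function(simple_graph) {
  tt <- simple_graph$triples
  soma <- tt[tt$p == "ilxtr:hasSomaLocation", c("s", "o")]
  term <- tt[tt$p %in% c("ilxtr:hasAxonTerminalLocation",
                         "ilxtr:hasAxonSensoryLocation"), c("s", "o")]
  out <- merge(soma, term, by = "s")
  names(out) <- c("population", "origin", "destination")
  out <- unique(out[order(out$population, out$origin, out$destination), ])
  rownames(out) <- NULL
  out
}

# Seeded random population over a small minted vocabulary; always valid.
random_population <- function(i, curie_pool) {
  somata <- sample(curie_pool, sample.int(3L, 1L))
  via <- sample(setdiff(curie_pool, somata), 1L)
  terms <- sample(setdiff(curie_pool, c(somata, via)), sample.int(2L, 1L))
  path <- do.call(po_tree, c(list("blank"), lapply(seq_along(somata), function(j) {
    if (j == 1L) {
      po_tree(somata[j], do.call(po_tree, c(list(via), lapply(terms, po_tree))))
    } else po_tree(somata[j], po_tree(via))
  })))
  ans_tok <- if (runif(1) < 0.7) {
    tab <- ans_phenotypes()
    tab$token[sample.int(nrow(tab), 1L)]
  } else NULL
  neuron_population(
    id = paste0("synkb:rt-", i),
    label = paste("random population", i),
    pref_label = paste("random A-to-B-via-C statement", i),
    locations = list(soma = somata, axon = via, axon_terminal = terms),
    path = path,
    ans = ans_tok,
    circuit_role = if (runif(1) < 0.3)
      sample(c("intrinsic", "motor", "sensory", "projection"), 1L) else NULL,
    functional_role = if (runif(1) < 0.2)
      sample(c("excitatory", "inhibitory"), 1L) else NULL,
    species = if (runif(1) < 0.6)
      sample(c("NCBITaxon:10116", "NCBITaxon:9606", "NCBITaxon:10090"),
             sample.int(2L, 1L)) else character(),
    sex = if (runif(1) < 0.3) sample(c("male", "female"), 1L) else NULL,
    forward_connections = if (runif(1) < 0.4)
      paste0("synkb:rt-", i + 1L) else character(),
    prov = provenance(
      citations = if (runif(1) < 0.7) sprintf("PMID:%07d", i) else character(),
      alert_notes = if (runif(1) < 0.2) "synthetic alert note" else character(),
      source_kind = sample(c("literature", "expert_model"), 1L))
  )
}

mint_pool <- function(n, offset = 0L) sprintf("ILX:07%05d", offset + seq_len(n))

# list-element removal without dropping the slot
null_path <- function(pop) {
  pop["path"] <- list(NULL)
  pop
}
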