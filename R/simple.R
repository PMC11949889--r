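#' Derive adjacency edges from a partial-order tree
#'
#' One directed edge per parent-to-child pair in the tree, excluding the
#' `"blank"` root marker. Structures shared across branches (e.g. a nerve
#' entered from several spinal segments) are merged by CURIE, so repeated
#' pairs are deduplicated; edge order is document order.
#'
#' @param path a [po_tree()].
#' @param population CURIE of the owning population.
#' @return data.frame with columns `from`, `to`, `population`.
#' @export
#' @examples
#' p <- po_tree("blank", po_tree("A:1", po_tree("A:2", po_tree("A:3"))))
#' partial_order_to_adjacency(p, "pop:1")
partial_order_to_adjacency <- function(path, population) {
  if (is.null(path)) return(empty_adjacency())
  stopifnot(inherits(path, "po_tree"))
  froms <- character(); tos <- character()
  walk <- function(t) {
    for (ch in t$children) {
      if (!identical(t$node, "blank")) {
        froms <<- c(froms, t$node)
        tos <<- c(tos, ch$node)
      }
      walk(ch)
    }
  }
  walk(path)
  edges <- data.frame(from = froms, to = tos,
                      population = rep(population, length(froms)),
                      stringsAsFactors = FALSE)
  edges[!duplicated(edges[c("from", "to")]), , drop = FALSE]
}

# Flat shortcut triples for one population (data.frame rows).
simple_pop_triples <- function(p) {
  s <- character(); pr <- character(); o <- character(); lit <- logical()
  emit <- function(pred, obj, is_lit = FALSE) {
    s <<- c(s, p$id); pr <<- c(pr, pred); o <<- c(o, obj)
    lit <<- c(lit, is_lit)
  }
  emit("rdfs:label", p$label, TRUE)
  emit("skos:prefLabel", p$pref_label, TRUE)
  emit("rdfs:subClassOf", BASE_MARKERS[[p$prov$source_kind]])
  for (r in location_roles()) {
    for (loc in p$locations[[r]]) emit(role_to_simple(r), loc)
  }
  for (loc in pop_all_locations(p)) emit("ilxtr:hasConnectedLocation", loc)
  for (tx in p$species) emit("ilxtr:hasInstanceInTaxon", tx)
  if (!is.null(p$sex)) {
    emit("ilxtr:hasBiologicalSex", SEX_CURIES[[p$sex]])
    emit("ilxtr:excludedBiologicalSex", SEX_CURIES[[opposite_sex(p$sex)]])
  }
  if (!is.null(p$ans)) emit("ilxtr:hasNeuronalPhenotype", ans_curie(p$ans))
  if (!is.null(p$circuit_role)) {
    emit("ilxtr:hasCircuitRolePhenotype", CIRCUIT_ROLES[[p$circuit_role]])
  }
  if (!is.null(p$functional_role)) {
    emit("ilxtr:hasFunctionalCircuitRolePhenotype",
         FUNCTIONAL_ROLES[[p$functional_role]])
  }
  for (fc in p$forward_connections) emit("ilxtr:hasForwardConnection", fc)
  for (r in p$prov$citations) emit("ilxtr:reference", r, TRUE)
  for (a in p$prov$alert_notes) emit("ilxtr:alertNote", a, TRUE)
  data.frame(s = s, p = pr, o = o, o_is_literal = lit,
             stringsAsFactors = FALSE)
}

#' Materialize the simple (shortcut) dialect
#'
#' Flattens the OWL axioms of every population into shortcut triples: one
#' triple per role-location pair, per taxon, per sex (plus the documented
#' `ilxtr:excludedBiologicalSex` triple carrying the closed-world
#' negation), per phenotype, per forward connection; plus
#' `ilxtr:hasConnectedLocation` to every location of every role, and
#' adjacency edges derived from the partial orders (reified edge records,
#' queryable without RDF-star edge properties). The operation is
#' idempotent: applying it to a simple graph returns an equal graph.
#'
#' @param graph a `sckan_graph` (either dialect).
#' @return a `sckan_graph` with dialect `"simple"`, its `triples` table
#'   populated and `adjacency` materialized. Populations lacking a partial
#'   order contribute no adjacency edges; they are listed in the
#'   `no_partial_order` attribute of the result.
#' @export
to_simple_graph <- function(graph) {
  stopifnot(inherits(graph, "sckan_graph"))
  g <- graph
  g$dialect <- "simple"
  ids <- sort(names(g$populations))
  tri <- do.call(rbind, c(
    list(data.frame(s = character(), p = character(), o = character(),
                    o_is_literal = logical(), stringsAsFactors = FALSE)),
    lapply(ids, function(i) simple_pop_triples(g$populations[[i]]))
  ))
  adj <- do.call(rbind, c(
    list(empty_adjacency()),
    lapply(ids, function(i) {
      p <- g$populations[[i]]
      if (is.null(p$path)) {
        # no partial order: keep any previously materialized edges
        graph$adjacency[graph$adjacency$population == i, , drop = FALSE]
      } else {
        partial_order_to_adjacency(p$path, p$id)
      }
    })
  ))
  rownames(tri) <- NULL; rownames(adj) <- NULL
  g$triples <- tri
  g$adjacency <- adj
  no_po <- ids[vapply(ids, function(i) {
    is.null(g$populations[[i]]$path) && !i %in% adj$population
  }, logical(1))]
  attr(g, "no_partial_order") <- no_po
  g
}

#' Write a simple-dialect graph as Turtle
#'
#' Entities are written as flat label/hierarchy triples, populations as
#' shortcut triples, adjacency edges as reified blank-node records
#' (`ilxtr:PathEdge` with `ilxtr:edgeSource`, `ilxtr:edgeTarget`,
#' `ilxtr:isConnectedBy`). Phenotype classes referenced by populations get
#' `rdfs:label` triples so label-based phenotype filters work on the
#' serialized form.
#'
#' @param graph a `sckan_graph`; materialized first if still OWL dialect.
#' @return single string: a Turtle document.
#' @export
write_simple_ttl <- function(graph) {
  if (graph$dialect != "simple") graph <- to_simple_graph(graph)
  ents <- graph$entities[order(names(graph$entities))]
  used <- c("rdf", "rdfs", "owl", "skos", "ilxtr",
            vapply(ents, function(e) curie_prefix(e$curie), character(1)),
            curie_prefix(graph$triples$s),
            curie_prefix(graph$triples$o[!graph$triples$o_is_literal]),
            curie_prefix(names(graph$labels)))
  prefixes <- graph$prefixes[intersect(names(graph$prefixes), unique(used))]
  out <- c(ttl_prefix_block(prefixes), "")
  for (e in ents) out <- c(out, ttl_entity_block(e), "")
  if (length(graph$labels)) {
    for (cu in sort(names(graph$labels))) {
      out <- c(out,
               paste0(cu, " rdfs:label ", ttl_term(graph$labels[[cu]], TRUE), " ."))
    }
    out <- c(out, "")
  }
  # labels for phenotype classes used by the populations
  phen <- sort(unique(graph$triples$o[graph$triples$p %in%
                 c("ilxtr:hasNeuronalPhenotype")]))
  for (cu in phen) {
    tok <- ans_from_curie(cu)
    if (!is.na(tok)) {
      out <- c(out, paste0(cu, " rdfs:label ", ttl_term(ans_label(tok), TRUE), " ."))
    }
  }
  if (length(phen)) out <- c(out, "")
  for (id in sort(unique(graph$triples$s))) {
    rows <- graph$triples[graph$triples$s == id, , drop = FALSE]
    body <- paste0("    ", rows$p, " ",
                   mapply(ttl_term, rows$o, rows$o_is_literal))
    out <- c(out, paste0(id, " a owl:Class ;"),
             paste0(body, c(rep(" ;", length(body) - 1L), " .")), "")
  }
  if (nrow(graph$adjacency)) {
    for (k in seq_len(nrow(graph$adjacency))) {
      e <- graph$adjacency[k, ]
      out <- c(out,
               "[ a ilxtr:PathEdge ;",
               paste0("  ilxtr:edgeSource ", e$from, " ;"),
               paste0("  ilxtr:edgeTarget ", e$to, " ;"),
               paste0("  ilxtr:isConnectedBy ", e$population, " ] ."),
               "")
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Read a simple-dialect Turtle document
#'
#' Reconstructs populations (without partial-order trees, which the simple
#' dialect does not carry -- the derived adjacency edges take their
#' place), entities, labels, and adjacency edges, so competency queries
#' run identically on a directly loaded simple graph and on one
#' materialized in memory.
#'
#' @param text Turtle source (string or lines) or a file path.
#' @param prefixes fallback prefix registry.
#' @return a `sckan_graph` with dialect `"simple"`.
#' @export
read_simple_ttl <- function(text, prefixes = default_prefixes()) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  parsed <- ttl_parse(text, prefixes)
  tt <- parsed$triples

  pop_ids <- sort(unique(tt$s[tt$p == "rdfs:subClassOf" &
                                tt$o %in% BASE_MARKERS]))
  pops <- lapply(pop_ids, function(s) {
    rows <- tt[tt$s == s, , drop = FALSE]
    locations <- stats::setNames(
      lapply(location_roles(), function(r) {
        rows$o[rows$p == role_to_simple(r)]
      }), location_roles())
    sexc <- rows$o[rows$p == "ilxtr:hasBiologicalSex"]
    ansc <- rows$o[rows$p == "ilxtr:hasNeuronalPhenotype"]
    circ <- rows$o[rows$p == "ilxtr:hasCircuitRolePhenotype"]
    fun <- rows$o[rows$p == "ilxtr:hasFunctionalCircuitRolePhenotype"]
    marker <- rows$o[rows$p == "rdfs:subClassOf" & rows$o %in% BASE_MARKERS]
    lab <- rows$o[rows$p == "rdfs:label" & rows$o_is_literal]
    pref <- rows$o[rows$p == "skos:prefLabel" & rows$o_is_literal]
    neuron_population(
      id = s,
      label = if (length(lab)) lab[1L] else s,
      pref_label = if (length(pref)) pref[1L] else if (length(lab)) lab[1L] else s,
      locations = locations,
      path = NULL,
      ans = if (length(ansc)) ans_from_curie(ansc[1L]) else NULL,
      circuit_role = if (length(circ))
        names(CIRCUIT_ROLES)[match(circ[1L], CIRCUIT_ROLES)] else NULL,
      functional_role = if (length(fun))
        names(FUNCTIONAL_ROLES)[match(fun[1L], FUNCTIONAL_ROLES)] else NULL,
      species = rows$o[rows$p == "ilxtr:hasInstanceInTaxon"],
      sex = if (length(sexc)) SEX_FROM_CURIE[[sexc[1L]]] else NULL,
      forward_connections = rows$o[rows$p == "ilxtr:hasForwardConnection"],
      prov = provenance(
        citations = rows$o[rows$p == "ilxtr:reference" & rows$o_is_literal],
        alert_notes = rows$o[rows$p == "ilxtr:alertNote" & rows$o_is_literal],
        source_kind = MARKER_TO_KIND[[marker[1L]]])
    )
  })
  names(pops) <- pop_ids

  ana_subjects <- sort(unique(tt$s[is_anatomical_curie(tt$s)]))
  ents <- list()
  for (s in ana_subjects) {
    lab <- tt$o[tt$s == s & tt$p == "rdfs:label" & tt$o_is_literal]
    if (length(lab) == 0L) next
    ents[[s]] <- anatomical_entity(
      curie = s, label = lab[1L],
      synonyms = tt$o[tt$s == s & tt$p == "skos:altLabel" & tt$o_is_literal],
      part_of = tt$o[tt$s == s & tt$p %in% c("ilxtr:isPartOf", "partOf:")],
      subclass_of = {
        sc <- tt$o[tt$s == s & tt$p == "rdfs:subClassOf"]
        sc[is_anatomical_curie(sc)]
      },
      supplies_to = tt$o[tt$s == s & tt$p == "ilxtr:suppliesTo"]
    )
  }

  edge_nodes <- tt$s[tt$p == RDF_TYPE & tt$o == "ilxtr:PathEdge"]
  adj <- if (length(edge_nodes)) {
    data.frame(
      from = vapply(edge_nodes, function(b)
        tt$o[tt$s == b & tt$p == "ilxtr:edgeSource"][1L], character(1)),
      to = vapply(edge_nodes, function(b)
        tt$o[tt$s == b & tt$p == "ilxtr:edgeTarget"][1L], character(1)),
      population = vapply(edge_nodes, function(b)
        tt$o[tt$s == b & tt$p == "ilxtr:isConnectedBy"][1L], character(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  } else empty_adjacency()

  lab_rows <- tt[tt$p == "rdfs:label" & tt$o_is_literal &
                   !tt$s %in% c(pop_ids, ana_subjects) &
                   !startsWith(tt$s, "_:"), , drop = FALSE]

  g <- kg_new(entities = ents, populations = pops, dialect = "simple",
              prefixes = parsed$prefixes)
  g$labels <- if (nrow(lab_rows)) stats::setNames(lab_rows$o, lab_rows$s)
              else character()
  g$adjacency <- adj
  g$triples <- tt
  g
}
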