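#' Connectivity knowledge graphs
#'
#' A knowledge graph holds a triple table together with indexed views of
#' its content: anatomical entities (with their raw part-of / subclass /
#' supplies-to edges), neuron populations, and -- for simple-dialect
#' graphs -- the materialized adjacency edges of the partial orders.
#' Anatomical CURIEs referenced by populations but missing from the entity
#' map are tracked in an `unresolved` registry surfaced by validation.
#'
#' @param entities list of [anatomical_entity()] objects.
#' @param populations list of [neuron_population()] objects.
#' @param dialect `"owl"` (nested axiom dialect) or `"simple"` (shortcut
#'   dialect with materialized adjacency edges).
#' @param prefixes prefix registry used for serialization.
#' @return object of class `sckan_graph`.
#' @export
kg_new <- function(entities = list(), populations = list(),
                   dialect = c("owl", "simple"),
                   prefixes = default_prefixes()) {
  dialect <- match.arg(dialect)
  g <- structure(
    list(entities = list(), populations = list(),
         adjacency = empty_adjacency(), dialect = dialect,
         prefixes = prefixes,
         labels = character()),   # rdfs:labels of non-anatomical terms
    class = "sckan_graph"
  )
  for (e in entities) g <- kg_add_entity(g, e)
  for (p in populations) g <- kg_add_population(g, p)
  if (length(g$entities)) g$entities <- g$entities[order(names(g$entities))]
  if (length(g$populations)) {
    g$populations <- g$populations[order(names(g$populations))]
  }
  g
}

empty_adjacency <- function() {
  data.frame(from = character(), to = character(),
             population = character(), stringsAsFactors = FALSE)
}

#' @rdname kg_new
#' @param graph a `sckan_graph`.
#' @param entity an [anatomical_entity()].
#' @export
kg_add_entity <- function(graph, entity) {
  stopifnot(inherits(graph, "sckan_graph"), inherits(entity, "anatomical_entity"))
  graph$entities[[entity$curie]] <- entity
  graph
}

#' @rdname kg_new
#' @param pop a [neuron_population()].
#' @export
kg_add_population <- function(graph, pop) {
  stopifnot(inherits(graph, "sckan_graph"), inherits(pop, "neuron_population"))
  graph$populations[[pop$id]] <- pop
  graph
}

#' @export
print.sckan_graph <- function(x, ...) {
  cat("<sckan_graph> dialect:", x$dialect, "\n",
      " ", length(x$entities), "anatomical entities,",
      length(x$populations), "neuron populations,",
      nrow(x$adjacency), "adjacency edges\n")
  invisible(x)
}

#' Unresolved anatomical references
#'
#' @param graph a `sckan_graph`.
#' @return CURIEs referenced by population locations but absent from the
#'   entity map.
#' @export
kg_unresolved <- function(graph) {
  used <- unique(unlist(lapply(graph$populations, pop_all_locations),
                        use.names = FALSE))
  sort(setdiff(used, names(graph$entities)))
}

# Edge list (from, to) for a set of relations, from the raw entity edges.
kg_edges <- function(graph, relations) {
  known <- c("part_of", "subclass_of", "supplies_to")
  bad <- setdiff(relations, known)
  if (length(bad)) {
    stop("unknown relation(s): ", paste(bad, collapse = ", "))
  }
  froms <- character(); tos <- character()
  for (e in graph$entities) {
    for (rel in relations) {
      parents <- e[[rel]]
      if (length(parents)) {
        froms <- c(froms, rep(e$curie, length(parents)))
        tos <- c(tos, parents)
      }
    }
  }
  data.frame(from = froms, to = tos, stringsAsFactors = FALSE)
}

#' Reflexive-transitive ancestor closure
#'
#' Walks the union of the named hierarchy relations upward from `start`,
#' returning every reachable CURIE including `start` itself (zero-length
#' path, matching SPARQL `*` path semantics). The walk is guarded by a
#' visited set, so cyclic (corrupt) inputs still terminate.
#'
#' @param graph a `sckan_graph`.
#' @param start CURIE to start from.
#' @param relations subset of `c("part_of", "subclass_of", "supplies_to")`.
#' @return sorted character vector of CURIEs, always containing `start`.
#' @export
#' @examples
#' g <- kg_new(entities = list(
#'   anatomical_entity("UBERON:0001258", "neck of urinary bladder",
#'                     part_of = "UBERON:0001255"),
#'   anatomical_entity("UBERON:0001255", "urinary bladder")))
#' kg_ancestors(g, "UBERON:0001258", "part_of")
kg_ancestors <- function(graph, start, relations = c("part_of", "subclass_of")) {
  stopifnot(inherits(graph, "sckan_graph"), length(start) == 1L)
  edges <- kg_edges(graph, relations)
  parents_of <- split(edges$to, edges$from)
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(parents_of[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

#' Resolve a label or synonym to CURIEs
#'
#' Case-insensitive exact match against entity labels and synonyms
#' (lowercase-folded string equality; no stemming or fuzzy matching).
#'
#' @param graph a `sckan_graph`.
#' @param label text to match.
#' @return sorted character vector of matching CURIEs (possibly empty).
#' @export
resolve_label <- function(graph, label) {
  stopifnot(inherits(graph, "sckan_graph"), length(label) == 1L)
  needle <- tolower(label)
  hits <- vapply(graph$entities, function(e) {
    tolower(e$label) == needle || needle %in% tolower(e$synonyms)
  }, logical(1))
  sort(names(graph$entities)[hits])
}

#' Is a structure nerve-like?
#'
#' True iff the subclass closure of `curie` reaches an entity labeled
#' "nerve", "nerve plexus", or "nerve fiber" -- the constraint the
#' competency queries place on axon "via" locations.
#'
#' @param graph a `sckan_graph`.
#' @param curie CURIE of a structure known to the graph.
#' @return logical scalar.
#' @export
is_nerve_like <- function(graph, curie) {
  stopifnot(length(curie) == 1L)
  if (is.null(graph$entities[[curie]])) {
    stop("unknown CURIE: ", curie)
  }
  closure <- kg_ancestors(graph, curie, "subclass_of")
  labels <- vapply(closure, function(cu) {
    e <- graph$entities[[cu]]
    if (is.null(e)) "" else tolower(e$label)
  }, character(1))
  any(labels %in% NERVE_LIKE_LABELS)
}

entity_label <- function(graph, curie) {
  e <- graph$entities[[curie]]
  if (is.null(e)) NA_character_ else e$label
}
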