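#' Competency queries over a connectivity knowledge graph
#'
#' The four standard questions a connectivity knowledge base must answer:
#' which populations terminate in an organ (and via which nerves), which
#' travel through a named nerve or its branches, which structures a
#' perturbation of one structure might affect, and how pre- and
#' post-ganglionic populations wire an end organ, including synapse
#' locations. All queries run on the simple (shortcut) form; an
#' OWL-dialect graph is materialized transparently.
#'
#' @name competency-queries
NULL

ensure_simple <- function(graph) {
  if (graph$dialect != "simple") to_simple_graph(graph) else graph
}

resolve_or_stop <- function(graph, label, what) {
  hits <- resolve_label(graph, label)
  if (length(hits) == 0L) {
    stop("cannot resolve ", what, " label: \"", label, "\"")
  }
  hits
}

nerve_like_safe <- function(graph, curie) {
  !is.null(graph$entities[[curie]]) && is_nerve_like(graph, curie)
}

labels_of <- function(graph, curies) {
  vapply(as.character(curies), function(cu) {
    if (is.na(cu)) NA_character_ else entity_label(graph, cu)
  }, character(1), USE.NAMES = FALSE)
}

connection_row <- function(graph, pop, origin, destination, via, organ) {
  data.frame(
    population = pop,
    origin = origin, origin_label = labels_of(graph, origin),
    destination = destination,
    destination_label = labels_of(graph, destination),
    via = via, via_label = labels_of(graph, via),
    target_organ = organ,
    target_organ_label = labels_of(graph, organ),
    stringsAsFactors = FALSE)
}

sort_rows <- function(df, cols) {
  if (nrow(df) == 0L) return(df)
  df <- df[do.call(order, df[cols]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Populations terminating in an organ
#'
#' Finds every population whose axon terminal or sensory terminal lies in
#' the part-of closure of the named organ, reporting one row per (origin,
#' matching destination, via) combination. With `require_nerve_via = TRUE`
#' only axon-course locations that are nerve-like (subclass closure
#' reaching nerve / nerve plexus / nerve fiber) qualify as `via`, and
#' populations with no such location are dropped; with `FALSE` the via
#' constraint is waived (rows with no axon-course location carry `NA`).
#'
#' @param graph a `sckan_graph`.
#' @param organ_label label or synonym of the target organ.
#' @param require_nerve_via require a nerve-like via location.
#' @return data.frame of connection rows, distinct, sorted by
#'   (population, origin, destination, via).
#' @export
connections_terminating_in <- function(graph, organ_label,
                                       require_nerve_via = TRUE) {
  graph <- ensure_simple(graph)
  organ <- resolve_or_stop(graph, organ_label, "organ")
  out <- list()
  for (pop in graph$populations) {
    dests <- pop_destinations(pop)
    in_organ <- vapply(dests, function(d) {
      anc <- kg_ancestors(graph, d, "part_of")
      length(intersect(anc, organ)) > 0L
    }, logical(1))
    dests <- dests[in_organ]
    if (length(dests) == 0L) next
    vias <- pop_axon_course(pop)
    if (require_nerve_via) {
      vias <- vias[vapply(vias, nerve_like_safe, logical(1), graph = graph)]
      if (length(vias) == 0L) next
    } else if (length(vias) == 0L) {
      vias <- NA_character_
    }
    grid <- expand.grid(origin = pop$locations$soma, destination = dests,
                        via = vias, stringsAsFactors = FALSE)
    if (nrow(grid) == 0L) next
    out[[pop$id]] <- connection_row(graph, pop$id, grid$origin,
                                    grid$destination, grid$via, organ[1L])
  }
  res <- do.call(rbind, c(list(connection_row(graph, character(),
                                              character(), character(),
                                              character(), character())),
                          unname(out)))
  res <- res[!duplicated(res), , drop = FALSE]
  sort_rows(res, c("population", "origin", "destination", "via"))
}

#' Populations traveling through a nerve
#'
#' Finds populations with an axon-course location whose subclass-or-part-of
#' closure reaches the named nerve, so branches of the nerve match too.
#'
#' @param graph a `sckan_graph`.
#' @param nerve_label label or synonym of the nerve.
#' @return data.frame of connection rows (origin x destination x matching
#'   via), distinct and sorted.
#' @export
connections_via <- function(graph, nerve_label) {
  graph <- ensure_simple(graph)
  nerve <- resolve_or_stop(graph, nerve_label, "nerve")
  out <- list()
  for (pop in graph$populations) {
    vias <- pop_axon_course(pop)
    hit <- vias[vapply(vias, function(v) {
      anc <- kg_ancestors(graph, v, c("subclass_of", "part_of"))
      length(intersect(anc, nerve)) > 0L
    }, logical(1))]
    if (length(hit) == 0L) next
    dests <- pop_destinations(pop)
    grid <- expand.grid(origin = pop$locations$soma, destination = dests,
                        via = hit, stringsAsFactors = FALSE)
    if (nrow(grid) == 0L) next
    out[[pop$id]] <- connection_row(graph, pop$id, grid$origin,
                                    grid$destination, grid$via, nerve[1L])
  }
  res <- do.call(rbind, c(list(connection_row(graph, character(),
                                              character(), character(),
                                              character(), character())),
                          unname(out)))
  res <- res[!duplicated(res), , drop = FALSE]
  sort_rows(res, c("population", "origin", "destination", "via"))
}

#' Structures affected by perturbing a structure
#'
#' For every population having the named structure among its connected
#' locations (any role: dendrite, soma, axon, terminals), collects all its
#' other connected locations. The perturbed structure itself is excluded.
#'
#' @param graph a `sckan_graph`.
#' @param structure_label label or synonym of the perturbed structure.
#' @return data.frame with columns `curie`, `label`, sorted by label then
#'   CURIE.
#' @export
affected_by_perturbation <- function(graph, structure_label) {
  graph <- ensure_simple(graph)
  target <- resolve_or_stop(graph, structure_label, "structure")
  affected <- character()
  for (pop in graph$populations) {
    locs <- pop_all_locations(pop)
    if (length(intersect(locs, target)) > 0L) {
      affected <- c(affected, setdiff(locs, target))
    }
  }
  affected <- sort(unique(affected))
  res <- data.frame(
    curie = affected,
    label = vapply(affected, entity_label, character(1), graph = graph),
    stringsAsFactors = FALSE, row.names = NULL)
  sort_rows(res, c("label", "curie"))
}

match_ans_phenotype <- function(phenotype) {
  tab <- ans_phenotypes()
  if (phenotype %in% tab$token) return(phenotype)
  hit <- tab$token[tolower(tab$label) == tolower(phenotype)]
  if (length(hit) == 1L) return(hit)
  stop("unknown ANS phenotype label: \"", phenotype, "\"")
}

#' Pre/post-ganglionic innervation circuit of an organ
#'
#' Target populations are those carrying the given ANS phenotype whose
#' final terminal reaches the organ through the part-of or supplies-to
#' closure. The circuit is the set of target populations together with
#' their reflexive-transitive predecessors under forward connections
#' (traversal is directed pre-to-post only; predecessors come from an
#' inverted index, no inverse triples are asserted). Rows are the
#' adjacency edges of all circuit populations, annotated with the
#' locational role of each endpoint; an edge endpoint is flagged as a
#' synapse when it is an axon-terminal location of its population and a
#' soma location of a directly forward-connected population -- the shared
#' structure where the preganglionic connection terminates and the
#' postganglionic one originates.
#'
#' @param graph a `sckan_graph`.
#' @param organ_label label or synonym of the end organ.
#' @param ans_phenotype phenotype token (e.g.
#'   `ans_phenotype("sympathetic", "post_ganglionic")`) or display label
#'   (e.g. `"Sympathetic Post-Ganglionic phenotype"`).
#' @return data.frame with columns `population`, `v1`, `v1_label`,
#'   `v1_role`, `v2`, `v2_label`, `v2_role`, `is_synapse`, sorted by
#'   (population, v1, v2).
#' @export
innervation_circuit <- function(graph, organ_label, ans_phenotype) {
  graph <- ensure_simple(graph)
  organ <- resolve_or_stop(graph, organ_label, "organ")
  token <- match_ans_phenotype(ans_phenotype)

  targets <- Filter(function(pop) {
    !is.null(pop$ans) && pop$ans == token &&
      any(vapply(pop_destinations(pop), function(d) {
        anc <- kg_ancestors(graph, d, c("part_of", "supplies_to"))
        length(intersect(anc, organ)) > 0L
      }, logical(1)))
  }, graph$populations)
  target_ids <- vapply(targets, function(p) p$id, character(1))

  # reflexive-transitive predecessors over forward connections
  preds_of <- list()
  for (pop in graph$populations) {
    for (fc in pop$forward_connections) {
      preds_of[[fc]] <- c(preds_of[[fc]], pop$id)
    }
  }
  members <- unname(target_ids)
  frontier <- members
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(preds_of[frontier], use.names = FALSE)),
                   members)
    members <- c(members, nxt)
    frontier <- nxt
  }
  members <- sort(members)

  rows <- list()
  for (id in members) {
    pop <- graph$populations[[id]]
    if (is.null(pop)) next
    edges <- graph$adjacency[graph$adjacency$population == id, , drop = FALSE]
    if (nrow(edges) == 0L) next
    fc_somata <- unique(unlist(lapply(pop$forward_connections, function(fc) {
      q <- graph$populations[[fc]]
      if (is.null(q)) character() else q$locations$soma
    }), use.names = FALSE))
    for (k in seq_len(nrow(edges))) {
      v1 <- edges$from[k]; v2 <- edges$to[k]
      v1_roles <- location_roles()[vapply(location_roles(), function(r)
        v1 %in% pop$locations[[r]], logical(1))]
      v2_roles <- location_roles()[vapply(location_roles(), function(r)
        v2 %in% pop$locations[[r]], logical(1))]
      if (length(v1_roles) == 0L) v1_roles <- NA_character_
      if (length(v2_roles) == 0L) v2_roles <- NA_character_
      grid <- expand.grid(v1_role = v1_roles, v2_role = v2_roles,
                          stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        population = id,
        v1 = v1, v1_label = entity_label(graph, v1), v1_role = grid$v1_role,
        v2 = v2, v2_label = entity_label(graph, v2), v2_role = grid$v2_role,
        is_synapse = !is.na(grid$v2_role) & grid$v2_role == "axon_terminal" &
          v2 %in% fc_somata,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(list(data.frame(
    population = character(), v1 = character(), v1_label = character(),
    v1_role = character(), v2 = character(), v2_label = character(),
    v2_role = character(), is_synapse = logical(),
    stringsAsFactors = FALSE)), rows))
  res <- res[!duplicated(res), , drop = FALSE]
  sort_rows(res, c("population", "v1", "v2"))
}

#' Filter populations by sex and species assertions
#'
#' Sex follows the closed-world rule: a population explicitly asserted in
#' one sex never matches a filter for the other; populations with no sex
#' axiom match both. Species follows the open-world rule: a named-taxon
#' filter matches only populations explicitly asserted in that taxon,
#' while `species = "unassigned"` matches exactly the populations with no
#' taxon assertion (mammalian, species unspecified).
#'
#' @param graph a `sckan_graph`.
#' @param sex optional `"male"` or `"female"`.
#' @param species optional taxon CURIE, taxon label (if labeled in the
#'   graph), or `"unassigned"`.
#' @return list of matching [neuron_population()] objects, sorted by id.
#' @export
filter_populations <- function(graph, sex = NULL, species = NULL) {
  pops <- graph$populations
  if (!is.null(sex)) {
    stopifnot(sex %in% c("male", "female"))
    pops <- Filter(function(p) is.null(p$sex) || p$sex == sex, pops)
  }
  if (!is.null(species)) {
    if (identical(species, "unassigned")) {
      pops <- Filter(function(p) length(p$species) == 0L, pops)
    } else {
      cu <- species
      if (!is_curie(cu) || !grepl("^NCBITaxon:", cu)) {
        hit <- names(graph$labels)[tolower(graph$labels) == tolower(species)]
        if (length(hit)) cu <- hit[1L]
      }
      pops <- Filter(function(p) cu %in% p$species, pops)
    }
  }
  pops[order(names(pops))]
}

#' Phenotype summary table
#'
#' Counts populations per phenotypic dimension: species (non-exclusive --
#' a population observed in several taxa counts once per taxon;
#' "Unassigned" counts populations with no taxon assertion), sex,
#' locational phenotype presence per role, functional circuit role,
#' circuit role, and coarse ANS subdivision (sympathetic /
#' parasympathetic / enteric, pooling pre-, post-, and unspecified
#' stages).
#'
#' @param graph a `sckan_graph`.
#' @return data.frame with columns `dimension`, `value`, `count`.
#' @export
phenotype_summary <- function(graph) {
  pops <- graph$populations
  rows <- list()
  add <- function(dimension, value, count) {
    rows[[length(rows) + 1L]] <<- data.frame(
      dimension = dimension, value = value, count = count,
      stringsAsFactors = FALSE)
  }

  taxa <- sort(unique(unlist(lapply(pops, function(p) p$species),
                             use.names = FALSE)))
  for (tx in taxa) {
    lab <- if (tx %in% names(graph$labels)) graph$labels[[tx]] else tx
    add("Species", lab,
        sum(vapply(pops, function(p) tx %in% p$species, logical(1))))
  }
  add("Species", "Unassigned",
      sum(vapply(pops, function(p) length(p$species) == 0L, logical(1))))

  for (sx in c("female", "male")) {
    add("Sex", tools::toTitleCase(sx),
        sum(vapply(pops, function(p) identical(p$sex, sx), logical(1))))
  }

  role_names <- c(soma = "Soma location", dendrite = "Dendrite location",
                  axon = "Axon location",
                  axon_to_sensory_terminal = "Sensory axon",
                  axon_terminal = "Axon terminal",
                  sensory_terminal = "Sensory terminal")
  for (r in location_roles()) {
    add("Locational phenotype", role_names[[r]],
        sum(vapply(pops, function(p) length(p$locations[[r]]) > 0L,
                   logical(1))))
  }

  for (fr in names(FUNCTIONAL_ROLES)) {
    add("Functional circuit role", tools::toTitleCase(fr),
        sum(vapply(pops, function(p) identical(p$functional_role, fr),
                   logical(1))))
  }
  for (cr in names(CIRCUIT_ROLES)) {
    add("Circuit role", tools::toTitleCase(cr),
        sum(vapply(pops, function(p) identical(p$circuit_role, cr),
                   logical(1))))
  }

  tab <- ans_phenotypes()
  for (dv in unique(tab$division)) {
    toks <- tab$token[tab$division == dv]
    add("ANS phenotype", tools::toTitleCase(dv),
        sum(vapply(pops, function(p) !is.null(p$ans) && p$ans %in% toks,
                   logical(1))))
  }
  # exact-label ANS buckets, for circuit-level filters
  for (k in seq_len(nrow(tab))) {
    n <- sum(vapply(pops, function(p) identical(p$ans, tab$token[k]),
                    logical(1)))
    if (n > 0L) add("ANS phenotype (exact)", tab$label[k], n)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
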