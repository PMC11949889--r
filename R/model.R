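#' Anatomical entities
#'
#' An anatomical structure identified by a UBERON or ILX CURIE, with a
#' display label, optional synonyms, and raw hierarchy edges: `part_of`
#' (partonomy), `subclass_of` (taxonomy), and `supplies_to` (vascular/neural
#' supply of an organ, used when scoping end-organ queries).
#'
#' @param curie anatomical CURIE (`UBERON:` or `ILX:`).
#' @param label non-empty display label.
#' @param synonyms character vector of alternative labels (may be empty).
#' @param part_of,subclass_of,supplies_to CURIEs of direct parents under
#'   each relation.
#' @return object of class `anatomical_entity`.
#' @export
#' @examples
#' anatomical_entity("UBERON:0018683", "lumbar splanchnic nerve",
#'                   subclass_of = "UBERON:0001021")
anatomical_entity <- function(curie, label, synonyms = character(),
                              part_of = character(),
                              subclass_of = character(),
                              supplies_to = character()) {
  stopifnot(length(curie) == 1L, is_curie(curie))
  if (!is_anatomical_curie(curie)) {
    stop("anatomical entities must use UBERON or ILX CURIEs, got: ", curie)
  }
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("entity label must be a non-empty string (", curie, ")")
  }
  structure(
    list(curie = curie, label = label,
         synonyms = sort(unique(as.character(synonyms))),
         part_of = sort(unique(as.character(part_of))),
         subclass_of = sort(unique(as.character(subclass_of))),
         supplies_to = sort(unique(as.character(supplies_to)))),
    class = "anatomical_entity"
  )
}

#' @export
print.anatomical_entity <- function(x, ...) {
  cat("<anatomical_entity> ", x$curie, " \"", x$label, "\"\n", sep = "")
  if (length(x$part_of)) cat("  part of:     ", paste(x$part_of, collapse = ", "), "\n")
  if (length(x$subclass_of)) cat("  subclass of: ", paste(x$subclass_of, collapse = ", "), "\n")
  invisible(x)
}

#' Partial-order trees: the axonal projection path
#'
#' The course of a population's axons from origins to destinations is an
#' ordered, possibly branching tree of anatomical CURIEs. The root is the
#' distinguished marker `"blank"`; its children are rooted at soma
#' locations and every leaf is a terminal location of the owning
#' population. The same structure may appear in several branches
#' (convergence); branches are merged by CURIE when deriving adjacency
#' edges.
#'
#' @param node a CURIE, or `"blank"` for the root marker.
#' @param ... child subtrees, each built with `po_tree()`.
#' @return nested list of class `po_tree` with fields `node` and
#'   `children`.
#' @export
#' @examples
#' # linear chain soma -> nerve -> ganglion
#' po_tree("blank",
#'   po_tree("UBERON:0006450",
#'     po_tree("UBERON:0018683",
#'       po_tree("UBERON:0005453"))))
po_tree <- function(node, ...) {
  children <- list(...)
  if (length(children) == 1L && is.list(children[[1L]]) &&
      is.null(children[[1L]]$node)) {
    children <- children[[1L]]   # allow passing a plain list of subtrees
  }
  stopifnot(is.character(node), length(node) == 1L)
  ok <- vapply(children, function(ch) inherits(ch, "po_tree"), logical(1))
  if (!all(ok)) stop("children of a po_tree must be po_tree objects")
  structure(list(node = node, children = children), class = "po_tree")
}

#' @export
print.po_tree <- function(x, ..., indent = 0) {
  cat(strrep("  ", indent), x$node, "\n", sep = "")
  for (ch in x$children) print(ch, indent = indent + 1)
  invisible(x)
}

#' All CURIEs in a partial-order tree
#'
#' Collects every node of the tree except the `"blank"` root marker.
#'
#' @param path a [po_tree()].
#' @return sorted character vector of distinct CURIEs.
#' @export
tree_nodes <- function(path) {
  if (is.null(path)) return(character())
  if (!inherits(path, "po_tree")) stop("not a partial-order tree")
  walk <- function(t) {
    if (!is.list(t) || is.null(t$node) || !is.list(t$children)) {
      stop("malformed partial-order tree node")
    }
    c(if (!identical(t$node, "blank")) t$node,
      unlist(lapply(t$children, walk), use.names = FALSE))
  }
  sort(unique(c(character(), walk(path))))
}

po_validate <- function(path) {
  # "blank" only at root
  has_blank_below <- function(t) {
    any(vapply(t$children, function(ch) {
      identical(ch$node, "blank") || has_blank_below(ch)
    }, logical(1)))
  }
  if (has_blank_below(path)) return("\"blank\" marker below the root")
  NULL
}

po_leaves <- function(path) {
  walk <- function(t) {
    if (length(t$children) == 0L) {
      if (identical(t$node, "blank")) character() else t$node
    } else {
      unlist(lapply(t$children, walk), use.names = FALSE)
    }
  }
  sort(unique(walk(path)))
}

#' Provenance of a connectivity statement
#'
#' @param citations character vector of typed identifiers; each must carry
#'   a type tag prefix: `DOI:`, `PMID:`, `ISBN:`, or `ORCID:`.
#' @param alert_notes free-text curatorial alerts (e.g. laterality caveats).
#' @param source_kind `"expert_model"` (expert-contributed circuit model) or
#'   `"literature"` (literature-extracted); determines the base class
#'   marker used in serialization.
#' @return object of class `provenance`.
#' @export
provenance <- function(citations = character(), alert_notes = character(),
                       source_kind = c("literature", "expert_model")) {
  source_kind <- match.arg(source_kind)
  citations <- as.character(citations)
  bad <- citations[!grepl("^(DOI|PMID|ISBN|ORCID):", citations)]
  if (length(bad)) {
    stop("citations must be typed (DOI:/PMID:/ISBN:/ORCID:): ",
         paste(bad, collapse = ", "))
  }
  structure(list(citations = sort(unique(citations)),
                 alert_notes = as.character(alert_notes),
                 source_kind = source_kind),
            class = "provenance")
}

#' Neuron populations
#'
#' One region-to-region connectivity statement: a theoretical grouping of
#' neurons sharing phenotypic properties, located by neuronal segment
#' (population N at A projects to B via C). A population must have at
#' least one origin (soma location) and one destination (axon terminal or
#' sensory terminal location).
#'
#' @param id population CURIE (e.g. `"prostate:24"`); the prefix must be
#'   declared in the registry used for serialization.
#' @param label short machine label (`rdfs:label`).
#' @param pref_label human-readable A-to-B-via-C label (`skos:prefLabel`).
#' @param locations named list mapping roles (see [location_roles()]) to
#'   character vectors of anatomical CURIEs.
#' @param path optional [po_tree()] encoding the axonal course.
#' @param ans optional ANS subdivision token from [ans_phenotype()].
#' @param circuit_role optional: `"intrinsic"`, `"motor"`, `"sensory"`, or
#'   `"projection"`.
#' @param functional_role optional: `"excitatory"` or `"inhibitory"`.
#' @param species character vector of taxon CURIEs; empty means observed in
#'   some mammal, species unspecified (open world), never "in no species".
#' @param sex optional `"male"` or `"female"`; when set, serialization adds
#'   an explicit negation of the opposite sex (closed world).
#' @param forward_connections CURIEs of post-synaptic partner populations.
#' @param prov a [provenance()] object.
#' @return object of class `neuron_population`.
#' @export
neuron_population <- function(id, label = id, pref_label = label,
                              locations = list(), path = NULL,
                              ans = NULL, circuit_role = NULL,
                              functional_role = NULL,
                              species = character(), sex = NULL,
                              forward_connections = character(),
                              prov = provenance()) {
  stopifnot(length(id) == 1L, is_curie(id))
  bad_roles <- setdiff(names(locations), location_roles())
  if (length(bad_roles)) {
    stop("unknown location role(s): ", paste(bad_roles, collapse = ", "))
  }
  locs <- stats::setNames(
    lapply(location_roles(), function(r) {
      sort(unique(as.character(locations[[r]] %||% character())))
    }),
    location_roles()
  )
  if (!is.null(path) && !inherits(path, "po_tree")) {
    stop("path must be a po_tree or NULL")
  }
  if (!is.null(ans) && !ans %in% ANS_TABLE$token) {
    stop("unknown ANS phenotype token: ", ans)
  }
  if (!is.null(circuit_role) && !circuit_role %in% names(CIRCUIT_ROLES)) {
    stop("unknown circuit role: ", circuit_role)
  }
  if (!is.null(functional_role) &&
      !functional_role %in% names(FUNCTIONAL_ROLES)) {
    stop("unknown functional role: ", functional_role)
  }
  if (!is.null(sex) && !sex %in% c("male", "female")) {
    stop("sex must be \"male\", \"female\", or NULL")
  }
  if (!inherits(prov, "provenance")) stop("prov must be a provenance()")
  structure(
    list(id = id, label = label, pref_label = pref_label,
         locations = locs, path = path,
         ans = ans, circuit_role = circuit_role,
         functional_role = functional_role,
         species = sort(unique(as.character(species))),
         sex = sex,
         forward_connections = sort(unique(as.character(forward_connections))),
         prov = prov),
    class = "neuron_population"
  )
}

#' @export
print.neuron_population <- function(x, ...) {
  cat("<neuron_population> ", x$id, "\n  ", x$pref_label, "\n", sep = "")
  for (r in location_roles()) {
    if (length(x$locations[[r]])) {
      cat("  ", format(r, width = 24), paste(x$locations[[r]], collapse = ", "),
          "\n", sep = "")
    }
  }
  if (!is.null(x$ans)) cat("  ANS phenotype:", ans_label(x$ans), "\n")
  if (!is.null(x$sex)) cat("  sex-specific:", x$sex, "\n")
  if (length(x$forward_connections)) {
    cat("  forward connections:", paste(x$forward_connections, collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pop_destinations <- function(pop) {
  sort(unique(unlist(pop$locations[DESTINATION_ROLES], use.names = FALSE)))
}
pop_axon_course <- function(pop) {
  sort(unique(unlist(pop$locations[AXON_COURSE_ROLES], use.names = FALSE)))
}
pop_all_locations <- function(pop) {
  sort(unique(unlist(pop$locations, use.names = FALSE)))
}

#' Validate a neuron population
#'
#' Checks the hard invariants (at least one origin and one destination;
#' no self forward-connection; well-formed path) and, as warnings, the
#' soft consistency rules: path nodes should appear in some location set,
#' and -- when a knowledge graph is supplied -- location CURIEs should
#' resolve and forward-connection targets should exist. Always returns a
#' report; callers decide whether warnings block. The check is idempotent
#' and side-effect free.
#'
#' @param pop a [neuron_population()].
#' @param graph optional [kg_new()] knowledge graph for reference checks.
#' @return data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `code`, `message`; zero rows iff all hard invariants and soft checks
#'   pass.
#' @export
validate_population <- function(pop, graph = NULL) {
  stopifnot(inherits(pop, "neuron_population"))
  sev <- character(); code <- character(); msg <- character()
  note <- function(s, c, m) {
    sev <<- c(sev, s); code <<- c(code, c); msg <<- c(msg, m)
  }

  if (length(pop$locations$soma) == 0L) {
    note("error", "MISSING_ORIGIN",
         paste0(pop$id, ": no soma location (at least one origin required)"))
  }
  if (length(pop_destinations(pop)) == 0L) {
    note("error", "MISSING_DESTINATION",
         paste0(pop$id, ": no axon terminal or sensory terminal location"))
  }
  if (pop$id %in% pop$forward_connections) {
    note("error", "SELF_FORWARD_CONNECTION",
         paste0(pop$id, ": forward connection to itself"))
  }
  if (!is.null(pop$path)) {
    structural <- po_validate(pop$path)
    if (!is.null(structural)) {
      note("error", "MALFORMED_PATH", paste0(pop$id, ": ", structural))
    } else {
      if (!identical(pop$path$node, "blank")) {
        note("warning", "PATH_ROOT_NOT_BLANK",
             paste0(pop$id, ": partial order root is not the \"blank\" marker"))
      }
      foreign <- setdiff(tree_nodes(pop$path), pop_all_locations(pop))
      for (f in foreign) {
        note("warning", "PATH_LOCATION_MISMATCH",
             paste0(pop$id, ": path node ", f,
                    " absent from all locational phenotype sets"))
      }
    }
  }
  if (!is.null(graph)) {
    unknown <- setdiff(pop_all_locations(pop), names(graph$entities))
    for (u in unknown) {
      note("warning", "UNKNOWN_CURIE",
           paste0(pop$id, ": location ", u, " not resolvable in the graph"))
    }
    missing_fc <- setdiff(pop$forward_connections, names(graph$populations))
    for (m in missing_fc) {
      note("warning", "UNKNOWN_FORWARD_TARGET",
           paste0(pop$id, ": forward connection target ", m,
                  " absent from the graph"))
    }
  }
  data.frame(severity = sev, code = code, message = msg,
             stringsAsFactors = FALSE)
}
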