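#' Write populations as the OWL axiom dialect
#'
#' Serializes neuron populations as Turtle: one `owl:equivalentClass` axiom
#' per population whose intersection starts with the base class marker
#' (`ilxtr:NeuronSparcNlp` for literature-extracted, `ilxtr:NeuronApinatSimple`
#' for expert-model populations) followed by `owl:someValuesFrom`
#' restrictions in canonical order (taxon, sex, phenotypes, locations by
#' role, forward connections). Every locational restriction nests a part-of
#' restriction around the location CURIE; sex-specific populations carry an
#' `owl:complementOf` negation of the opposite sex (closed-world sex).
#' Axonal courses are serialized as `ilxtr:neuronPartialOrder` nested RDF
#' collections whose root element is the literal `"blank"`. Output is
#' byte-stable for identical input: populations sorted by id, locations by
#' role order then CURIE.
#'
#' @param pops list of [neuron_population()]; all must pass hard
#'   validation.
#' @param entities list of [anatomical_entity()]; serialized as flat label
#'   / `ilxtr:isPartOf` / `rdfs:subClassOf` / `ilxtr:suppliesTo` triples.
#' @param prefixes prefix registry; every prefix used must be declared.
#' @param labels named character vector of extra `rdfs:label` triples for
#'   non-anatomical terms (taxa, phenotype classes).
#' @param label_comments emit `# label` comments next to partial-order
#'   nodes (non-semantic).
#' @return single string: a Turtle document.
#' @export
write_ttl <- function(pops, entities = list(), prefixes = default_prefixes(),
                      labels = character(), label_comments = FALSE) {
  pops <- pops[order(vapply(pops, function(p) p$id, character(1)))]
  for (p in pops) {
    rep <- validate_population(p)
    hard <- rep[rep$severity == "error", , drop = FALSE]
    # stubs (forward-connection targets with no locations yet) are the one
    # tolerated exception: no locations at all, only identity metadata
    is_stub <- length(pop_all_locations(p)) == 0L && is.null(p$path)
    if (nrow(hard) && !is_stub) {
      stop("refusing to serialize invalid population ", p$id, ":\n  ",
           paste(hard$message, collapse = "\n  "))
    }
  }
  used_prefixes <- ttl_used_prefixes(pops, entities, labels, prefixes)
  out <- c(ttl_prefix_block(used_prefixes), "")
  for (e in entities[order(vapply(entities, function(e) e$curie, character(1)))]) {
    out <- c(out, ttl_entity_block(e), "")
  }
  if (length(labels)) {
    for (cu in sort(names(labels))) {
      out <- c(out, paste0(cu, " rdfs:label ", ttl_term(labels[[cu]], TRUE), " ."), "")
    }
  }
  for (p in pops) {
    out <- c(out, ttl_population_block(p, label_comments), "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

ttl_used_prefixes <- function(pops, entities, labels, prefixes) {
  used <- c("rdf", "rdfs", "owl", "skos", "ilxtr", "partOf",
            vapply(entities, function(e) curie_prefix(e$curie), character(1)),
            unlist(lapply(pops, function(p) {
              c(curie_prefix(p$id),
                curie_prefix(pop_all_locations(p)),
                curie_prefix(p$species),
                curie_prefix(p$forward_connections),
                if (!is.null(p$sex)) "PATO")
            }), use.names = FALSE),
            curie_prefix(names(labels)))
  used <- intersect(names(prefixes), unique(used))
  prefixes[used]
}

ttl_entity_block <- function(e) {
  lines <- paste0(e$curie, " a owl:Class ;")
  body <- paste0("    rdfs:label ", ttl_term(e$label, TRUE))
  for (s in e$synonyms) body <- c(body, paste0("    skos:altLabel ", ttl_term(s, TRUE)))
  for (p in e$part_of) body <- c(body, paste0("    ilxtr:isPartOf ", p))
  for (s in e$subclass_of) body <- c(body, paste0("    rdfs:subClassOf ", s))
  for (s in e$supplies_to) body <- c(body, paste0("    ilxtr:suppliesTo ", s))
  c(lines, paste0(body, c(rep(" ;", length(body) - 1L), " .")))
}

restriction_block <- function(prop, filler, indent, part_of_wrap = TRUE) {
  pad <- strrep(" ", indent)
  if (part_of_wrap) {
    c(paste0(pad, "[ a owl:Restriction ;"),
      paste0(pad, "  owl:onProperty ", prop, " ;"),
      paste0(pad, "  owl:someValuesFrom [ a owl:Restriction ;"),
      paste0(pad, "      owl:onProperty partOf: ;"),
      paste0(pad, "      owl:someValuesFrom ", filler, " ] ]"))
  } else {
    c(paste0(pad, "[ a owl:Restriction ;"),
      paste0(pad, "  owl:onProperty ", prop, " ;"),
      paste0(pad, "  owl:someValuesFrom ", filler, " ]"))
  }
}

complement_block <- function(prop, filler, indent) {
  pad <- strrep(" ", indent)
  c(paste0(pad, "[ a owl:Class ;"),
    paste0(pad, "  owl:complementOf [ a owl:Restriction ;"),
    paste0(pad, "      owl:onProperty ", prop, " ;"),
    paste0(pad, "      owl:someValuesFrom ", filler, " ] ]"))
}

ttl_po_block <- function(tree, indent, label_comments, entities_env = NULL) {
  pad <- strrep(" ", indent)
  node_txt <- if (identical(tree$node, "blank")) "\"blank\"" else tree$node
  if (length(tree$children) == 0L) {
    paste0(pad, "( ", node_txt, " )")
  } else {
    kids <- unlist(lapply(tree$children, ttl_po_block, indent = indent + 4L,
                          label_comments = label_comments),
                   use.names = FALSE)
    c(paste0(pad, "( ", node_txt), kids, paste0(pad, ")"))
  }
}

ttl_population_block <- function(p, label_comments = FALSE) {
  lines <- c(paste0(p$id, " a owl:Class ;"),
             paste0("    rdfs:label ", ttl_term(p$label, TRUE), " ;"),
             paste0("    skos:prefLabel ", ttl_term(p$pref_label, TRUE), " ;"))
  for (r in p$prov$citations) {
    lines <- c(lines, paste0("    ilxtr:reference ", ttl_term(r, TRUE), " ;"))
  }
  for (a in p$prov$alert_notes) {
    lines <- c(lines, paste0("    ilxtr:alertNote ", ttl_term(a, TRUE), " ;"))
  }
  if (!is.null(p$path)) {
    po <- ttl_po_block(p$path, 8L, label_comments)
    lines <- c(lines, "    ilxtr:neuronPartialOrder", po[1:(length(po))])
    lines[length(lines)] <- paste0(lines[length(lines)], " ;")
  }
  members <- list(BASE_MARKERS[[p$prov$source_kind]])
  add <- function(x) members[[length(members) + 1L]] <<- x
  for (tx in p$species) {
    add(restriction_block("ilxtr:hasInstanceInTaxon", tx, 12L, part_of_wrap = FALSE))
  }
  if (!is.null(p$sex)) {
    add(restriction_block("ilxtr:hasBiologicalSex", SEX_CURIES[[p$sex]], 12L,
                          part_of_wrap = FALSE))
    add(complement_block("ilxtr:hasBiologicalSex",
                         SEX_CURIES[[opposite_sex(p$sex)]], 12L))
  }
  if (!is.null(p$ans)) {
    add(restriction_block("ilxtr:hasAnatomicalSystemPhenotype",
                          ans_curie(p$ans), 12L, part_of_wrap = FALSE))
  }
  if (!is.null(p$circuit_role)) {
    add(restriction_block("ilxtr:hasCircuitRolePhenotype",
                          CIRCUIT_ROLES[[p$circuit_role]], 12L,
                          part_of_wrap = FALSE))
  }
  if (!is.null(p$functional_role)) {
    add(restriction_block("ilxtr:hasFunctionalCircuitRolePhenotype",
                          FUNCTIONAL_ROLES[[p$functional_role]], 12L,
                          part_of_wrap = FALSE))
  }
  for (r in location_roles()) {
    for (loc in p$locations[[r]]) {
      add(restriction_block(role_to_owl(r), loc, 12L, part_of_wrap = TRUE))
    }
  }
  for (fc in p$forward_connections) {
    add(restriction_block("ilxtr:hasForwardConnectionPhenotype", fc, 12L,
                          part_of_wrap = FALSE))
  }
  member_lines <- unlist(lapply(members, function(m) {
    if (length(m) == 1L && !grepl("\n", m) && !startsWith(trimws(m), "[")) {
      paste0(strrep(" ", 12L), m)
    } else m
  }), use.names = FALSE)
  c(lines,
    "    owl:equivalentClass [ a owl:Class ;",
    "        owl:intersectionOf (",
    member_lines,
    "        ) ] .")
}

#' Read the OWL axiom dialect
#'
#' Parses a Turtle document in the nested-axiom dialect and reconstructs
#' neuron populations (including their partial-order trees) and anatomical
#' entities. `read_ttl(write_ttl(x))` is structurally identical to `x`.
#'
#' Dialect tolerances: taxon and sex fillers may or may not be wrapped in a
#' part-of restriction; a locational restriction lacking the nested
#' part-of wrapper raises a dialect warning but the location is still
#' captured; an equivalent-class axiom with no base class marker is an
#' error naming the population IRI.
#'
#' @param text Turtle source (string or lines) or a file path.
#' @param prefixes fallback prefix registry.
#' @return list with `populations`, `entities`, `labels`, `prefixes`.
#' @export
read_ttl <- function(text, prefixes = default_prefixes()) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  parsed <- ttl_parse(text, prefixes)
  tt <- parsed$triples

  eq_subjects <- unique(tt$s[tt$p == "owl:equivalentClass"])
  eq_subjects <- sort(eq_subjects[!startsWith(eq_subjects, "_:")])

  pops <- lapply(eq_subjects, function(s) read_population(tt, s))
  names(pops) <- eq_subjects

  ana_subjects <- unique(tt$s[is_anatomical_curie(tt$s)])
  ana_subjects <- sort(setdiff(ana_subjects, eq_subjects))
  ents <- list()
  for (s in ana_subjects) {
    lab <- tt$o[tt$s == s & tt$p == "rdfs:label" & tt$o_is_literal]
    if (length(lab) == 0L) next
    part_of <- tt$o[tt$s == s & tt$p %in% c("ilxtr:isPartOf", "partOf:")]
    ents[[s]] <- anatomical_entity(
      curie = s, label = lab[1L],
      synonyms = tt$o[tt$s == s & tt$p == "skos:altLabel" & tt$o_is_literal],
      part_of = part_of[!startsWith(part_of, "_:")],
      subclass_of = {
        sc <- tt$o[tt$s == s & tt$p == "rdfs:subClassOf"]
        sc[is_anatomical_curie(sc)]
      },
      supplies_to = tt$o[tt$s == s & tt$p == "ilxtr:suppliesTo"]
    )
  }

  lab_rows <- tt[tt$p == "rdfs:label" & tt$o_is_literal &
                   !tt$s %in% c(eq_subjects, ana_subjects) &
                   !startsWith(tt$s, "_:"), , drop = FALSE]
  labels <- if (nrow(lab_rows)) stats::setNames(lab_rows$o, lab_rows$s)
            else character()

  list(populations = pops, entities = ents, labels = labels,
       prefixes = parsed$prefixes)
}

# Reconstruct one population from the triple table.
read_population <- function(tt, s) {
  lab <- tt$o[tt$s == s & tt$p == "rdfs:label" & tt$o_is_literal]
  pref <- tt$o[tt$s == s & tt$p == "skos:prefLabel" & tt$o_is_literal]
  refs <- tt$o[tt$s == s & tt$p == "ilxtr:reference" & tt$o_is_literal]
  alerts <- tt$o[tt$s == s & tt$p == "ilxtr:alertNote" & tt$o_is_literal]

  eq <- tt$o[tt$s == s & tt$p == "owl:equivalentClass"][1L]
  inter <- tt$o[tt$s == eq & tt$p == "owl:intersectionOf"]
  if (length(inter) != 1L) {
    stop("population ", s, ": equivalent class without owl:intersectionOf")
  }
  items <- rdf_list_items(tt, inter[1L])
  terms <- vapply(items, `[[`, character(1), "term")

  marker <- terms[terms %in% BASE_MARKERS]
  if (length(marker) == 0L) {
    stop("population ", s,
         ": no base class marker (NeuronSparcNlp/NeuronApinatSimple) ",
         "in its equivalent-class intersection")
  }
  source_kind <- MARKER_TO_KIND[[marker[1L]]]

  locations <- stats::setNames(
    lapply(location_roles(), function(r) character()), location_roles())
  species <- character(); sex <- NULL; complemented <- NULL
  ans <- NULL; circuit_role <- NULL; functional_role <- NULL
  forward <- character()

  unwrap_filler <- function(val, prop, want_wrap) {
    # val may be a nested part-of restriction or a direct CURIE
    if (startsWith(val, "_:")) {
      inner_prop <- tt$o[tt$s == val & tt$p == "owl:onProperty"]
      if (length(inner_prop) && inner_prop[1L] %in% c("partOf:", "ilxtr:isPartOf")) {
        return(tt$o[tt$s == val & tt$p == "owl:someValuesFrom"][1L])
      }
      stop("population ", s, ": unrecognized nested filler under ", prop)
    }
    if (want_wrap) {
      warning("population ", s, ": locational restriction on ", prop,
              " lacks the nested part-of wrapper; capturing the bare filler",
              call. = FALSE)
    }
    val
  }

  for (it in items) {
    term <- it$term
    if (term %in% BASE_MARKERS) next
    if (!startsWith(term, "_:")) {
      stop("population ", s, ": unexpected named member ", term,
           " in its intersection")
    }
    types <- tt$o[tt$s == term & tt$p == RDF_TYPE]
    if ("owl:Restriction" %in% types) {
      prop <- tt$o[tt$s == term & tt$p == "owl:onProperty"][1L]
      val <- tt$o[tt$s == term & tt$p == "owl:someValuesFrom"][1L]
      role <- owl_to_role(prop)
      if (!is.na(role)) {
        locations[[role]] <- c(locations[[role]], unwrap_filler(val, prop, TRUE))
      } else if (prop == "ilxtr:hasInstanceInTaxon") {
        species <- c(species, unwrap_filler(val, prop, FALSE))
      } else if (prop == "ilxtr:hasBiologicalSex") {
        sex <- SEX_FROM_CURIE[[unwrap_filler(val, prop, FALSE)]]
      } else if (prop == "ilxtr:hasAnatomicalSystemPhenotype") {
        ans <- ans_from_curie(val)
        if (is.na(ans)) stop("population ", s, ": unknown ANS phenotype ", val)
      } else if (prop == "ilxtr:hasCircuitRolePhenotype") {
        circuit_role <- names(CIRCUIT_ROLES)[match(val, CIRCUIT_ROLES)]
      } else if (prop == "ilxtr:hasFunctionalCircuitRolePhenotype") {
        functional_role <- names(FUNCTIONAL_ROLES)[match(val, FUNCTIONAL_ROLES)]
      } else if (prop == "ilxtr:hasForwardConnectionPhenotype") {
        forward <- c(forward, val)
      } else {
        warning("population ", s, ": ignoring restriction on unknown property ",
                prop, call. = FALSE)
      }
    } else if ("owl:Class" %in% types) {
      comp <- tt$o[tt$s == term & tt$p == "owl:complementOf"]
      if (length(comp) == 1L) {
        cv <- tt$o[tt$s == comp & tt$p == "owl:someValuesFrom"][1L]
        complemented <- SEX_FROM_CURIE[[cv]]
      }
    }
  }
  if (!is.null(sex) && !identical(complemented, opposite_sex(sex))) {
    warning("population ", s, ": sex-specific axiom without the matching ",
            "opposite-sex negation", call. = FALSE)
  }

  path <- NULL
  po_head <- tt$o[tt$s == s & tt$p == "ilxtr:neuronPartialOrder"]
  if (length(po_head) == 1L) path <- po_from_collection(tt, po_head)

  neuron_population(
    id = s,
    label = if (length(lab)) lab[1L] else s,
    pref_label = if (length(pref)) pref[1L] else if (length(lab)) lab[1L] else s,
    locations = locations, path = path,
    ans = ans, circuit_role = circuit_role, functional_role = functional_role,
    species = species, sex = sex, forward_connections = forward,
    prov = provenance(citations = refs, alert_notes = alerts,
                      source_kind = source_kind)
  )
}

# A partial-order collection is ( node child1 child2 ... ) where node is a
# literal ("blank") or CURIE and each child is itself a collection.
po_from_collection <- function(tt, head) {
  items <- rdf_list_items(tt, head)
  if (length(items) == 0L) stop("empty partial-order collection")
  node <- items[[1L]]$term
  children <- lapply(items[-1L], function(it) {
    if (it$lit || !startsWith(it$term, "_:")) {
      stop("malformed partial-order: child element is not a nested collection")
    }
    po_from_collection(tt, it$term)
  })
  do.call(po_tree, c(list(node), children))
}

#' Load an OWL-dialect document as a knowledge graph
#'
#' @param text Turtle source or file path.
#' @param prefixes fallback prefix registry.
#' @return a `sckan_graph` with dialect `"owl"`.
#' @export
kg_from_owl <- function(text, prefixes = default_prefixes()) {
  r <- read_ttl(text, prefixes)
  g <- kg_new(entities = r$entities, populations = r$populations,
              dialect = "owl", prefixes = r$prefixes)
  g$labels <- r$labels
  g
}
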