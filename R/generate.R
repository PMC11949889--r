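#' Seeded generator of connectivity-graph test worlds
#'
#' Builds a knowledge graph with the structural features of a real
#' connectivity release -- an organ partonomy, a nerve / nerve-plexus
#' hierarchy with branch nerves, ganglia, spinal segments, populations
#' with locational phenotypes and ANS / sex / species annotations, and
#' planted pre-to-post ganglionic circuits sharing synapse structures --
#' together with a ground-truth ledger that the query engine must recover
#' exactly. The default phenotype mix mirrors the proportions observed in
#' a mature autonomic connectivity release: roughly 45% sympathetic, 26%
#' parasympathetic, a rare enteric population, a quarter female-specific
#' and under a tenth male-specific populations, and about 70% of
#' populations carrying at least one species assertion.
#'
#' @param n_entities target number of anatomical entities (>= 25).
#' @param n_populations number of neuron populations (>= 2).
#' @param partonomy_depth depth of each organ's part-of chain (>= 1).
#' @param ans_fractions named proportions for `sympathetic`,
#'   `parasympathetic`, `enteric` populations (remainder unannotated).
#' @param sex_fractions named proportions for `female` and
#'   `male`-specific populations.
#' @param species_fraction proportion of populations with at least one
#'   taxon assertion.
#' @param n_circuits number of planted pre/post circuits (each consumes
#'   two populations and one dedicated organ).
#' @param seed integer seed; identical `(config, seed)` gives identical
#'   output.
#' @return `generator_config` object for [generate_graph()].
#' @export
generator_config <- function(n_entities = 80, n_populations = 30,
                             partonomy_depth = 2,
                             ans_fractions = c(sympathetic = 0.45,
                                               parasympathetic = 0.26,
                                               enteric = 0.01),
                             sex_fractions = c(female = 0.24, male = 0.09),
                             species_fraction = 0.7,
                             n_circuits = 3, seed = 1) {
  stopifnot(n_entities >= 25, n_populations >= 2, partonomy_depth >= 1,
            n_circuits >= 0, all(ans_fractions >= 0), sum(ans_fractions) <= 1,
            all(sex_fractions >= 0), sum(sex_fractions) <= 1,
            species_fraction >= 0, species_fraction <= 1)
  if (2L * n_circuits > n_populations) {
    stop("infeasible config: ", n_circuits, " circuits need ",
         2L * n_circuits, " populations, only ", n_populations, " requested")
  }
  structure(list(n_entities = as.integer(n_entities),
                 n_populations = as.integer(n_populations),
                 partonomy_depth = as.integer(partonomy_depth),
                 ans_fractions = ans_fractions,
                 sex_fractions = sex_fractions,
                 species_fraction = species_fraction,
                 n_circuits = as.integer(n_circuits),
                 seed = as.integer(seed)),
            class = "generator_config")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

mint_ilx <- function(k) sprintf("ILX:08%05d", k)

# sample() treats a length-1 numeric-looking vector as sample.int(); avoid
sample_from <- function(x, size = 1L) {
  if (length(x) == 1L) rep(x, min(size, 1L)) else sample(x, size)
}

#' Generate a synthetic connectivity graph with its ground-truth ledger
#'
#' @param config a [generator_config()].
#' @return list with elements `graph` (a `sckan_graph`, OWL dialect, all
#'   populations passing hard validation) and `ledger` (the ground truth:
#'   per-population organ target, routing nerve, and terminals; the
#'   planted circuits with their synapse locations).
#' @export
#' @examples
#' gl <- generate_graph(generator_config(seed = 42))
#' gl$ledger$circuits[[1]]$synapse
generate_graph <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_graph_impl(config))
}

generate_graph_impl <- function(config) {
  k <- 0L
  mint <- function() { k <<- k + 1L; mint_ilx(k) }
  ents <- base_entities()
  add_ent <- function(...) ents[[length(ents) + 1L]] <<- anatomical_entity(...)

  budget <- config$n_entities - length(ents)
  n_organs <- max(config$n_circuits + 2L, ceiling(budget * 0.1))
  n_nerves <- max(4L, ceiling(budget * 0.2))
  n_ganglia <- max(config$n_circuits, ceiling(budget * 0.12))
  n_segments <- max(3L, ceiling(budget * 0.15))
  n_parts_total <- max(n_organs,
                       budget - n_organs - n_nerves - n_ganglia - n_segments)

  organs <- character(n_organs)
  organ_labels <- character(n_organs)
  for (i in seq_len(n_organs)) {
    organs[i] <- mint()
    organ_labels[i] <- paste("synthetic organ", i)
    add_ent(organs[i], organ_labels[i])
  }
  # each organ gets a part chain of depth partonomy_depth; extra parts are
  # spread round-robin as siblings of the chain tips
  organ_parts <- stats::setNames(vector("list", n_organs), organs)
  part_count <- 0L
  for (i in seq_len(n_organs)) {
    parent <- organs[i]
    for (d in seq_len(config$partonomy_depth)) {
      if (part_count >= n_parts_total) break
      cu <- mint(); part_count <- part_count + 1L
      add_ent(cu, paste0("region ", d, " of ", organ_labels[i]),
              part_of = parent)
      organ_parts[[organs[i]]] <- c(organ_parts[[organs[i]]], cu)
      parent <- cu
    }
    if (length(organ_parts[[organs[i]]]) == 0L) {
      cu <- mint()
      add_ent(cu, paste0("region 1 of ", organ_labels[i]),
              part_of = organs[i])
      organ_parts[[organs[i]]] <- cu
    }
  }

  nerves <- character(n_nerves)
  nerve_trunk <- stats::setNames(rep(NA_character_, n_nerves), character(n_nerves))
  for (i in seq_len(n_nerves)) {
    nerves[i] <- mint()
    if (i > 1L && stats::runif(1) < 0.3) {
      # a branch nerve: part of an earlier trunk
      trunk <- nerves[sample.int(i - 1L, 1L)]
      add_ent(nerves[i], paste("synthetic nerve", i),
              subclass_of = "UBERON:0001021", part_of = trunk)
    } else {
      trunk <- NA_character_
      add_ent(nerves[i], paste("synthetic nerve", i),
              subclass_of = "UBERON:0001021")
    }
    nerve_trunk[i] <- trunk
    names(nerve_trunk)[i] <- nerves[i]
  }
  # reflexive trunk closure of each nerve, from the edges just created
  nerve_closure <- lapply(nerves, function(nv) {
    out <- nv
    while (!is.na(nerve_trunk[[nv]])) {
      nv <- nerve_trunk[[nv]]
      out <- c(out, nv)
    }
    out
  })
  names(nerve_closure) <- nerves
  ganglia <- character(n_ganglia)
  for (i in seq_len(n_ganglia)) {
    ganglia[i] <- mint()
    add_ent(ganglia[i], paste("synthetic ganglion", i),
            subclass_of = "UBERON:0000045")
  }
  segments <- character(n_segments)
  for (i in seq_len(n_segments)) {
    segments[i] <- mint()
    add_ent(segments[i], paste("synthetic spinal segment", i))
  }

  taxa <- c("NCBITaxon:10116", "NCBITaxon:9606", "NCBITaxon:10090")
  draw_sex <- function() {
    u <- stats::runif(1)
    if (u < config$sex_fractions[["female"]]) "female"
    else if (u < sum(config$sex_fractions)) "male"
    else NULL
  }
  draw_species <- function() {
    if (stats::runif(1) < config$species_fraction) {
      sample(taxa, sample.int(2L, 1L))
    } else character()
  }
  draw_ans <- function() {
    u <- stats::runif(1)
    f <- config$ans_fractions
    if (u < f[["sympathetic"]]) {
      ans_phenotype("sympathetic",
                    sample(c("pre_ganglionic", "post_ganglionic"), 1L))
    } else if (u < f[["sympathetic"]] + f[["parasympathetic"]]) {
      ans_phenotype("parasympathetic",
                    sample(c("pre_ganglionic", "post_ganglionic"), 1L))
    } else if (u < sum(f)) {
      ans_phenotype("enteric")
    } else NULL
  }

  chain_path <- function(somata, via, terminals) {
    term_leaves <- lapply(terminals, po_tree)
    do.call(po_tree, c(list("blank"), lapply(seq_along(somata), function(j) {
      if (j == 1L) {
        po_tree(somata[j], do.call(po_tree, c(list(via), term_leaves)))
      } else {
        po_tree(somata[j], po_tree(via))
      }
    })))
  }

  pops <- list()
  led_id <- character(); led_organ <- character(); led_via <- character()
  led_terms <- list()
  circuits <- list()
  pop_id <- function(i) paste0("synkb:pop-", i)

  # planted circuits occupy the first 2*n_circuits population slots and the
  # first n_circuits organs/ganglia, so circuit organs are never targeted
  # by distractor populations
  for (c in seq_len(config$n_circuits)) {
    pre_id <- pop_id(2L * c - 1L); post_id <- pop_id(2L * c)
    g_c <- ganglia[c]
    organ_c <- organs[c]
    term_c <- organ_parts[[organ_c]][length(organ_parts[[organ_c]])]
    pre_somata <- sample_from(segments, sample.int(2L, 1L))
    pre_via <- sample_from(nerves)
    post_via <- sample_from(nerves)
    pops[[pre_id]] <- neuron_population(
      id = pre_id, label = paste("synthetic population", 2L * c - 1L),
      pref_label = paste("planted preganglionic", c),
      locations = list(soma = pre_somata, axon = pre_via,
                       axon_terminal = g_c),
      path = chain_path(pre_somata, pre_via, g_c),
      ans = ans_phenotype("sympathetic", "pre_ganglionic"),
      species = draw_species(), sex = draw_sex(),
      forward_connections = post_id,
      prov = provenance(source_kind = "expert_model"))
    pops[[post_id]] <- neuron_population(
      id = post_id, label = paste("synthetic population", 2L * c),
      pref_label = paste("planted postganglionic", c),
      locations = list(soma = g_c, axon = post_via,
                       axon_terminal = term_c),
      path = chain_path(g_c, post_via, term_c),
      ans = ans_phenotype("sympathetic", "post_ganglionic"),
      species = draw_species(), sex = draw_sex(),
      prov = provenance(source_kind = "expert_model"))
    led_id <- c(led_id, pre_id, post_id)
    led_organ <- c(led_organ, NA_character_, organ_c)
    led_via <- c(led_via, pre_via, post_via)
    led_terms <- c(led_terms, list(g_c), list(term_c))
    circuits[[c]] <- list(pre = pre_id, post = post_id, synapse = g_c,
                          organ = organ_c, organ_label = organ_labels[c])
  }

  free_organs <- organs[(config$n_circuits + 1L):n_organs]
  extra <- if (2L * config$n_circuits < config$n_populations) {
    (2L * config$n_circuits + 1L):config$n_populations
  } else integer()
  for (i in extra) {
    id <- pop_id(i)
    organ_i <- sample_from(free_organs)
    parts <- organ_parts[[organ_i]]
    terms <- sample_from(parts, min(length(parts), sample.int(2L, 1L)))
    somata <- sample_from(segments, sample.int(2L, 1L))
    via <- sample_from(nerves)
    pops[[id]] <- neuron_population(
      id = id, label = paste("synthetic population", i),
      pref_label = paste("synthetic connection", i),
      locations = list(soma = somata, axon = via, axon_terminal = terms),
      path = chain_path(somata, via, terms),
      ans = draw_ans(), species = draw_species(), sex = draw_sex(),
      prov = provenance(
        source_kind = sample(c("literature", "expert_model"), 1L)))
    led_id <- c(led_id, id)
    led_organ <- c(led_organ, organ_i)
    led_via <- c(led_via, via)
    led_terms <- c(led_terms, list(terms))
  }

  graph <- kg_new(entities = ents, populations = pops, dialect = "owl")
  graph$labels <- TAXON_LABELS[taxa]

  for (p in graph$populations) {
    rep <- validate_population(p, graph)
    if (any(rep$severity == "error")) {
      stop("generator produced an invalid population: ",
           paste(rep$message, collapse = "; "))
    }
  }

  ledger <- list(
    populations = data.frame(
      id = led_id, organ = led_organ,
      organ_label = ifelse(is.na(led_organ), NA_character_,
                           organ_labels[match(led_organ, organs)]),
      via = led_via, stringsAsFactors = FALSE),
    via_closure = stats::setNames(nerve_closure[led_via], led_id),
    terminals = stats::setNames(led_terms, led_id),
    circuits = circuits,
    config = config)
  list(graph = graph, ledger = ledger)
}
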