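#' Compact URIs (CURIEs) and the prefix registry
#'
#' Every identifier in a connectivity graph -- anatomical structures, neuron
#' populations, predicates, phenotype values -- is a CURIE of the form
#' `prefix:local_id`. Anatomical structures are restricted to the `UBERON`
#' and `ILX` namespaces; population and predicate namespaces are free but
#' must be declared in the prefix registry so that documents can be expanded
#' to full IRIs and parsed back.
#'
#' @name curies
NULL

#' Default prefix registry
#'
#' Named character vector mapping prefix tokens to IRI bases. The defaults
#' cover the readable-predicate namespace (`ilxtr`), the anatomical
#' namespaces (`UBERON`, `ILX`), taxon and quality namespaces
#' (`NCBITaxon`, `PATO`), the RDF/OWL core, and the population namespaces
#' used by the bundled fixtures. Additional population namespaces can be
#' appended by the caller.
#'
#' @param ... further `prefix = "iri-base"` pairs to append or override.
#' @return named character vector of IRI bases.
#' @export
#' @examples
#' default_prefixes()[["ilxtr"]]
#' default_prefixes(mypop = "http://example.org/pop/")[["mypop"]]
default_prefixes <- function(...) {
  base <- c(
    rdf       = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs      = "http://www.w3.org/2000/01/rdf-schema#",
    owl       = "http://www.w3.org/2002/07/owl#",
    skos      = "http://www.w3.org/2004/02/skos/core#",
    xsd       = "http://www.w3.org/2001/XMLSchema#",
    ilxtr     = "http://uri.interlex.org/tgbugs/uris/readable/",
    UBERON    = "http://purl.obolibrary.org/obo/UBERON_",
    ILX       = "http://uri.interlex.org/base/ilx_",
    NCBITaxon = "http://purl.obolibrary.org/obo/NCBITaxon_",
    PATO      = "http://purl.obolibrary.org/obo/PATO_",
    partOf    = "http://purl.obolibrary.org/obo/BFO_0000050",
    prostate  = "http://uri.interlex.org/tgbugs/uris/readable/sparc-nlp/prostate/",
    femrep    = "http://uri.interlex.org/tgbugs/uris/readable/sparc-nlp/femrep/",
    salivary  = "http://uri.interlex.org/tgbugs/uris/readable/sparc-nlp/salivary/",
    synkb     = "http://example.org/sckanr/synthetic/"
  )
  extra <- c(...)
  if (length(extra)) base[names(extra)] <- extra
  base
}

#' Parse and render CURIEs
#'
#' A CURIE renders as `"prefix:local_id"` and round-trips through
#' [curie_prefix()] / [curie_local()] unchanged. The local part may be empty
#' (e.g. the bare relation prefix `partOf:`).
#'
#' @param x character vector of CURIEs.
#' @return `curie_prefix`/`curie_local`: character vectors; `is_curie`:
#'   logical vector.
#' @export
curie_prefix <- function(x) sub(":.*$", "", x)

#' @rdname curie_prefix
#' @export
curie_local <- function(x) sub("^[^:]*:", "", x)

#' @rdname curie_prefix
#' @export
is_curie <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9_.-]*:[^ \t\n<>\"]*$", x)
}

#' @rdname curie_prefix
#' @param prefix,local components to assemble.
#' @export
make_curie <- function(prefix, local) paste0(prefix, ":", local)

ANATOMICAL_PREFIXES <- c("UBERON", "ILX")

#' Check that a CURIE is a legal anatomical identifier
#'
#' Anatomical structures are restricted to UBERON and InterLex (ILX)
#' namespaces; terms from other ontologies are expected to be imported and
#' assigned an ILX identifier upstream.
#'
#' @param x character vector of CURIEs.
#' @return logical vector.
#' @export
is_anatomical_curie <- function(x) {
  is_curie(x) & curie_prefix(x) %in% ANATOMICAL_PREFIXES
}

#' Expand a CURIE to a full IRI / contract an IRI to a CURIE
#'
#' @param x CURIE (for `curie_to_iri`) or IRI (for `iri_to_curie`).
#' @param prefixes prefix registry, as from [default_prefixes()].
#' @return character vector; `iri_to_curie` leaves IRIs with no registered
#'   prefix unchanged.
#' @export
curie_to_iri <- function(x, prefixes = default_prefixes()) {
  pre <- curie_prefix(x)
  unknown <- setdiff(unique(pre), names(prefixes))
  if (length(unknown)) {
    stop("undeclared prefix(es): ", paste(unknown, collapse = ", "))
  }
  paste0(unname(prefixes[pre]), curie_local(x))
}

#' @rdname curie_to_iri
#' @export
iri_to_curie <- function(x, prefixes = default_prefixes()) {
  # longest-base-first so e.g. an "ilxtr" base never shadows a longer one
  ord <- order(nchar(prefixes), decreasing = TRUE)
  out <- x
  for (i in ord) {
    base <- prefixes[[i]]
    hit <- startsWith(out, base) & out == x   # only rewrite untouched entries
    out[hit] <- paste0(names(prefixes)[i], ":",
                       substring(x[hit], nchar(base) + 1L))
  }
  out
}
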