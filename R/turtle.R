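#' Turtle reading and writing primitives
#'
#' A self-contained reader and writer for the Turtle subset used by the two
#' connectivity dialects: prefix declarations, prefixed names (including
#' empty local parts such as `partOf:`), full IRIs, string literals,
#' blank-node property lists `[ ... ]`, RDF collections `( ... )`, the `a`
#' keyword, comments, and `;`/`,` predicate-object lists. Collections and
#' blank-node property lists are expanded to plain triples over generated
#' blank-node identifiers (`_:b1`, ...), so downstream code works on a flat
#' triple table. No R RDF library is available in the supported toolchain,
#' so this subset is implemented natively; it is deliberately limited to
#' the constructs the dialects use (no language tags, no numeric literals,
#' no `@base`).
#'
#' @name turtle
NULL

RDF_FIRST <- "rdf:first"
RDF_REST  <- "rdf:rest"
RDF_NIL   <- "rdf:nil"
RDF_TYPE  <- "rdf:type"

ttl_tokenize <- function(text) {
  pattern <- paste0(
    '"(?:[^"\\\\]|\\\\.)*"',                     # string literal
    "|<[^>]*>",                                  # IRI ref
    "|#[^\n]*",                                  # comment
    "|@prefix",
    "|\\^\\^",
    "|[;,.()\\[\\]]",
    "|[A-Za-z][A-Za-z0-9_.\\-]*:[A-Za-z0-9_.\\-]*",  # prefixed name
    "|[A-Za-z][A-Za-z0-9_\\-]*",                 # bare word (a, ...)
    "|\\S"                                       # anything else -> error
  )
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(character())
  toks <- regmatches(text, list(m))[[1]]
  toks <- toks[!startsWith(toks, "#")]
  # a prefixed name must not end in '.' -- detach statement-final dots
  out <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    t <- toks[i]
    if (grepl("^[A-Za-z]", t) && grepl(":", t, fixed = TRUE)) {
      dots <- 0L
      while (endsWith(t, ".")) {
        t <- substr(t, 1L, nchar(t) - 1L)
        dots <- dots + 1L
      }
      out[[i]] <- c(t, rep(".", dots))
    } else {
      out[[i]] <- t
    }
  }
  unlist(out, use.names = FALSE)
}

ttl_unescape <- function(s) {
  s <- substr(s, 2L, nchar(s) - 1L)
  s <- gsub('\\\\"', '"', s)
  gsub("\\\\\\\\", "\\\\", s)
}

ttl_escape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  gsub('"', '\\\\"', s)
}

#' Parse a Turtle document into a flat triple table
#'
#' @param text Turtle source, as a single string or character vector of
#'   lines.
#' @param prefixes fallback prefix registry used to contract full IRIs;
#'   `@prefix` declarations inside the document extend/override it.
#' @return list with elements `triples` (data.frame `s`, `p`, `o`,
#'   `o_is_literal`) and `prefixes` (the effective registry). All IRIs are
#'   contracted to CURIEs where a prefix is known; blank nodes appear as
#'   `_:b<n>` identifiers.
#' @export
ttl_parse <- function(text, prefixes = default_prefixes()) {
  text <- paste(text, collapse = "\n")
  toks <- ttl_tokenize(text)
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$i <- 1L
  env$n <- length(toks)
  env$bn <- 0L
  env$prefixes <- prefixes
  env$s <- character(); env$p <- character(); env$o <- character()
  env$lit <- logical()

  peek <- function() if (env$i <= env$n) env$toks[env$i] else NA_character_
  advance <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of Turtle input")
    env$i <- env$i + 1L
    t
  }
  expect <- function(tok) {
    t <- advance()
    if (!identical(t, tok)) {
      stop("Turtle parse error near token ", env$i - 1L, ": expected '",
           tok, "', got '", t, "'")
    }
  }
  fresh_bnode <- function() {
    env$bn <- env$bn + 1L
    paste0("_:b", env$bn)
  }
  emit <- function(s, p, o, is_lit = FALSE) {
    env$s <- c(env$s, s); env$p <- c(env$p, p); env$o <- c(env$o, o)
    env$lit <- c(env$lit, is_lit)
  }
  contract <- function(iri) iri_to_curie(iri, env$prefixes)

  is_pname <- function(t) {
    grepl("^[A-Za-z][A-Za-z0-9_.\\-]*:", t) && !startsWith(t, "<")
  }

  parse_verb <- function() {
    t <- advance()
    if (identical(t, "a")) return(RDF_TYPE)
    if (startsWith(t, "<")) return(contract(substr(t, 2L, nchar(t) - 1L)))
    if (is_pname(t)) return(t)
    stop("Turtle parse error: expected predicate, got '", t, "'")
  }

  # returns list(term=, lit=) and emits triples for nested structures
  parse_term <- function() {
    t <- advance()
    if (startsWith(t, "\"")) {
      # optional datatype annotation, discarded
      if (identical(peek(), "^^")) { advance(); advance() }
      return(list(term = ttl_unescape(t), lit = TRUE))
    }
    if (startsWith(t, "<")) {
      return(list(term = contract(substr(t, 2L, nchar(t) - 1L)), lit = FALSE))
    }
    if (identical(t, "[")) {
      node <- fresh_bnode()
      if (!identical(peek(), "]")) parse_predicate_object_list(node)
      expect("]")
      return(list(term = node, lit = FALSE))
    }
    if (identical(t, "(")) {
      items <- list()
      while (!identical(peek(), ")")) {
        items[[length(items) + 1L]] <- parse_term()
      }
      expect(")")
      if (length(items) == 0L) return(list(term = RDF_NIL, lit = FALSE))
      head <- fresh_bnode()
      node <- head
      for (k in seq_along(items)) {
        emit(node, RDF_FIRST, items[[k]]$term, items[[k]]$lit)
        nxt <- if (k < length(items)) fresh_bnode() else RDF_NIL
        emit(node, RDF_REST, nxt)
        node <- nxt
      }
      return(list(term = head, lit = FALSE))
    }
    if (is_pname(t)) return(list(term = t, lit = FALSE))
    stop("Turtle parse error: unexpected token '", t, "'")
  }

  parse_predicate_object_list <- function(subject) {
    repeat {
      p <- parse_verb()
      repeat {
        obj <- parse_term()
        emit(subject, p, obj$term, obj$lit)
        if (identical(peek(), ",")) advance() else break
      }
      if (identical(peek(), ";")) {
        advance()
        # tolerate trailing ';' before '.' or ']'
        if (identical(peek(), ".") || identical(peek(), "]")) break
      } else break
    }
  }

  while (env$i <= env$n) {
    t <- peek()
    if (identical(t, "@prefix")) {
      advance()
      label <- advance()            # e.g. "ilxtr:"
      if (!endsWith(label, ":")) stop("bad @prefix label: ", label)
      iri <- advance()
      if (!startsWith(iri, "<")) stop("bad @prefix IRI: ", iri)
      env$prefixes[[substr(label, 1L, nchar(label) - 1L)]] <-
        substr(iri, 2L, nchar(iri) - 1L)
      expect(".")
    } else {
      subj <- parse_term()
      if (subj$lit) stop("literal cannot be a subject")
      # a blank-node property list may stand alone as a whole statement
      if (!identical(peek(), ".")) parse_predicate_object_list(subj$term)
      expect(".")
    }
  }

  list(
    triples = data.frame(s = env$s, p = env$p, o = env$o,
                         o_is_literal = env$lit, stringsAsFactors = FALSE),
    prefixes = env$prefixes
  )
}

# Walk an rdf:first/rdf:rest chain; returns list of list(term=, lit=).
rdf_list_items <- function(triples, head) {
  items <- list()
  node <- head
  seen <- character()
  while (!identical(node, RDF_NIL)) {
    if (node %in% seen) stop("cyclic RDF collection at ", node)
    seen <- c(seen, node)
    fi <- which(triples$s == node & triples$p == RDF_FIRST)
    re <- which(triples$s == node & triples$p == RDF_REST)
    if (length(fi) != 1L || length(re) != 1L) {
      stop("malformed RDF collection at node ", node)
    }
    items[[length(items) + 1L]] <- list(term = triples$o[fi],
                                        lit = triples$o_is_literal[fi])
    node <- triples$o[re]
  }
  items
}

# objects of (s, p), in table order
tt_objects <- function(triples, s, p) {
  triples$o[triples$s == s & triples$p == p]
}

ttl_prefix_block <- function(prefixes) {
  paste0("@prefix ", names(prefixes), ": <", unname(prefixes), "> .")
}

ttl_term <- function(x, lit = FALSE) {
  if (lit) paste0('"', ttl_escape(x), '"') else x
}
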