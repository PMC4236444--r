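## Subsumption, obsolescence and replacement reasoning over an
## OntologyGraph. Reasoning uses only is_a transitivity; edges leaving an
## obsolete term are ignored and obsolete terms never appear in results.

## children adjacency restricted to reasoning edges (child not obsolete)
reasoningChildren <- function(graph) {
  e <- graph@edges
  if (!nrow(e)) return(list())
  obsolete <- names(graph@terms)[vapply(graph@terms, function(t) t@isObsolete,
                                        logical(1))]
  keep <- !(e[, "child"] %in% obsolete)
  e <- e[keep, , drop = FALSE]
  split(e[, "child"], e[, "parent"])
}

#' Descendants of a term
#'
#' All terms reachable from \code{rootId} by following \code{is_a} edges
#' downward (reflexive-transitive when \code{includeSelf}). Obsolete terms
#' take no part: they are excluded from the result and their own
#' \code{is_a} edges are not traversed.
#'
#' @param graph an \code{\linkS4class{OntologyGraph}}.
#' @param rootId id of the subtree root; must exist in the graph.
#' @param includeSelf should \code{rootId} itself be included (if not
#'   obsolete)?
#' @return character vector of term ids (unordered set semantics).
#' @export
#' @examples
#' g <- parseOBO(c("[Term]", "id: A", "", "[Term]", "id: B", "is_a: A"))
#' descendants(g, "A", includeSelf = TRUE)
descendants <- function(graph, rootId, includeSelf = FALSE) {
  stopifnot(is(graph, "OntologyGraph"))
  if (!rootId %in% names(graph@terms)) {
    eqStop("eq_missing_term_error", "term '%s' not in graph", rootId)
  }
  kids <- reasoningChildren(graph)
  seen <- character(0)
  queue <- rootId
  while (length(queue)) {
    n <- queue[[1L]]
    queue <- queue[-1L]
    below <- setdiff(kids[[n]], seen)
    seen <- c(seen, below)
    queue <- c(queue, below)
  }
  out <- if (includeSelf) unique(c(rootId, seen)) else setdiff(seen, rootId)
  obsolete <- vapply(graph@terms[out], function(t) t@isObsolete, logical(1))
  out[!obsolete]
}

#' Is one term subsumed by another?
#'
#' \code{TRUE} iff \code{termId} is \code{rootId} itself or reachable from
#' it via \code{is_a} descent (obsolete terms never qualify).
#'
#' @inheritParams descendants
#' @param termId candidate descendant id; must exist in the graph.
#' @return logical(1).
#' @export
isDescendant <- function(graph, termId, rootId) {
  if (!termId %in% names(graph@terms)) {
    eqStop("eq_missing_term_error", "term '%s' not in graph", termId)
  }
  termId %in% descendants(graph, rootId, includeSelf = TRUE)
}

#' Follow replaced_by links to a terminal id
#'
#' Obsolete and resolved-provisional terms carry \code{replaced_by}
#' metadata naming their successor; migration follows these transitively —
#' whether they stem from ordinary ontology maintenance or from
#' provisional-term resolution — until a term with no replacement is
#' reached. A term with no replacement resolves to itself. When a term
#' lists several replacements the first is followed and a warning is
#' raised (the provisional workflow yields exactly one permanent id per
#' term, so multiplicity is an out-of-band ontology event).
#'
#' @inheritParams descendants
#' @param termId id to resolve; must exist in the graph.
#' @return character(1): the terminal replacement id.
#' @section Errors: a replacement cycle (the visited ids are listed) and a
#'   \code{replaced_by} target absent from the graph are errors.
#' @export
resolveReplacement <- function(graph, termId) {
  stopifnot(is(graph, "OntologyGraph"))
  if (!termId %in% names(graph@terms)) {
    eqStop("eq_missing_term_error", "term '%s' not in graph", termId)
  }
  visited <- character(0)
  cur <- termId
  repeat {
    if (cur %in% visited) {
      eqStop("eq_cycle_error", "replaced_by cycle: %s",
             paste(c(visited, cur), collapse = " -> "))
    }
    visited <- c(visited, cur)
    term <- graph@terms[[cur]]
    if (!length(term@replacedBy)) {
      return(cur)
    }
    if (length(term@replacedBy) > 1L) {
      eqWarn("eq_multiple_replacements_warning",
             "term '%s' lists %d replacements; following the first ('%s')",
             cur, length(term@replacedBy), term@replacedBy[[1L]])
    }
    nxt <- term@replacedBy[[1L]]
    if (!nxt %in% names(graph@terms)) {
      eqStop("eq_dangling_replacement_error",
             "replaced_by target '%s' (from '%s') not in graph", nxt, cur)
    }
    cur <- nxt
  }
}

#' Merge provisional term requests into an ontology session
#'
#' Each pending request becomes a provisional \code{\linkS4class{Term}},
#' available for use in annotations; its suggested superclass contributes
#' an \code{is_a} edge when that superclass is present in the graph. Each
#' resolved request becomes an obsolete provisional term whose
#' \code{replaced_by} names the permanent id, so that ordinary
#' replacement-following migrates annotations. A permanent id not present
#' in the graph is materialised as a placeholder term (resolution to a
#' term outside the loaded ontology slice is legitimate). Merging the same
#' request list twice is a no-op.
#'
#' @inheritParams descendants
#' @param requests list of \code{\linkS4class{ProvisionalRequest}}.
#' @return the merged \code{\linkS4class{OntologyGraph}}.
#' @section Errors: a provisional id colliding with an existing
#'   non-provisional term is an error.
#' @export
mergeProvisional <- function(graph, requests) {
  stopifnot(is(graph, "OntologyGraph"))
  terms <- graph@terms
  edges <- graph@edges
  for (req in requests) {
    stopifnot(is(req, "ProvisionalRequest"))
    pid <- req@provisionalId
    if (pid %in% names(terms) && !terms[[pid]]@isProvisional) {
      eqStop("eq_collision_error",
             "provisional id '%s' collides with a non-provisional term", pid)
    }
    resolved <- !is.na(req@permanentId)
    terms[[pid]] <- new("Term",
      id = pid,
      label = req@label,
      definition = req@definition,
      synonyms = lapply(req@synonyms, function(s) list(text = s, scope = "EXACT")),
      isObsolete = resolved,
      replacedBy = if (resolved) req@permanentId else character(0),
      isProvisional = TRUE
    )
    if (resolved && !req@permanentId %in% names(terms)) {
      terms[[req@permanentId]] <- new("Term", id = req@permanentId,
                                      isPlaceholder = TRUE)
    }
    super <- req@suggestedSuperclass
    if (!is.null(super) && super@id %in% names(terms)) {
      edges <- unique(rbind(edges, c(pid, super@id)))
    }
  }
  colnames(edges) <- c("child", "parent")
  new("OntologyGraph", terms = terms, edges = edges)
}

#' Union of several ontology graphs
#'
#' Consistency checking reasons over one graph; a study typically loads an
#' anatomy ontology, a quality ontology, a process ontology and a taxonomy.
#' Terms must not clash across inputs, except that a placeholder is
#' superseded by a real definition of the same id.
#'
#' @param ... \code{\linkS4class{OntologyGraph}} objects.
#' @return one merged \code{\linkS4class{OntologyGraph}}.
#' @export
combineGraphs <- function(...) {
  graphs <- list(...)
  if (length(graphs) == 1L && is.list(graphs[[1L]]) &&
      !is(graphs[[1L]], "OntologyGraph")) {
    graphs <- graphs[[1L]]
  }
  terms <- list()
  edges <- matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("child", "parent")))
  for (g in graphs) {
    stopifnot(is(g, "OntologyGraph"))
    for (id in names(g@terms)) {
      t <- g@terms[[id]]
      if (id %in% names(terms)) {
        have <- terms[[id]]
        if (have@isPlaceholder) {
          terms[[id]] <- t
        } else if (!t@isPlaceholder) {
          eqStop("eq_collision_error",
                 "term id '%s' defined in more than one graph", id)
        }
      } else {
        terms[[id]] <- t
      }
    }
    edges <- unique(rbind(edges, g@edges))
  }
  new("OntologyGraph", terms = terms, edges = edges)
}
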