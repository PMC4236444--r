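## Generics and simple accessors. Slot access from user code goes through
## these, never through `@`.

#' Term map of an ontology graph
#' @param x an \code{\linkS4class{OntologyGraph}}.
#' @return named list of \code{\linkS4class{Term}}.
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' @rdname ontologyTerms
#' @export
setMethod("ontologyTerms", "OntologyGraph", function(x) x@terms)

#' Term ids present in a graph
#' @param x an \code{\linkS4class{OntologyGraph}}.
#' @return character vector of ids.
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname termIds
#' @export
setMethod("termIds", "OntologyGraph", function(x) names(x@terms))

#' is_a edges of a graph
#' @param x an \code{\linkS4class{OntologyGraph}}.
#' @return two-column character matrix (child, parent).
#' @export
setGeneric("isaEdges", function(x) standardGeneric("isaEdges"))

#' @rdname isaEdges
#' @export
setMethod("isaEdges", "OntologyGraph", function(x) x@edges)

#' Fetch one term by id
#' @param x an \code{\linkS4class{OntologyGraph}}.
#' @param id term id.
#' @return a \code{\linkS4class{Term}}.
#' @export
setGeneric("getTerm", function(x, id) standardGeneric("getTerm"))

#' @rdname getTerm
#' @export
setMethod("getTerm", "OntologyGraph", function(x, id) {
  if (!id %in% names(x@terms)) {
    eqStop("eq_missing_term_error", "term '%s' not in graph", id)
  }
  x@terms[[id]]
})

#' Taxa of a study document
#' @param x a \code{\linkS4class{StudyDocument}}.
#' @return list of \code{\linkS4class{Taxon}}.
#' @export
setGeneric("docTaxa", function(x) standardGeneric("docTaxa"))

#' @rdname docTaxa
#' @export
setMethod("docTaxa", "StudyDocument", function(x) x@taxa)

#' Characters of a study document
#' @param x a \code{\linkS4class{StudyDocument}}.
#' @return list of \code{\linkS4class{MatrixCharacter}}.
#' @export
setGeneric("docCharacters", function(x) standardGeneric("docCharacters"))

#' @rdname docCharacters
#' @export
setMethod("docCharacters", "StudyDocument", function(x) x@characters)

#' Document-level source metadata
#' @param x a \code{\linkS4class{StudyDocument}}.
#' @return named list of strings.
#' @export
setGeneric("sourceMetadata", function(x) standardGeneric("sourceMetadata"))

#' @rdname sourceMetadata
#' @export
setMethod("sourceMetadata", "StudyDocument", function(x) x@sourceMetadata)

#' Read one matrix cell
#' @param x a \code{\linkS4class{StudyDocument}}.
#' @param taxonIndex,characterIndex 1-based indices.
#' @return character vector of state symbols, or \code{NULL} if unscored.
#' @export
setGeneric("cellValue", function(x, taxonIndex, characterIndex)
  standardGeneric("cellValue"))

#' @rdname cellValue
#' @export
setMethod("cellValue", "StudyDocument", function(x, taxonIndex, characterIndex) {
  x@cells[[cellKey(x, taxonIndex, characterIndex)]]
})

#' Replacements of a migration report
#' @param x a \code{\linkS4class{MigrationReport}}.
#' @return named list: old id -> list(new_id, count).
#' @export
setGeneric("replacements", function(x) standardGeneric("replacements"))

#' @rdname replacements
#' @export
setMethod("replacements", "MigrationReport", function(x) x@replacements)

#' Pending provisional ids untouched by a migration
#' @param x a \code{\linkS4class{MigrationReport}}.
#' @return character vector of provisional ids.
#' @export
setGeneric("untouchedProvisional", function(x)
  standardGeneric("untouchedProvisional"))

#' @rdname untouchedProvisional
#' @export
setMethod("untouchedProvisional", "MigrationReport", function(x)
  x@untouchedProvisional)

#' Current document of an edit session
#' @param x an \code{\linkS4class{EditSession}}.
#' @return the session's \code{\linkS4class{StudyDocument}}.
#' @export
setGeneric("sessionDocument", function(x) standardGeneric("sessionDocument"))

#' @rdname sessionDocument
#' @export
setMethod("sessionDocument", "EditSession", function(x) x@document)

#' Does a session hold unsaved edits?
#' @param x an \code{\linkS4class{EditSession}}.
#' @return logical(1).
#' @export
setGeneric("isDirty", function(x) standardGeneric("isDirty"))

#' @rdname isDirty
#' @export
setMethod("isDirty", "EditSession", function(x) x@dirty)

#' Provisional-request accessors
#' @param x a \code{\linkS4class{ProvisionalRequest}}.
#' @return \code{provisionalId}/\code{permanentId}: character(1);
#'   \code{isPending}: logical(1).
#' @export
setGeneric("provisionalId", function(x) standardGeneric("provisionalId"))

#' @rdname provisionalId
#' @export
setMethod("provisionalId", "ProvisionalRequest", function(x) x@provisionalId)

#' @rdname provisionalId
#' @export
setGeneric("permanentId", function(x) standardGeneric("permanentId"))

#' @rdname provisionalId
#' @export
setMethod("permanentId", "ProvisionalRequest", function(x) x@permanentId)

#' @rdname provisionalId
#' @export
setGeneric("isPending", function(x) standardGeneric("isPending"))

#' @rdname provisionalId
#' @export
setMethod("isPending", "ProvisionalRequest", function(x) is.na(x@permanentId))

#' Fixture-bundle accessors
#' @param x a \code{\linkS4class{FixtureBundle}}.
#' @return the corresponding component.
#' @export
setGeneric("bundleDocument", function(x) standardGeneric("bundleDocument"))

#' @rdname bundleDocument
#' @export
setMethod("bundleDocument", "FixtureBundle", function(x) x@document)

#' @rdname bundleDocument
#' @export
setGeneric("expectedIssues", function(x) standardGeneric("expectedIssues"))

#' @rdname bundleDocument
#' @export
setMethod("expectedIssues", "FixtureBundle", function(x) x@expectedIssues)

#' @rdname bundleDocument
#' @export
setGeneric("bundleRuleConfig", function(x) standardGeneric("bundleRuleConfig"))

#' @rdname bundleDocument
#' @export
setMethod("bundleRuleConfig", "FixtureBundle", function(x) x@ruleConfig)

#' @rdname bundleDocument
#' @export
setGeneric("bundleGraphs", function(x) standardGeneric("bundleGraphs"))

#' @rdname bundleDocument
#' @export
setMethod("bundleGraphs", "FixtureBundle", function(x) {
  list(anatomy = x@anatomyGraph, quality = x@qualityGraph,
       process = x@processGraph, taxonomy = x@taxonomyGraph)
})
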