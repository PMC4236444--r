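## StudyDocument editing primitives and term-id migration.

cellKey <- function(doc, taxonIndex, characterIndex) {
  taxonIndex <- as.integer(taxonIndex)
  characterIndex <- as.integer(characterIndex)
  if (is.na(taxonIndex) || taxonIndex < 1L || taxonIndex > length(doc@taxa)) {
    eqStop("eq_value_error", "taxon index %s out of range", taxonIndex)
  }
  if (is.na(characterIndex) || characterIndex < 1L ||
      characterIndex > length(doc@characters)) {
    eqStop("eq_value_error", "character index %s out of range", characterIndex)
  }
  sprintf("%d_%d", taxonIndex, characterIndex)
}

stateSymbols <- function(ch) {
  vapply(ch@states, function(s) s@symbol, character(1))
}

## canonical cell-map ordering (taxon-major), so that documents reached by
## different edit orders compare deep-equal
orderCells <- function(doc) {
  keys <- names(doc@cells)
  if (length(keys) < 2L) return(doc)
  parts <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  doc@cells <- doc@cells[order(as.integer(parts[, 1L]),
                               as.integer(parts[, 2L]))]
  doc
}

#' Score a matrix cell
#'
#' Records the state symbol(s) of a taxon for a character. Polymorphic
#' cells are sets of more than one symbol; a single score is a singleton
#' set. Symbols are stored sorted (set semantics).
#'
#' @param doc a \code{\linkS4class{StudyDocument}}.
#' @param taxonIndex,characterIndex 1-based indices.
#' @param symbols character vector of state symbols, all defined for that
#'   character.
#' @return the updated document.
#' @export
#' @examples
#' doc <- studyDocument(list(taxon("Danio rerio")),
#'                      list(matrixCharacter("fin", c("0", "1"))))
#' doc <- setCell(doc, 1, 1, "0")
#' cellValue(doc, 1, 1)
setCell <- function(doc, taxonIndex, characterIndex, symbols) {
  stopifnot(is(doc, "StudyDocument"))
  key <- cellKey(doc, taxonIndex, characterIndex)
  symbols <- unique(as.character(symbols))
  if (!length(symbols)) {
    eqStop("eq_value_error", "a cell needs at least one symbol")
  }
  ch <- doc@characters[[as.integer(characterIndex)]]
  bad <- setdiff(symbols, stateSymbols(ch))
  if (length(bad)) {
    eqStop("eq_value_error",
           "symbol(s) %s not defined for character %d ('%s')",
           paste(sQuote(bad, q = FALSE), collapse = ", "),
           as.integer(characterIndex), ch@label)
  }
  doc@cells[[key]] <- sort(symbols)
  validObject(doc)
  orderCells(doc)
}

#' Clear a matrix cell (mark unscored)
#' @inheritParams setCell
#' @return the updated document.
#' @export
clearCell <- function(doc, taxonIndex, characterIndex) {
  key <- cellKey(doc, taxonIndex, characterIndex)
  doc@cells[[key]] <- NULL
  doc
}

#' Attach an EQ annotation to a character state
#'
#' Appends \code{ann} to the state's annotation list; a state may carry any
#' number of annotations and their order is preserved. The reserved missing
#' symbol \code{"?"} may never be annotated.
#'
#' @param doc a \code{\linkS4class{StudyDocument}}.
#' @param characterIndex 1-based character index.
#' @param stateSymbol symbol of an existing state of that character.
#' @param ann an \code{\link{eqAnnotation}}.
#' @return the updated document.
#' @export
annotateState <- function(doc, characterIndex, stateSymbol, ann) {
  stopifnot(is(doc, "StudyDocument"), is(ann, "EQAnnotation"))
  characterIndex <- as.integer(characterIndex)
  if (characterIndex < 1L || characterIndex > length(doc@characters)) {
    eqStop("eq_value_error", "character index %s out of range", characterIndex)
  }
  ch <- doc@characters[[characterIndex]]
  pos <- match(stateSymbol, stateSymbols(ch))
  if (is.na(pos)) {
    eqStop("eq_value_error", "character %d ('%s') has no state '%s'",
           characterIndex, ch@label, stateSymbol)
  }
  if (identical(stateSymbol, "?")) {
    eqStop("eq_value_error",
           "the reserved missing symbol '?' may not be annotated")
  }
  st <- ch@states[[pos]]
  st@annotations <- c(st@annotations, list(ann))
  ch@states[[pos]] <- st
  doc@characters[[characterIndex]] <- ch
  doc
}

#' Replace a state's annotation list
#' @inheritParams annotateState
#' @param annotations list of \code{\link{eqAnnotation}} (may be empty).
#' @return the updated document.
#' @export
setStateAnnotations <- function(doc, characterIndex, stateSymbol, annotations) {
  stopifnot(is(doc, "StudyDocument"))
  characterIndex <- as.integer(characterIndex)
  ch <- doc@characters[[characterIndex]]
  pos <- match(stateSymbol, stateSymbols(ch))
  if (is.na(pos)) {
    eqStop("eq_value_error", "character %d ('%s') has no state '%s'",
           characterIndex, ch@label, stateSymbol)
  }
  st <- ch@states[[pos]]
  st@annotations <- annotations
  validObject(st)
  ch@states[[pos]] <- st
  doc@characters[[characterIndex]] <- ch
  doc
}

## visit every TermRef position in a document; fn(ref) -> ref
mapTermRefs <- function(doc, fn) {
  doc@taxa <- lapply(doc@taxa, function(tx) {
    if (!is.null(tx@taxonomyRef)) tx@taxonomyRef <- fn(tx@taxonomyRef)
    tx
  })
  doc@characters <- lapply(doc@characters, function(ch) {
    ch@states <- lapply(ch@states, function(st) {
      st@annotations <- lapply(st@annotations, function(ann) {
        if (!is.null(ann@entity)) ann@entity <- fn(ann@entity)
        if (!is.null(ann@quality)) ann@quality <- fn(ann@quality)
        if (!is.null(ann@relatedEntity)) ann@relatedEntity <- fn(ann@relatedEntity)
        ann
      })
      st
    })
    ch
  })
  doc
}

#' All term ids referenced by a document
#' @param doc a \code{\linkS4class{StudyDocument}}.
#' @return character vector of distinct ids (taxonomy, entity, quality,
#'   related-entity positions).
#' @export
documentTermIds <- function(doc) {
  ids <- character(0)
  mapTermRefs(doc, function(ref) {
    ids <<- c(ids, ref@id)
    ref
  })
  unique(ids)
}

#' Migrate term references through a resolver
#'
#' Rewrites every term reference in the document (entity, quality,
#' related-entity and taxonomy positions) to \code{resolver(id)}. The
#' resolver must be total over the ids appearing in the document (identity
#' for ids it does not know). A rewritten reference drops its cached label,
#' which belonged to the old term. The document is otherwise unchanged, and
#' migrating a second time with the same resolver rewrites nothing.
#'
#' @param doc a \code{\linkS4class{StudyDocument}}.
#' @param resolver function(character id) -> character id.
#' @return \code{list(document=, report=)} where \code{report} is a
#'   \code{\linkS4class{MigrationReport}} listing each changed id with its
#'   rewrite count.
#' @seealso \code{\link{syncAndMigrate}}, \code{\link{resolveReplacement}}
#' @export
applyTermMigration <- function(doc, resolver) {
  stopifnot(is(doc, "StudyDocument"), is.function(resolver))
  counts <- list()
  out <- mapTermRefs(doc, function(ref) {
    new_id <- resolver(ref@id)
    stopifnot(is.character(new_id), length(new_id) == 1L, nzchar(new_id))
    if (!identical(new_id, ref@id)) {
      entry <- counts[[ref@id]]
      if (is.null(entry)) entry <- list(new_id = new_id, count = 0L)
      entry$count <- entry$count + 1L
      counts[[ref@id]] <<- entry
      ref <- termRef(new_id)
    }
    ref
  })
  if (!length(counts)) counts <- structure(list(), names = character(0))
  report <- new("MigrationReport", replacements = counts,
                untouchedProvisional = character(0))
  list(document = out, report = report)
}
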