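#' @import methods
NULL

## ---------------------------------------------------------------------------
## Ontology layer
## ---------------------------------------------------------------------------

#' Term: one ontology class
#'
#' A single ontology term as parsed from an OBO \code{[Term]} stanza or
#' minted from a provisional request. Identifiers are CURIEs
#' (\code{"PATO:0001236"}) or full URIs; equality is exact string equality.
#'
#' @slot id character(1), CURIE or URI; non-empty, unique within a graph.
#' @slot label character(1), the \code{name} tag (may be \code{NA}).
#' @slot definition character(1) or \code{NA}.
#' @slot synonyms list of \code{list(text=, scope=)} where scope is one of
#'   \code{EXACT}, \code{BROAD}, \code{NARROW}, \code{RELATED}.
#' @slot isObsolete logical(1); obsolete terms take no part in subsumption.
#' @slot replacedBy character vector of successor ids (non-empty only for
#'   obsolete or resolved provisional terms).
#' @slot namespace character(1) or \code{NA}.
#' @slot isProvisional logical(1); \code{TRUE} for broker-minted terms.
#' @slot isPlaceholder logical(1); \code{TRUE} for terms created to stand in
#'   for a referenced but unloaded id (dangling \code{is_a} parent or a
#'   permanent id outside the loaded slice); flagged incomplete, never
#'   silently dropped.
#'
#' @export
setClass("Term",
  representation(
    id = "character",
    label = "character",
    definition = "character",
    synonyms = "list",
    isObsolete = "logical",
    replacedBy = "character",
    namespace = "character",
    isProvisional = "logical",
    isPlaceholder = "logical"
  ),
  prototype(
    label = NA_character_,
    definition = NA_character_,
    synonyms = list(),
    isObsolete = FALSE,
    replacedBy = character(0),
    namespace = NA_character_,
    isProvisional = FALSE,
    isPlaceholder = FALSE
  )
)

setValidity("Term", function(object) {
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id)) {
    return("id must be a single non-empty string")
  }
  if (length(object@replacedBy) > 0L &&
      !(object@isObsolete || object@isProvisional)) {
    return("replacedBy may be non-empty only for obsolete or provisional terms")
  }
  scopes <- vapply(object@synonyms, function(s) s$scope, character(1))
  if (length(scopes) && !all(scopes %in% c("EXACT", "BROAD", "NARROW", "RELATED"))) {
    return("synonym scope must be EXACT, BROAD, NARROW or RELATED")
  }
  TRUE
})

#' OntologyGraph: terms plus is_a edges
#'
#' The reasoning substrate for all consistency rules: a map of id to
#' \code{\linkS4class{Term}} plus a set of directed \code{is_a} edges
#' (child, parent). The edge relation is verified acyclic; edges leaving an
#' obsolete term are ignored by reasoning.
#'
#' @slot terms named list of \code{\linkS4class{Term}}, names equal ids.
#' @slot edges two-column character matrix (\code{child}, \code{parent});
#'   endpoints must exist in \code{terms} (dangling parents are materialised
#'   as placeholder terms at parse time, never dropped).
#'
#' @seealso \code{\link{parseOBO}}, \code{\link{descendants}},
#'   \code{\link{resolveReplacement}}
#' @export
setClass("OntologyGraph",
  representation(terms = "list", edges = "matrix"),
  prototype(
    terms = structure(list(), names = character(0)),
    edges = matrix(character(0), ncol = 2L,
                   dimnames = list(NULL, c("child", "parent")))
  )
)

setValidity("OntologyGraph", function(object) {
  ids <- names(object@terms)
  if (length(object@terms) &&
      (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))) {
    return("terms must be uniquely named by non-empty ids")
  }
  for (i in seq_along(object@terms)) {
    t <- object@terms[[i]]
    if (!is(t, "Term")) return("terms must contain Term objects")
    if (t@id != ids[i]) return("term list names must equal term ids")
  }
  e <- object@edges
  if (!is.character(e) || ncol(e) != 2L) {
    return("edges must be a two-column character matrix")
  }
  if (nrow(e)) {
    missing <- setdiff(c(e[, 1L], e[, 2L]), ids)
    if (length(missing)) {
      return(paste0("edge endpoints not in terms: ",
                    paste(missing, collapse = ", ")))
    }
    cyc <- findCycle(e)
    if (!is.null(cyc)) {
      return(paste0("is_a cycle: ", paste(cyc, collapse = " -> ")))
    }
  }
  TRUE
})

## Kahn's algorithm; returns NULL if acyclic, else one cycle's node ids.
findCycle <- function(edges) {
  nodes <- unique(c(edges[, 1L], edges[, 2L]))
  if (!length(nodes)) return(NULL)
  indeg <- table(factor(edges[, 2L], levels = nodes))
  ## edge child -> parent: treat parent as having in-degree from child
  remaining <- edges
  queue <- nodes[indeg[nodes] == 0L]
  seen <- character(0)
  indeg <- as.integer(indeg[nodes])
  names(indeg) <- nodes
  while (length(queue)) {
    n <- queue[[1L]]
    queue <- queue[-1L]
    seen <- c(seen, n)
    out <- remaining[, 1L] == n
    for (p in remaining[out, 2L]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
    remaining <- remaining[!out, , drop = FALSE]
  }
  if (length(seen) == length(nodes)) return(NULL)
  ## extract one cycle among the unprocessed nodes
  left <- setdiff(nodes, seen)
  start <- left[[1L]]
  path <- start
  cur <- start
  repeat {
    nxt <- edges[edges[, 1L] == cur, 2L]
    nxt <- intersect(nxt, left)[1L]
    if (nxt %in% path) {
      return(c(path[which(path == nxt):length(path)], nxt))
    }
    path <- c(path, nxt)
    cur <- nxt
  }
}

#' TermRef: a reference to an ontology term
#'
#' Annotations hold references, not terms: an id plus an optional cached
#' display label (the label may be stale relative to the loaded ontology).
#'
#' @slot id character(1) non-empty CURIE or URI.
#' @slot label character(1) cached label, or \code{NA}.
#' @export
setClass("TermRef",
  representation(id = "character", label = "character"),
  prototype(label = NA_character_)
)

setValidity("TermRef", function(object) {
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id)) {
    return("id must be a single non-empty string")
  }
  if (length(object@label) != 1L) return("label must be length 1")
  TRUE
})

setClassUnion("TermRefOrNULL", c("TermRef", "NULL"))

#' Construct a TermRef
#' @param id term id (CURIE or URI).
#' @param label optional cached display label.
#' @return a \code{\linkS4class{TermRef}}.
#' @export
#' @examples
#' termRef("PATO:0001236", "process quality")
termRef <- function(id, label = NA_character_) {
  new("TermRef", id = id, label = as.character(label))
}

## ---------------------------------------------------------------------------
## Matrix model
## ---------------------------------------------------------------------------

#' EQAnnotation: one Entity-Quality phenotype expression
#'
#' The Entity-Quality model pairs an anatomical or process entity with a
#' quality from the quality ontology (e.g. femur + curved). Relational
#' qualities, which hold between two entities rather than inhering in one,
#' additionally carry a related entity (e.g. fin ray, fused with, fin ray).
#' At least one of entity/quality must be present; whether the combination
#' is ontologically coherent is the consistency checker's business, not the
#' constructor's.
#'
#' @slot entity \code{TermRef} or \code{NULL}.
#' @slot quality \code{TermRef} or \code{NULL}.
#' @slot relatedEntity \code{TermRef} or \code{NULL}.
#' @slot comment character(1) free-text curator comment, or \code{NA}.
#' @export
setClass("EQAnnotation",
  representation(
    entity = "TermRefOrNULL",
    quality = "TermRefOrNULL",
    relatedEntity = "TermRefOrNULL",
    comment = "character"
  ),
  prototype(entity = NULL, quality = NULL, relatedEntity = NULL,
            comment = NA_character_)
)

setValidity("EQAnnotation", function(object) {
  if (is.null(object@entity) && is.null(object@quality)) {
    return("an annotation must carry at least one of entity/quality")
  }
  if (length(object@comment) != 1L) return("comment must be length 1")
  TRUE
})

#' Construct an EQAnnotation
#' @param entity,quality,relatedEntity \code{\link{termRef}} or \code{NULL}.
#' @param comment optional free-text comment.
#' @return an \code{\linkS4class{EQAnnotation}}.
#' @export
#' @examples
#' eqAnnotation(entity = termRef("UBERON:0002103"),
#'              quality = termRef("PATO:0000460"))
eqAnnotation <- function(entity = NULL, quality = NULL, relatedEntity = NULL,
                         comment = NA_character_) {
  new("EQAnnotation", entity = entity, quality = quality,
      relatedEntity = relatedEntity, comment = as.character(comment))
}

#' CharacterState: one discrete state of a character
#'
#' @slot symbol character(1) single token (e.g. \code{"0"}, \code{"1"},
#'   \code{"?"}); unique within its character. \code{"?"} is the reserved
#'   missing-data symbol and may never carry annotations.
#' @slot label character(1) free-text state description.
#' @slot annotations list of \code{\linkS4class{EQAnnotation}}.
#' @export
setClass("CharacterState",
  representation(symbol = "character", label = "character",
                 annotations = "list"),
  prototype(label = NA_character_, annotations = list())
)

setValidity("CharacterState", function(object) {
  if (length(object@symbol) != 1L || is.na(object@symbol) ||
      !nzchar(object@symbol) || grepl("[[:space:]]", object@symbol)) {
    return("symbol must be a single non-empty whitespace-free token")
  }
  if (object@symbol == "?" && length(object@annotations)) {
    return("the reserved missing symbol '?' may not carry annotations")
  }
  if (length(object@annotations) &&
      !all(vapply(object@annotations, is, logical(1), "EQAnnotation"))) {
    return("annotations must be EQAnnotation objects")
  }
  TRUE
})

#' Construct a CharacterState
#' @param symbol single-token state symbol.
#' @param label free-text description.
#' @param annotations list of \code{\link{eqAnnotation}}.
#' @return a \code{\linkS4class{CharacterState}}.
#' @export
characterState <- function(symbol, label = NA_character_, annotations = list()) {
  new("CharacterState", symbol = as.character(symbol),
      label = as.character(label), annotations = annotations)
}

#' MatrixCharacter: one column of the matrix
#'
#' @slot label character(1) free-text character description.
#' @slot states ordered list of \code{\linkS4class{CharacterState}} with
#'   unique symbols; at least one state.
#' @export
setClass("MatrixCharacter",
  representation(label = "character", states = "list"),
  prototype(label = NA_character_, states = list())
)

setValidity("MatrixCharacter", function(object) {
  if (!length(object@states)) return("a character needs at least one state")
  if (!all(vapply(object@states, is, logical(1), "CharacterState"))) {
    return("states must be CharacterState objects")
  }
  syms <- vapply(object@states, function(s) s@symbol, character(1))
  if (anyDuplicated(syms)) {
    return(paste0("duplicate state symbols: ",
                  paste(unique(syms[duplicated(syms)]), collapse = ", ")))
  }
  TRUE
})

#' Construct a MatrixCharacter
#' @param label free-text character description.
#' @param states list of \code{\link{characterState}}, or a character vector
#'   of symbols for unlabelled states.
#' @return a \code{\linkS4class{MatrixCharacter}}.
#' @export
#' @examples
#' matrixCharacter("dorsal fin", c("0", "1"))
matrixCharacter <- function(label, states) {
  if (is.character(states)) {
    states <- lapply(states, characterState)
  }
  new("MatrixCharacter", label = as.character(label), states = states)
}

#' Taxon: one row of the matrix
#'
#' @slot publicationLabel character(1) the taxon name as published; non-empty.
#' @slot taxonomyRef \code{TermRef} into a taxonomy ontology, or \code{NULL}.
#' @export
setClass("Taxon",
  representation(publicationLabel = "character",
                 taxonomyRef = "TermRefOrNULL"),
  prototype(taxonomyRef = NULL)
)

setValidity("Taxon", function(object) {
  if (length(object@publicationLabel) != 1L ||
      is.na(object@publicationLabel) || !nzchar(object@publicationLabel)) {
    return("publicationLabel must be a single non-empty string")
  }
  TRUE
})

#' Construct a Taxon
#' @param publicationLabel taxon name as published.
#' @param taxonomyRef optional \code{\link{termRef}} into a taxonomy ontology.
#' @return a \code{\linkS4class{Taxon}}.
#' @export
taxon <- function(publicationLabel, taxonomyRef = NULL) {
  new("Taxon", publicationLabel = as.character(publicationLabel),
      taxonomyRef = taxonomyRef)
}

#' StudyDocument: an annotated character matrix
#'
#' The central container: taxa by characters, cell scores (possibly
#' polymorphic sets of state symbols; absent cell = unscored), per-state EQ
#' annotations and per-taxon taxonomy references, plus document-level source
#' metadata (publication citation, curator ids, and opaque foreign metadata
#' preserved through NeXML round trips).
#'
#' @slot taxa ordered list of \code{\linkS4class{Taxon}}.
#' @slot characters ordered list of \code{\linkS4class{MatrixCharacter}}.
#' @slot cells named list; key \code{"<taxonIndex>_<characterIndex>"}
#'   (1-based), value a sorted character vector of state symbols.
#' @slot sourceMetadata named list of character strings; keys starting
#'   \code{"foreign_"} hold serialized foreign XML metadata.
#' @seealso \code{\link{studyDocument}}, \code{\link{setCell}},
#'   \code{\link{annotateState}}, \code{\link{writeNexml}}
#' @export
setClass("StudyDocument",
  representation(taxa = "list", characters = "list", cells = "list",
                 sourceMetadata = "list"),
  prototype(taxa = list(), characters = list(),
            cells = structure(list(), names = character(0)),
            sourceMetadata = structure(list(), names = character(0)))
)

setValidity("StudyDocument", function(object) {
  if (length(object@taxa) &&
      !all(vapply(object@taxa, is, logical(1), "Taxon"))) {
    return("taxa must be Taxon objects")
  }
  if (length(object@characters) &&
      !all(vapply(object@characters, is, logical(1), "MatrixCharacter"))) {
    return("characters must be MatrixCharacter objects")
  }
  keys <- names(object@cells)
  if (length(object@cells) && is.null(keys)) return("cells must be named")
  for (k in keys) {
    idx <- as.integer(strsplit(k, "_", fixed = TRUE)[[1L]])
    if (length(idx) != 2L || anyNA(idx)) {
      return(paste0("malformed cell key: ", k))
    }
    if (idx[1L] < 1L || idx[1L] > length(object@taxa) ||
        idx[2L] < 1L || idx[2L] > length(object@characters)) {
      return(paste0("cell key out of range: ", k))
    }
    syms <- object@cells[[k]]
    if (!is.character(syms) || !length(syms)) {
      return(paste0("cell ", k, " must hold a non-empty character vector"))
    }
    defined <- vapply(object@characters[[idx[2L]]]@states,
                      function(s) s@symbol, character(1))
    bad <- setdiff(syms, defined)
    if (length(bad)) {
      return(sprintf("cell %s uses undefined symbol(s): %s",
                     k, paste(bad, collapse = ", ")))
    }
  }
  if (length(object@sourceMetadata) && is.null(names(object@sourceMetadata))) {
    return("sourceMetadata must be named")
  }
  TRUE
})

#' Construct a StudyDocument
#' @param taxa list of \code{\link{taxon}}.
#' @param characters list of \code{\link{matrixCharacter}}.
#' @param sourceMetadata named list of strings (e.g. publication, curators).
#' @return an empty-celled \code{\linkS4class{StudyDocument}}.
#' @export
#' @examples
#' doc <- studyDocument(
#'   taxa = list(taxon("Danio rerio")),
#'   characters = list(matrixCharacter("dorsal fin", c("0", "1")))
#' )
studyDocument <- function(taxa = list(), characters = list(),
                          sourceMetadata = list()) {
  if (length(sourceMetadata)) {
    ## canonical (sorted) key order, so documents compare deep-equal across
    ## construction and serialization round trips
    sourceMetadata <- lapply(sourceMetadata, as.character)
    sourceMetadata <- sourceMetadata[order(names(sourceMetadata))]
  } else {
    sourceMetadata <- structure(list(), names = character(0))
  }
  new("StudyDocument", taxa = taxa, characters = characters,
      cells = structure(list(), names = character(0)),
      sourceMetadata = sourceMetadata)
}

#' MigrationReport: what a term migration rewrote
#'
#' @slot replacements named list: old id to \code{list(new_id=, count=)}
#'   with \code{count >= 1} and \code{old != new}.
#' @slot untouchedProvisional character vector of still-pending provisional
#'   ids left in the document.
#' @export
setClass("MigrationReport",
  representation(replacements = "list", untouchedProvisional = "character"),
  prototype(replacements = structure(list(), names = character(0)),
            untouchedProvisional = character(0))
)

setValidity("MigrationReport", function(object) {
  for (old in names(object@replacements)) {
    r <- object@replacements[[old]]
    if (!is.list(r) || is.null(r$new_id) || is.null(r$count)) {
      return("replacements entries must be list(new_id=, count=)")
    }
    if (r$count < 1L) return("replacement counts must be >= 1")
    if (identical(old, r$new_id)) return("old id must differ from new id")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Broker
## ---------------------------------------------------------------------------

#' ProvisionalRequest: a minted provisional term request
#'
#' Status is derived, never stored: a request is pending while
#' \code{permanentId} is \code{NA}, resolved once it is set (exactly once).
#'
#' @slot provisionalId character(1) URI, globally unique, never reused.
#' @slot label character(1) requested term name.
#' @slot definition character(1).
#' @slot suggestedSuperclass \code{TermRef} or \code{NULL}.
#' @slot synonyms character vector.
#' @slot submitter character(1) shared submitter id.
#' @slot created character(1) ISO-8601 UTC timestamp.
#' @slot permanentId character(1) URI or \code{NA} while pending.
#' @export
setClass("ProvisionalRequest",
  representation(
    provisionalId = "character",
    label = "character",
    definition = "character",
    suggestedSuperclass = "TermRefOrNULL",
    synonyms = "character",
    submitter = "character",
    created = "character",
    permanentId = "character"
  ),
  prototype(definition = NA_character_, suggestedSuperclass = NULL,
            synonyms = character(0), permanentId = NA_character_)
)

setValidity("ProvisionalRequest", function(object) {
  if (!nzchar(object@provisionalId)) return("provisionalId must be non-empty")
  if (!nzchar(object@label)) return("label must be non-empty")
  if (!nzchar(object@submitter)) return("submitter must be non-empty")
  if (!is.na(object@permanentId) &&
      identical(object@permanentId, object@provisionalId)) {
    return("permanentId must differ from provisionalId")
  }
  TRUE
})

#' BrokerStore: handle on a provisional-request store
#'
#' The default backend is a local JSON-lines file: one request record per
#' line, appended on create, whole-file rewrite on update (only
#' \code{permanent_id} may ever change after creation). The same three
#' capabilities (create with a fresh unique id, list by submitter, update
#' the permanent id) define the REST backend contract:
#' create = \code{POST}, list = \code{GET} filtered by submitter,
#' update = \code{PATCH} of \code{permanent_id}.
#'
#' @slot path character(1) path to the JSON-lines store file.
#' @slot namespace character(1) provisional-id namespace; minted ids are
#'   \code{<namespace><UUID>}.
#' @seealso \code{\link{brokerStore}}, \code{\link{requestTerm}}
#' @export
setClass("BrokerStore",
  representation(path = "character", namespace = "character")
)

setValidity("BrokerStore", function(object) {
  if (length(object@path) != 1L || !nzchar(object@path)) {
    return("path must be a single non-empty string")
  }
  if (length(object@namespace) != 1L || !nzchar(object@namespace)) {
    return("namespace must be a single non-empty string")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Consistency checking
## ---------------------------------------------------------------------------

#' RuleConfig: consistency-rule configuration
#'
#' The process rule defaults are the ontology ids the rules are defined
#' against: Gene Ontology \emph{biological process} (GO:0008150) entities
#' must pair with descendants of PATO \emph{process quality} (PATO:0001236).
#' No default exists for the relational-quality root: it must be supplied
#' when the relational rules are enabled.
#'
#' @slot processEntityRoot character(1), default \code{"GO:0008150"}.
#' @slot processQualityRoot character(1), default \code{"PATO:0001236"}.
#' @slot relationalQualityRoot character(1) or \code{NA} (must be set when
#'   the relational rules are enabled).
#' @slot enabledRules character vector of rule ids (see \code{\link{allRules}}).
#' @export
setClass("RuleConfig",
  representation(
    processEntityRoot = "character",
    processQualityRoot = "character",
    relationalQualityRoot = "character",
    enabledRules = "character"
  ),
  prototype(processEntityRoot = "GO:0008150",
            processQualityRoot = "PATO:0001236",
            relationalQualityRoot = NA_character_)
)

## ---------------------------------------------------------------------------
## Editing session
## ---------------------------------------------------------------------------

#' Edit: one reversible document transformation
#'
#' @slot description character(1) human-readable description.
#' @slot forward function(StudyDocument) -> StudyDocument.
#' @slot inverse function(StudyDocument) -> StudyDocument; must undo
#'   \code{forward} on the document the edit was recorded against.
#' @export
setClass("Edit",
  representation(description = "character", forward = "function",
                 inverse = "function")
)

#' EditSession: undo/redo, autosave, change classification
#'
#' @slot document the current \code{\linkS4class{StudyDocument}}.
#' @slot boundPath character(1) file the session is bound to, or \code{NA}.
#' @slot undoStack,redoStack lists of \code{\linkS4class{Edit}}.
#' @slot dirty logical(1); \code{TRUE} iff unsaved edits exist.
#' @slot autosaveEnabled logical(1); when set (and bound), every edit,
#'   undo and redo is followed by an atomic save, so \code{dirty} is
#'   \code{FALSE} at every quiescent point.
#' @slot lastToken character(1) MD5 of the last bytes this session wrote
#'   (the self-save token), or \code{NA}.
#' @slot ackToken character(1) MD5 of the last file content this session
#'   classified, used to distinguish \code{self_save} from \code{unchanged}.
#' @export
setClass("EditSession",
  representation(
    document = "StudyDocument",
    boundPath = "character",
    undoStack = "list",
    redoStack = "list",
    dirty = "logical",
    autosaveEnabled = "logical",
    lastToken = "character",
    ackToken = "character"
  ),
  prototype(boundPath = NA_character_, undoStack = list(), redoStack = list(),
            dirty = FALSE, autosaveEnabled = FALSE,
            lastToken = NA_character_, ackToken = NA_character_)
)

## ---------------------------------------------------------------------------
## Fixtures
## ---------------------------------------------------------------------------

#' FixtureSpec: parameters of a generated test bundle
#'
#' @slot seed integer(1) RNG seed; all outputs are deterministic in it.
#' @slot nTaxa,nCharacters,statesPerCharacter integer(1) matrix dimensions.
#' @slot annotatedFraction numeric(1) in [0,1]: fraction of characters that
#'   receive clean EQ annotations on every non-missing state.
#' @slot injectedViolations named integer vector: rule id -> count of
#'   violations to plant (validated for feasibility at generation time).
#' @export
setClass("FixtureSpec",
  representation(
    seed = "integer",
    nTaxa = "integer",
    nCharacters = "integer",
    statesPerCharacter = "integer",
    annotatedFraction = "numeric",
    injectedViolations = "integer"
  )
)

setValidity("FixtureSpec", function(object) {
  if (object@nTaxa < 0L || object@nCharacters < 0L ||
      object@statesPerCharacter < 1L) {
    return("dimensions must be non-negative (>=1 state per character)")
  }
  if (object@annotatedFraction < 0 || object@annotatedFraction > 1) {
    return("annotatedFraction must lie in [0, 1]")
  }
  if (length(object@injectedViolations) &&
      (is.null(names(object@injectedViolations)) ||
       any(object@injectedViolations < 0L))) {
    return("injectedViolations must be a named non-negative integer vector")
  }
  TRUE
})

#' FixtureBundle: generated ontologies + document + ground truth
#'
#' @slot anatomyGraph,qualityGraph,processGraph,taxonomyGraph generated
#'   \code{\linkS4class{OntologyGraph}}s.
#' @slot document the generated annotated \code{\linkS4class{StudyDocument}}.
#' @slot expectedIssues named integer vector: rule id -> count planted at
#'   generation time (recorded from the injection plan, not by running the
#'   checker — generator/checker agreement is the acceptance property).
#' @slot ruleConfig the \code{\linkS4class{RuleConfig}} whose roots the
#'   generated graphs contain.
#' @export
setClass("FixtureBundle",
  representation(
    anatomyGraph = "OntologyGraph",
    qualityGraph = "OntologyGraph",
    processGraph = "OntologyGraph",
    taxonomyGraph = "OntologyGraph",
    document = "StudyDocument",
    expectedIssues = "integer",
    ruleConfig = "RuleConfig"
  )
)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "OntologyGraph", function(object) {
  n_obs <- sum(vapply(object@terms, function(t) t@isObsolete, logical(1)))
  n_prov <- sum(vapply(object@terms, function(t) t@isProvisional, logical(1)))
  cat(sprintf("OntologyGraph: %d terms, %d is_a edges (%d obsolete, %d provisional)\n",
              length(object@terms), nrow(object@edges), n_obs, n_prov))
})

setMethod("show", "StudyDocument", function(object) {
  n_ann <- sum(vapply(object@characters, function(ch)
    sum(lengths(lapply(ch@states, function(s) s@annotations))), integer(1)))
  cat(sprintf("StudyDocument: %d taxa x %d characters, %d scored cells, %d EQ annotations\n",
              length(object@taxa), length(object@characters),
              length(object@cells), n_ann))
})

setMethod("show", "TermRef", function(object) {
  lab <- if (is.na(object@label)) "" else sprintf(" '%s'", object@label)
  cat(sprintf("<%s%s>\n", object@id, lab))
})

setMethod("show", "EQAnnotation", function(object) {
  part <- function(ref) if (is.null(ref)) "-" else ref@id
  cat(sprintf("EQ[entity=%s quality=%s related=%s]\n",
              part(object@entity), part(object@quality),
              part(object@relatedEntity)))
})

setMethod("show", "ProvisionalRequest", function(object) {
  status <- if (is.na(object@permanentId)) "pending"
            else sprintf("resolved -> %s", object@permanentId)
  cat(sprintf("ProvisionalRequest '%s' (%s)\n  %s [%s]\n",
              object@label, status, object@provisionalId, object@created))
})

setMethod("show", "BrokerStore", function(object) {
  cat(sprintf("BrokerStore: %s (namespace %s)\n", object@path, object@namespace))
})

setMethod("show", "EditSession", function(object) {
  cat(sprintf("EditSession: %s%s, %d undoable / %d redoable, autosave %s\n",
              if (is.na(object@boundPath)) "unbound" else object@boundPath,
              if (object@dirty) " [dirty]" else "",
              length(object@undoStack), length(object@redoStack),
              if (object@autosaveEnabled) "on" else "off"))
})

setMethod("show", "MigrationReport", function(object) {
  cat(sprintf("MigrationReport: %d id(s) rewritten, %d pending provisional id(s) untouched\n",
              length(object@replacements), length(object@untouchedProvisional)))
  for (old in names(object@replacements)) {
    r <- object@replacements[[old]]
    cat(sprintf("  %s -> %s (%d reference(s))\n", old, r$new_id, r$count))
  }
})

setMethod("show", "FixtureBundle", function(object) {
  cat("FixtureBundle\n")
  show(object@document)
  inj <- object@expectedIssues[object@expectedIssues > 0L]
  if (length(inj)) {
    cat("  planted issues:",
        paste(sprintf("%s=%d", names(inj), inj), collapse = ", "), "\n")
  } else {
    cat("  clean (no planted issues)\n")
  }
})
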