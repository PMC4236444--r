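## Ontology Request Broker: minting, listing and resolving provisional term
## requests, plus the launch-time sync that merges the request list into the
## ontology session and migrates document annotations.
##
## Store file format (JSON lines, one record per line):
##   provisional_id, label, definition, suggested_superclass {id, label}|null,
##   synonyms [..], submitter, created (ISO-8601 UTC), permanent_id (null
##   while pending). Records are appended on create; the file is rewritten
##   atomically on update, and only permanent_id may change after creation.

#' Open (or create) a broker store
#'
#' @param path path to the JSON-lines store file; created empty on first
#'   use.
#' @param namespace provisional-id namespace; minted ids are
#'   \code{<namespace><UUID>}. The default is deliberately generic — any
#'   service hosting the store will have its own URI space.
#' @return a \code{\linkS4class{BrokerStore}} handle.
#' @export
#' @examples
#' store <- brokerStore(tempfile(fileext = ".jsonl"))
brokerStore <- function(path, namespace = "http://example.org/provisional/") {
  if (!file.exists(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    if (!file.create(path)) {
      eqStop("eq_store_error", "cannot create store file '%s'", path)
    }
  }
  new("BrokerStore", path = path, namespace = namespace)
}

recordToRequest <- function(rec) {
  super <- NULL
  if (!is.null(rec$suggested_superclass)) {
    super <- termRef(rec$suggested_superclass$id,
                     rec$suggested_superclass$label %||% NA_character_)
  }
  new("ProvisionalRequest",
      provisionalId = rec$provisional_id,
      label = rec$label,
      definition = rec$definition %||% NA_character_,
      suggestedSuperclass = super,
      synonyms = as.character(unlist(rec$synonyms)),
      submitter = rec$submitter,
      created = rec$created,
      permanentId = if (is.null(rec$permanent_id)) NA_character_
                    else rec$permanent_id)
}

requestToRecord <- function(req) {
  super <- NULL
  if (!is.null(req@suggestedSuperclass)) {
    super <- list(id = req@suggestedSuperclass@id)
    if (!is.na(req@suggestedSuperclass@label)) {
      super$label <- req@suggestedSuperclass@label
    }
  }
  list(
    provisional_id = req@provisionalId,
    label = req@label,
    definition = if (is.na(req@definition)) NULL else req@definition,
    suggested_superclass = super,
    synonyms = as.list(req@synonyms),
    submitter = req@submitter,
    created = req@created,
    permanent_id = if (is.na(req@permanentId)) NULL else req@permanentId
  )
}

readStore <- function(store) {
  lines <- tryCatch(readLines(store@path, warn = FALSE, encoding = "UTF-8"),
                    error = function(e) eqStop("eq_store_error",
                                               "cannot read store '%s': %s",
                                               store@path,
                                               conditionMessage(e)))
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  ## one parse for the whole file: JSON-lines is a JSON array joined by commas
  recs <- tryCatch(
    jsonlite::fromJSON(paste0("[", paste(lines, collapse = ","), "]"),
                       simplifyVector = FALSE),
    error = function(e) eqStop("eq_store_error", "corrupt store record: %s",
                               conditionMessage(e)))
  lapply(recs, recordToRequest)
}

writeStore <- function(store, requests) {
  lines <- vapply(requests, function(req) {
    jsonlite::toJSON(requestToRecord(req), auto_unbox = TRUE,
                     null = "null")
  }, character(1))
  atomicWriteBytes(charToRaw(paste0(paste(lines, collapse = "\n"),
                                    if (length(lines)) "\n" else "")),
                   store@path)
}

appendStore <- function(store, req) {
  line <- jsonlite::toJSON(requestToRecord(req), auto_unbox = TRUE,
                           null = "null")
  con <- file(store@path, open = "ab")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(paste0(line, "\n")), con)
}

#' Request a provisional term
#'
#' Mints a fresh, never-reused provisional URI
#' (\code{<namespace><UUID>}) and persists a pending request record. The
#' returned term id is immediately usable in annotations; the request is
#' reviewed asynchronously and later resolved to a permanent id. Requests
#' with a label identical to an existing request are allowed — duplicate
#' avoidance is social, via a shared submitter id — but raise a warning
#' naming the prior requests.
#'
#' @param store a \code{\link{brokerStore}}.
#' @param label requested term name (non-empty).
#' @param definition free-text definition.
#' @param superclass optional \code{\link{termRef}}: suggested superclass.
#' @param synonyms character vector of synonyms.
#' @param submitter submitter id (non-empty; a curation team typically
#'   shares one so members see each other's requests).
#' @return the pending \code{\linkS4class{ProvisionalRequest}}.
#' @export
requestTerm <- function(store, label, definition = "", superclass = NULL,
                        synonyms = character(0), submitter) {
  stopifnot(is(store, "BrokerStore"))
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    eqStop("eq_validation_error", "request label must be non-empty")
  }
  if (!is.character(submitter) || length(submitter) != 1L || !nzchar(submitter)) {
    eqStop("eq_validation_error", "submitter must be non-empty")
  }
  existing <- readStore(store)
  same <- Filter(function(r) identical(r@label, label), existing)
  if (length(same)) {
    eqWarn("eq_duplicate_label_warning",
           "label '%s' already requested: %s", label,
           paste(vapply(same, function(r) r@provisionalId, character(1)),
                 collapse = ", "))
  }
  known <- vapply(existing, function(r) r@provisionalId, character(1))
  repeat {
    pid <- paste0(store@namespace, randomUUID())
    if (!pid %in% known) break
  }
  req <- new("ProvisionalRequest",
             provisionalId = pid,
             label = label,
             definition = as.character(definition),
             suggestedSuperclass = superclass,
             synonyms = as.character(synonyms),
             submitter = submitter,
             created = isoNow(),
             permanentId = NA_character_)
  appendStore(store, req)
  req
}

#' List a submitter's provisional requests
#'
#' Every record ever created under the submitter, pending and resolved, in
#' creation order (ties broken by provisional id).
#'
#' @param store a \code{\link{brokerStore}}.
#' @param submitter submitter id.
#' @param status one of \code{"all"}, \code{"pending"}, \code{"resolved"}.
#' @return list of \code{\linkS4class{ProvisionalRequest}}.
#' @export
listRequests <- function(store, submitter,
                         status = c("all", "pending", "resolved")) {
  status <- match.arg(status)
  reqs <- Filter(function(r) identical(r@submitter, submitter),
                 readStore(store))
  if (status == "pending") {
    reqs <- Filter(function(r) is.na(r@permanentId), reqs)
  } else if (status == "resolved") {
    reqs <- Filter(function(r) !is.na(r@permanentId), reqs)
  }
  created <- vapply(reqs, function(r) r@created, character(1))
  ids <- vapply(reqs, function(r) r@provisionalId, character(1))
  reqs[order(created, ids)]
}

#' Resolve a provisional request to a permanent id
#'
#' Sets the record's permanent id, exactly once. The permanent id need not
#' exist in any loaded ontology: review may find that a suitable term
#' already existed, in which case its URI is simply entered as the
#' permanent identifier and downstream migration treats it like a newly
#' created term.
#'
#' @param store a \code{\link{brokerStore}}.
#' @param provisionalId id of a pending request.
#' @param permanentId the permanent term URI (different from the
#'   provisional id).
#' @return the resolved \code{\linkS4class{ProvisionalRequest}}.
#' @section Errors: unknown provisional id; already-resolved request
#'   (re-resolution is forbidden); permanent id equal to the provisional id.
#' @export
resolveRequest <- function(store, provisionalId, permanentId) {
  stopifnot(is(store, "BrokerStore"))
  if (!is.character(permanentId) || length(permanentId) != 1L ||
      !nzchar(permanentId)) {
    eqStop("eq_validation_error", "permanent id must be non-empty")
  }
  if (identical(permanentId, provisionalId)) {
    eqStop("eq_validation_error",
           "permanent id must differ from the provisional id")
  }
  reqs <- readStore(store)
  pos <- which(vapply(reqs, function(r) identical(r@provisionalId, provisionalId),
                      logical(1)))
  if (!length(pos)) {
    eqStop("eq_missing_request_error", "no request with id '%s'",
           provisionalId)
  }
  req <- reqs[[pos[[1L]]]]
  if (!is.na(req@permanentId)) {
    eqStop("eq_already_resolved_error",
           "request '%s' already resolved to '%s'",
           provisionalId, req@permanentId)
  }
  req@permanentId <- permanentId
  validObject(req)
  reqs[[pos[[1L]]]] <- req
  writeStore(store, reqs)
  req
}

#' Sync the ontology session with the broker and migrate annotations
#'
#' The launch-time workflow: fetch all of the submitter's requests, merge
#' them into the ontology session (\code{\link{mergeProvisional}}: pending
#' requests become usable provisional terms; resolved ones become obsolete
#' terms carrying \code{replaced_by}), then rewrite every document
#' reference through \code{\link{resolveReplacement}} on the merged graph.
#' Replacement chains are followed to their terminus, so a reference lands
#' on the final id whether the intermediate hops come from provisional
#' resolutions or from ordinary ontology obsolescence. Ids unknown to the
#' merged graph are left untouched. Running the sync a second time rewrites
#' nothing.
#'
#' @param store a \code{\link{brokerStore}}.
#' @param submitter submitter id whose requests to sync.
#' @param graph the loaded \code{\linkS4class{OntologyGraph}}.
#' @param doc the open \code{\linkS4class{StudyDocument}}.
#' @return \code{list(graph=, document=, report=)}: the merged graph, the
#'   migrated document, and a \code{\linkS4class{MigrationReport}} whose
#'   \code{untouchedProvisional} lists still-pending provisional ids used
#'   by the document.
#' @export
syncAndMigrate <- function(store, submitter, graph, doc) {
  reqs <- listRequests(store, submitter)
  merged <- mergeProvisional(graph, reqs)
  known <- names(merged@terms)
  resolver <- function(id) {
    if (id %in% known) resolveReplacement(merged, id) else id
  }
  res <- applyTermMigration(doc, resolver)
  pending <- vapply(Filter(function(r) is.na(r@permanentId), reqs),
                    function(r) r@provisionalId, character(1))
  used <- documentTermIds(res$document)
  report <- res$report
  report@untouchedProvisional <- intersect(pending, used)
  list(graph = merged, document = res$document, report = report)
}
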