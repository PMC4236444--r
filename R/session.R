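## Collaboration-safe editing: reversible edits with undo/redo, continual
## autosave, and content-hash based file-change classification that tells a
## session's own saves apart from changes made by collaborators (e.g. via a
## folder-sync service). Hashing rather than mtime: sync services may
## rewrite identical bytes, and clocks skew across machines.

#' Construct a reversible edit
#'
#' An edit pairs a forward document transformation with its inverse; the
#' inverse must undo the forward transformation on the document the edit is
#' recorded against (capture the prior value in the closure — see
#' \code{\link{editSetCell}} for the pattern).
#'
#' @param description human-readable description.
#' @param forward,inverse functions \code{StudyDocument -> StudyDocument}.
#' @return an \code{\linkS4class{Edit}}.
#' @export
makeEdit <- function(description, forward, inverse) {
  new("Edit", description = description, forward = forward, inverse = inverse)
}

#' Reversible cell edit
#'
#' @param doc the document the edit will be applied to (its current cell
#'   value is captured for the inverse).
#' @param taxonIndex,characterIndex 1-based indices.
#' @param symbols new state symbols, or \code{NULL} to clear the cell.
#' @return an \code{\linkS4class{Edit}}.
#' @export
editSetCell <- function(doc, taxonIndex, characterIndex, symbols) {
  old <- cellValue(doc, taxonIndex, characterIndex)
  apply_symbols <- function(d, value) {
    if (is.null(value)) clearCell(d, taxonIndex, characterIndex)
    else setCell(d, taxonIndex, characterIndex, value)
  }
  makeEdit(
    sprintf("set cell (%d, %d)", taxonIndex, characterIndex),
    forward = function(d) apply_symbols(d, symbols),
    inverse = function(d) apply_symbols(d, old)
  )
}

#' Reversible annotation append
#'
#' @param doc the document the edit will be applied to.
#' @param characterIndex 1-based character index.
#' @param stateSymbol state to annotate.
#' @param ann an \code{\link{eqAnnotation}}.
#' @return an \code{\linkS4class{Edit}}.
#' @export
editAnnotateState <- function(doc, characterIndex, stateSymbol, ann) {
  makeEdit(
    sprintf("annotate character %d state '%s'", characterIndex, stateSymbol),
    forward = function(d) annotateState(d, characterIndex, stateSymbol, ann),
    inverse = function(d) {
      ch <- docCharacters(d)[[characterIndex]]
      pos <- match(stateSymbol, vapply(ch@states, function(s) s@symbol,
                                       character(1)))
      anns <- ch@states[[pos]]@annotations
      setStateAnnotations(d, characterIndex, stateSymbol,
                          anns[-length(anns)])
    }
  )
}

#' Open an edit session
#'
#' @param document the initial \code{\linkS4class{StudyDocument}} (ignored
#'   when \code{path} is given and exists: the file is read instead).
#' @param path optional file to bind the session to.
#' @param autosave when \code{TRUE} (and bound), the document is saved
#'   atomically after every edit, undo and redo, so unsaved-edit loss
#'   windows disappear.
#' @return an \code{\linkS4class{EditSession}}.
#' @export
editSession <- function(document = NULL, path = NA_character_,
                        autosave = FALSE) {
  token <- NA_character_
  if (!is.na(path) && file.exists(path)) {
    document <- readNexml(path)
    token <- md5Bytes(readBin(path, "raw", file.size(path)))
  }
  if (is.null(document)) {
    eqStop("eq_value_error", "an initial document or a readable path is required")
  }
  session <- new("EditSession", document = document, boundPath = path,
                 autosaveEnabled = autosave,
                 lastToken = token, ackToken = token)
  if (autosave && !is.na(path) && !file.exists(path)) {
    session <- saveSession(session)
  }
  session
}

#' Save a session's document to its bound file
#'
#' The write is atomic; the written bytes' hash becomes the session's
#' self-save token, so the next \code{\link{classifyFileChange}} recognises
#' the save as the session's own.
#'
#' @param session an \code{\linkS4class{EditSession}} with a bound path.
#' @return the updated session (\code{dirty = FALSE}).
#' @export
saveSession <- function(session) {
  stopifnot(is(session, "EditSession"))
  if (is.na(session@boundPath)) {
    eqStop("eq_value_error", "session is not bound to a file")
  }
  token <- writeNexml(session@document, session@boundPath)
  session@lastToken <- token
  session@dirty <- FALSE
  session
}

afterChange <- function(session) {
  session@dirty <- TRUE
  if (session@autosaveEnabled && !is.na(session@boundPath)) {
    session <- saveSession(session)
  }
  session
}

#' Apply an edit to a session
#'
#' The document is transformed, the edit is pushed onto the undo stack and
#' the redo stack is cleared; with autosave enabled the bound file is
#' rewritten before the call returns. An edit whose forward transformation
#' fails leaves the session untouched.
#'
#' @param session an \code{\linkS4class{EditSession}}.
#' @param edit an \code{\linkS4class{Edit}}.
#' @return the updated session.
#' @export
applyEdit <- function(session, edit) {
  stopifnot(is(session, "EditSession"), is(edit, "Edit"))
  newdoc <- tryCatch(edit@forward(session@document), error = function(e) e)
  if (inherits(newdoc, "error")) {
    eqStop("eq_edit_error", "edit '%s' not applicable: %s",
           edit@description, conditionMessage(newdoc))
  }
  session@document <- newdoc
  session@undoStack <- c(session@undoStack, list(edit))
  session@redoStack <- list()
  afterChange(session)
}

#' Undo the most recent edit
#' @param session an \code{\linkS4class{EditSession}}.
#' @return the updated session.
#' @export
undo <- function(session) {
  stopifnot(is(session, "EditSession"))
  n <- length(session@undoStack)
  if (!n) eqStop("eq_edit_error", "nothing to undo")
  edit <- session@undoStack[[n]]
  session@document <- edit@inverse(session@document)
  session@undoStack <- session@undoStack[-n]
  session@redoStack <- c(session@redoStack, list(edit))
  afterChange(session)
}

#' Redo the most recently undone edit
#' @param session an \code{\linkS4class{EditSession}}.
#' @return the updated session.
#' @export
redo <- function(session) {
  stopifnot(is(session, "EditSession"))
  n <- length(session@redoStack)
  if (!n) eqStop("eq_edit_error", "nothing to redo")
  edit <- session@redoStack[[n]]
  session@document <- edit@forward(session@document)
  session@redoStack <- session@redoStack[-n]
  session@undoStack <- c(session@undoStack, list(edit))
  afterChange(session)
}

#' Classify a change to the bound file
#'
#' Compares the file's current content hash with the session's self-save
#' token: content the session itself wrote classifies as \code{self_save}
#' (once — subsequent polls of the same content report \code{unchanged});
#' anything else is an \code{external_change} that should be reported to
#' the user with an offer to reload. A deleted file is an external change
#' with the \code{deleted} flag set.
#'
#' @param session an \code{\linkS4class{EditSession}} with a bound path.
#' @return \code{list(session=, event=, deleted=)} where \code{event} is
#'   one of \code{"self_save"}, \code{"external_change"},
#'   \code{"unchanged"}.
#' @export
classifyFileChange <- function(session) {
  stopifnot(is(session, "EditSession"))
  if (is.na(session@boundPath)) {
    eqStop("eq_value_error", "session is not bound to a file")
  }
  if (!file.exists(session@boundPath)) {
    return(list(session = session, event = "external_change", deleted = TRUE))
  }
  bytes <- readBin(session@boundPath, "raw", file.size(session@boundPath))
  h <- md5Bytes(bytes)
  if (!is.na(session@ackToken) && identical(h, session@ackToken)) {
    return(list(session = session, event = "unchanged", deleted = FALSE))
  }
  if (!is.na(session@lastToken) && identical(h, session@lastToken)) {
    session@ackToken <- h
    return(list(session = session, event = "self_save", deleted = FALSE))
  }
  list(session = session, event = "external_change", deleted = FALSE)
}

#' Reload the bound file into the session
#'
#' Replaces the in-memory document with the file's content and clears both
#' stacks. A dirty session refuses to reload unless forced, because
#' reloading would discard the unsaved edits; with autosave enabled a
#' session is never dirty at a quiescent point, so reload always succeeds.
#'
#' @param session an \code{\linkS4class{EditSession}} with a bound path.
#' @param force discard unsaved edits?
#' @return the updated session.
#' @export
reloadSession <- function(session, force = FALSE) {
  stopifnot(is(session, "EditSession"))
  if (is.na(session@boundPath)) {
    eqStop("eq_value_error", "session is not bound to a file")
  }
  if (session@dirty && !force) {
    eqStop("eq_unsaved_changes_error",
           "session has unsaved changes; reloading would discard them (use force)")
  }
  if (!file.exists(session@boundPath)) {
    eqStop("eq_io_error", "bound file '%s' no longer exists",
           session@boundPath)
  }
  bytes <- readBin(session@boundPath, "raw", file.size(session@boundPath))
  session@document <- readNexml(session@boundPath)
  session@undoStack <- list()
  session@redoStack <- list()
  session@dirty <- FALSE
  h <- md5Bytes(bytes)
  session@lastToken <- h
  session@ackToken <- h
  session
}

#' Poll the bound file for changes
#'
#' A polling equivalent of a filesystem watcher: classifies the bound
#' file's state \code{times} times, sleeping \code{interval} seconds
#' between polls, and invokes \code{callback(event, deleted)} for every
#' non-\code{unchanged} event. The CLI \code{watch} command prints one line
#' per event on top of this.
#'
#' @param session an \code{\linkS4class{EditSession}} with a bound path.
#' @param times number of polls.
#' @param interval seconds between polls.
#' @param callback function(event, deleted).
#' @return the updated session, invisibly.
#' @export
watchFile <- function(session, times = 1L, interval = 0.5,
                      callback = function(event, deleted) {}) {
  for (i in seq_len(times)) {
    res <- classifyFileChange(session)
    session <- res$session
    if (res$event != "unchanged") callback(res$event, res$deleted)
    if (i < times) Sys.sleep(interval)
  }
  invisible(session)
}
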