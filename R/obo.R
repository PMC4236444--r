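## OBO flat-file (1.2/1.4) parsing and deterministic serialization.
##
## Supported tag subset: format-version (header); [Term] stanzas with id,
## name, def, synonym, is_a, is_obsolete, replaced_by, namespace. Unknown
## tags are ignored with a logged notice; non-[Term] stanzas are skipped.

## strip an OBO trailing comment ("VALUE ! human readable label")
stripOboComment <- function(value) {
  sub("\\s*!.*$", "", value)
}

parseSynonymLine <- function(value, lineno) {
  m <- regmatches(value, regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*([A-Z]+)?', value))[[1L]]
  if (length(m) < 2L || !nzchar(m[1L])) {
    eqStop("eq_parse_error", "line %d: malformed synonym line", lineno)
  }
  scope <- if (length(m) >= 3L && nzchar(m[3L])) m[3L] else "RELATED"
  list(text = gsub('\\\\(.)', "\\1", m[2L]), scope = scope)
}

parseDefLine <- function(value, lineno) {
  m <- regmatches(value, regexec('^"((?:[^"\\\\]|\\\\.)*)"', value))[[1L]]
  if (length(m) < 2L) {
    eqStop("eq_parse_error", "line %d: malformed def line", lineno)
  }
  gsub('\\\\(.)', "\\1", m[2L])
}

#' Parse an OBO document into an ontology graph
#'
#' Parses the documented OBO tag subset (\code{id}, \code{name}, \code{def},
#' \code{synonym}, \code{is_a}, \code{is_obsolete}, \code{replaced_by},
#' \code{namespace} inside \code{[Term]} stanzas). Unknown tags and
#' non-Term stanzas are skipped with a notice via \code{message()}.
#' \code{is_a} parents that are not themselves defined in the file are kept
#' as placeholder terms flagged incomplete — curators routinely load
#' ontology slices — and reported in a notice, never silently dropped.
#'
#' @param text character: either a single string containing the whole
#'   document or a vector of lines.
#' @return an \code{\linkS4class{OntologyGraph}}.
#' @section Errors: duplicate term ids, is_a cycles (the cycle is listed),
#'   and malformed stanza lines (reported with their line number) are
#'   errors.
#' @seealso \code{\link{readOBO}}, \code{\link{writeOBO}}
#' @export
#' @examples
#' g <- parseOBO(c(
#'   "format-version: 1.4",
#'   "", "[Term]", "id: X:1", "name: a",
#'   "", "[Term]", "id: X:2", "name: b", "is_a: X:1"
#' ))
#' termIds(g)
parseOBO <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  lines <- sub("\r$", "", text)

  terms <- list()
  edges_child <- character(0)
  edges_parent <- character(0)
  unknown_tags <- character(0)

  in_term <- FALSE
  in_other <- FALSE
  cur <- NULL
  cur_line <- 0L

  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) {
      eqStop("eq_parse_error", "line %d: [Term] stanza without id", cur_line)
    }
    if (cur$id %in% names(terms)) {
      eqStop("eq_parse_error", "duplicate term id '%s'", cur$id)
    }
    terms[[cur$id]] <<- new("Term",
      id = cur$id,
      label = cur$name %||% NA_character_,
      definition = cur$def %||% NA_character_,
      synonyms = cur$synonyms,
      isObsolete = isTRUE(cur$obsolete),
      replacedBy = cur$replaced_by,
      namespace = cur$namespace %||% NA_character_
    )
    if (length(cur$parents)) {
      edges_child <<- c(edges_child, rep(cur$id, length(cur$parents)))
      edges_parent <<- c(edges_parent, cur$parents)
    }
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^\\s*$", line) || grepl("^\\s*!", line)) next
    if (grepl("^\\[", line)) {
      flush()
      cur <- NULL
      if (identical(trimws(line), "[Term]")) {
        in_term <- TRUE
        in_other <- FALSE
        cur <- list(synonyms = list(), parents = character(0),
                    replaced_by = character(0))
        cur_line <- i
      } else {
        in_term <- FALSE
        in_other <- TRUE
        message("eqmatrix: skipping stanza ", trimws(line), " at line ", i)
      }
      next
    }
    colon <- regexpr(": ", line, fixed = TRUE)
    if (colon < 0L) colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 0L) {
      eqStop("eq_parse_error", "line %d: malformed line (no tag): %s", i, line)
    }
    tag <- substr(line, 1L, colon - 1L)
    value <- trimws(substr(line, colon + attr(colon, "match.length"), nchar(line)))
    if (!in_term) {
      ## header or foreign stanza content; header tags are free-form
      next
    }
    switch(tag,
      id = { cur$id <- stripOboComment(value) },
      name = { cur$name <- value },
      def = { cur$def <- parseDefLine(value, i) },
      synonym = { cur$synonyms <- c(cur$synonyms, list(parseSynonymLine(value, i))) },
      is_a = { cur$parents <- c(cur$parents, trimws(stripOboComment(value))) },
      is_obsolete = { cur$obsolete <- identical(trimws(stripOboComment(value)), "true") },
      replaced_by = { cur$replaced_by <- c(cur$replaced_by, trimws(stripOboComment(value))) },
      namespace = { cur$namespace <- value },
      {
        if (!tag %in% unknown_tags) {
          unknown_tags <- c(unknown_tags, tag)
          message("eqmatrix: ignoring unknown OBO tag '", tag, "' (line ", i, ")")
        }
      }
    )
  }
  flush()

  ## dangling parents become placeholder terms, reported but kept
  dangling <- setdiff(unique(edges_parent), names(terms))
  if (length(dangling)) {
    message("eqmatrix: ", length(dangling),
            " is_a parent(s) not defined in file kept as placeholders: ",
            paste(dangling, collapse = ", "))
    for (id in dangling) {
      terms[[id]] <- new("Term", id = id, isPlaceholder = TRUE)
    }
  }

  edges <- matrix(c(edges_child, edges_parent), ncol = 2L,
                  dimnames = list(NULL, c("child", "parent")))
  edges <- unique(edges)
  cyc <- if (nrow(edges)) findCycle(edges) else NULL
  if (!is.null(cyc)) {
    eqStop("eq_cycle_error", "is_a cycle: %s", paste(cyc, collapse = " -> "))
  }
  new("OntologyGraph", terms = terms, edges = edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an OBO file
#' @param path path to an OBO-format file.
#' @return an \code{\linkS4class{OntologyGraph}}.
#' @export
readOBO <- function(path) {
  if (!file.exists(path)) {
    eqStop("eq_io_error", "OBO file not found: '%s'", path)
  }
  parseOBO(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' Serialize an ontology graph as OBO (deterministic debug writer)
#'
#' Stanzas are emitted sorted by term id with tags in a fixed order, so
#' identical graphs serialize identically (the round-trip test substrate).
#' Placeholder terms (materialised for dangling parents) are not written:
#' re-parsing the output recreates them from the surviving \code{is_a}
#' lines. The provisional flag has no OBO tag and is likewise not written.
#'
#' @param graph an \code{\linkS4class{OntologyGraph}}.
#' @param path optional file path; when \code{NULL} the text is returned.
#' @return character vector of lines (invisibly when \code{path} is given).
#' @export
writeOBO <- function(graph, path = NULL) {
  stopifnot(is(graph, "OntologyGraph"))
  out <- c("format-version: 1.4", "")
  parents_of <- split(graph@edges[, "parent"], graph@edges[, "child"])
  for (id in sort(names(graph@terms))) {
    term <- graph@terms[[id]]
    if (term@isPlaceholder) next
    stanza <- c("[Term]", paste0("id: ", term@id))
    if (!is.na(term@label)) stanza <- c(stanza, paste0("name: ", term@label))
    if (!is.na(term@namespace)) {
      stanza <- c(stanza, paste0("namespace: ", term@namespace))
    }
    if (!is.na(term@definition)) {
      stanza <- c(stanza, sprintf('def: "%s" []',
                                  gsub('"', '\\\\"', term@definition)))
    }
    for (s in term@synonyms) {
      stanza <- c(stanza, sprintf('synonym: "%s" %s []',
                                  gsub('"', '\\\\"', s$text), s$scope))
    }
    for (p in sort(unique(parents_of[[id]]))) {
      stanza <- c(stanza, paste0("is_a: ", p))
    }
    if (term@isObsolete) stanza <- c(stanza, "is_obsolete: true")
    for (r in term@replacedBy) {
      stanza <- c(stanza, paste0("replaced_by: ", r))
    }
    out <- c(out, stanza, "")
  }
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}
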