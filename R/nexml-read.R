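## NeXML parsing back into a StudyDocument.
##
## The reader is the inverse of the writer on documents the writer produced
## (read(write(doc)) == doc), and tolerant beyond that: element ids are
## treated as opaque, annotation predicates are resolved as QNames against
## the file's own namespace declarations, and unknown (foreign) metadata on
## the document element is preserved verbatim in sourceMetadata and
## re-emitted on the next write.

## resolve the namespace URI + local part of a QName attribute value,
## against the prefixes declared in the document
resolveQName <- function(qname, nsMap) {
  if (is.na(qname)) return(NULL)
  parts <- strsplit(qname, ":", fixed = TRUE)[[1L]]
  if (length(parts) == 2L && parts[1L] %in% names(nsMap)) {
    return(list(ns = unname(nsMap[[parts[1L]]]), local = parts[2L]))
  }
  list(ns = "", local = qname)
}

isPaPredicate <- function(qname, nsMap, local) {
  q <- resolveQName(qname, nsMap)
  !is.null(q) && identical(q$ns, PA_NS) && identical(q$local, local)
}

childMetas <- function(node) {
  xml2::xml_find_all(node, "./*[local-name() = 'meta']")
}

## read a ResourceMeta into a TermRef (href -> id, nested pa:label -> label)
readTermRefMeta <- function(node, nsMap, prefixMap) {
  href <- xml2::xml_attr(node, "href")
  if (is.na(href)) {
    eqStop("eq_format_error", "resource meta without href")
  }
  label <- NA_character_
  for (m in childMetas(node)) {
    if (isPaPredicate(xml2::xml_attr(m, "property"), nsMap, "label")) {
      label <- xml2::xml_attr(m, "content")
    }
  }
  termRef(contractTermId(href, prefixMap), label)
}

readPhenotypeMeta <- function(node, nsMap, prefixMap) {
  entity <- quality <- related <- NULL
  comment <- NA_character_
  for (m in childMetas(node)) {
    rel <- xml2::xml_attr(m, "rel")
    prop <- xml2::xml_attr(m, "property")
    if (isPaPredicate(rel, nsMap, "entity")) {
      entity <- readTermRefMeta(m, nsMap, prefixMap)
    } else if (isPaPredicate(rel, nsMap, "quality")) {
      quality <- readTermRefMeta(m, nsMap, prefixMap)
    } else if (isPaPredicate(rel, nsMap, "related_entity")) {
      related <- readTermRefMeta(m, nsMap, prefixMap)
    } else if (isPaPredicate(prop, nsMap, "comment")) {
      comment <- xml2::xml_attr(m, "content")
    }
  }
  eqAnnotation(entity = entity, quality = quality, relatedEntity = related,
               comment = comment)
}

#' Read a NeXML file into a StudyDocument
#'
#' Reconstructs taxa, characters, states, cell scores and annotations from
#' a NeXML document. Document-level metadata in the annotation vocabulary
#' becomes \code{sourceMetadata} entries; any other document-level meta
#' element is preserved opaquely under a \code{foreign_NNN} key and
#' re-emitted by \code{\link{writeNexml}}.
#'
#' @param source path to a NeXML file, or a literal XML string.
#' @param prefixMap optional named character vector for URI-to-CURIE
#'   contraction (see \code{\link{contractTermId}}).
#' @return a \code{\linkS4class{StudyDocument}}.
#' @section Errors: a non-NeXML root is a format error; a cell referencing
#'   an undeclared state id is an integrity error naming the row and
#'   character.
#' @export
readNexml <- function(source, prefixMap = NULL) {
  x <- tryCatch(xml2::read_xml(source),
                error = function(e) eqStop("eq_format_error",
                                           "not well-formed XML: %s",
                                           conditionMessage(e)))
  root <- xml2::xml_root(x)
  nsMap <- as.list(xml2::xml_ns(x))
  if (xml2::xml_name(root) != "nexml" ||
      !NEXML_NS %in% unlist(nsMap, use.names = FALSE)) {
    eqStop("eq_format_error", "root element is not a NeXML <nexml> document")
  }

  ## document-level metadata
  meta <- structure(list(), names = character(0))
  n_foreign <- 0L
  for (m in childMetas(root)) {
    prop <- xml2::xml_attr(m, "property")
    q <- resolveQName(prop, nsMap)
    if (!is.null(q) && identical(q$ns, PA_NS)) {
      meta[[q$local]] <- xml2::xml_attr(m, "content")
    } else {
      n_foreign <- n_foreign + 1L
      meta[[sprintf("foreign_%03d", n_foreign)]] <- as.character(m)
    }
  }

  ## taxa
  otuNodes <- xml2::xml_find_all(root,
    "./*[local-name() = 'otus']/*[local-name() = 'otu']")
  otuIds <- xml2::xml_attr(otuNodes, "id")
  taxa <- lapply(otuNodes, function(node) {
    ref <- NULL
    for (m in childMetas(node)) {
      if (isPaPredicate(xml2::xml_attr(m, "rel"), nsMap, "taxon")) {
        ref <- readTermRefMeta(m, nsMap, prefixMap)
      }
    }
    lab <- xml2::xml_attr(node, "label")
    taxon(if (is.na(lab)) "(unlabelled taxon)" else lab, ref)
  })

  ## characters: format block
  charsBlock <- xml2::xml_find_first(root, "./*[local-name() = 'characters']")
  characters <- list()
  stateSymbolById <- list()   # state xml id -> character vector of symbols
  charIndexById <- list()     # char xml id -> index
  if (!inherits(charsBlock, "xml_missing")) {
    fmt <- xml2::xml_find_first(charsBlock, "./*[local-name() = 'format']")
    statesNodes <- xml2::xml_find_all(fmt, "./*[local-name() = 'states']")
    statesById <- list()      # states xml id -> list(states=, symById=)
    for (sn in statesNodes) {
      sid <- xml2::xml_attr(sn, "id")
      sts <- list()
      symById <- list()
      for (node in xml2::xml_find_all(sn, "./*[local-name() = 'state']")) {
        anns <- list()
        for (m in childMetas(node)) {
          if (isPaPredicate(xml2::xml_attr(m, "rel"), nsMap, "phenotype")) {
            anns <- c(anns, list(readPhenotypeMeta(m, nsMap, prefixMap)))
          }
        }
        st <- characterState(xml2::xml_attr(node, "symbol"),
                             xml2::xml_attr(node, "label"),
                             anns)
        sts <- c(sts, list(st))
        symById[[xml2::xml_attr(node, "id")]] <- st@symbol
      }
      for (node in xml2::xml_find_all(sn,
          "./*[local-name() = 'polymorphic_state_set' or local-name() = 'uncertain_state_set']")) {
        members <- xml2::xml_find_all(node, "./*[local-name() = 'member']")
        refs <- xml2::xml_attr(members, "state")
        syms <- unlist(symById[refs], use.names = FALSE)
        symById[[xml2::xml_attr(node, "id")]] <- sort(syms)
      }
      statesById[[sid]] <- list(states = sts, symById = symById)
    }
    charNodes <- xml2::xml_find_all(fmt, "./*[local-name() = 'char']")
    for (i in seq_along(charNodes)) {
      node <- charNodes[[i]]
      sref <- xml2::xml_attr(node, "states")
      entry <- statesById[[sref]]
      if (is.null(entry)) {
        eqStop("eq_integrity_error",
               "char '%s' references undeclared states block '%s'",
               xml2::xml_attr(node, "id"), sref)
      }
      characters[[i]] <- new("MatrixCharacter",
                             label = xml2::xml_attr(node, "label"),
                             states = entry$states)
      charIndexById[[xml2::xml_attr(node, "id")]] <- i
      stateSymbolById[[i]] <- entry$symById
    }
  }

  if (length(meta)) meta <- meta[order(names(meta))]
  doc <- new("StudyDocument", taxa = taxa, characters = characters,
             cells = structure(list(), names = character(0)),
             sourceMetadata = meta)

  ## matrix block
  if (!inherits(charsBlock, "xml_missing")) {
    rows <- xml2::xml_find_all(charsBlock,
      "./*[local-name() = 'matrix']/*[local-name() = 'row']")
    for (row in rows) {
      otuRef <- xml2::xml_attr(row, "otu")
      ti <- match(otuRef, otuIds)
      if (is.na(ti)) {
        eqStop("eq_integrity_error", "row references unknown otu '%s'", otuRef)
      }
      for (cell in xml2::xml_find_all(row, "./*[local-name() = 'cell']")) {
        cref <- xml2::xml_attr(cell, "char")
        ci <- charIndexById[[cref]]
        if (is.null(ci)) {
          eqStop("eq_integrity_error",
                 "row '%s': cell references unknown char '%s'",
                 xml2::xml_attr(row, "id"), cref)
        }
        sref <- xml2::xml_attr(cell, "state")
        syms <- stateSymbolById[[ci]][[sref]]
        if (is.null(syms)) {
          eqStop("eq_integrity_error",
                 "row '%s', char '%s': cell references undeclared state '%s'",
                 xml2::xml_attr(row, "id"), cref, sref)
        }
        doc@cells[[sprintf("%d_%d", ti, ci)]] <- sort(syms)
      }
    }
  }
  validObject(doc)
  orderCells(doc)
}
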