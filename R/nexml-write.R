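## NeXML serialization of a StudyDocument.
##
## Vocabulary: annotations are embedded as NeXML meta elements in the `pa:`
## namespace (http://example.org/phenotype-annotation#):
##   - on <otu>:  ResourceMeta rel="pa:taxon" href=<taxonomy term URI>
##   - on <state>: ResourceMeta rel="pa:phenotype" containing child
##     ResourceMeta rel="pa:entity" / "pa:quality" / "pa:related_entity"
##     (each optionally holding LiteralMeta property="pa:label" with the
##     cached display label) and LiteralMeta property="pa:comment"
##   - on <nexml>: LiteralMeta property="pa:<key>" for each sourceMetadata
##     entry; foreign (non-pa) meta elements are re-emitted verbatim.
## Output is deterministic: fixed element ordering, fixed prefixes, meta ids
## assigned in emission order — identical documents serialize byte-identically.

NEXML_NS <- "http://www.nexml.org/2009"
XSI_NS <- "http://www.w3.org/2001/XMLSchema-instance"
PA_NS <- "http://example.org/phenotype-annotation#"

#' Namespace bindings written into NeXML output
#'
#' The document-level prefix-to-URI map used by the writer: the NeXML core
#' namespace (default and \code{nex:}), XML Schema instance, and the
#' annotation vocabulary bound to \code{pa:}.
#'
#' @return named character vector (prefix -> namespace URI).
#' @export
vocabularyBinding <- function() {
  c(nex = NEXML_NS, xsi = XSI_NS, pa = PA_NS)
}

## id generator shared across one serialization
newMetaCounter <- function() {
  n <- 0L
  function() {
    n <<- n + 1L
    sprintf("meta%d", n)
  }
}

addLiteralMeta <- function(parent, nextId, property, content) {
  xml2::xml_add_child(parent, "meta",
    id = nextId(),
    "xsi:type" = "nex:LiteralMeta",
    property = property,
    content = content,
    datatype = "xsd:string"
  )
}

addResourceMeta <- function(parent, nextId, rel, href) {
  xml2::xml_add_child(parent, "meta",
    id = nextId(),
    "xsi:type" = "nex:ResourceMeta",
    rel = rel,
    href = href
  )
}

addTermRefMeta <- function(parent, nextId, rel, ref, prefixMap) {
  node <- addResourceMeta(parent, nextId, rel, expandTermId(ref@id, prefixMap))
  if (!is.na(ref@label)) {
    addLiteralMeta(node, nextId, "pa:label", ref@label)
  }
  node
}

## polymorphic state-set key: sorted symbols joined (cells store sorted sets)
polyKey <- function(symbols) paste(symbols, collapse = "")

#' Serialize a StudyDocument to a NeXML string
#'
#' @param doc a \code{\linkS4class{StudyDocument}}.
#' @param prefixMap optional named character vector overriding the default
#'   CURIE expansion (see \code{\link{expandTermId}}).
#' @return character(1): the complete XML document.
#' @seealso \code{\link{writeNexml}}, \code{\link{readNexml}}
#' @export
nexmlString <- function(doc, prefixMap = NULL) {
  stopifnot(is(doc, "StudyDocument"))
  validObject(doc)
  nextId <- newMetaCounter()

  root <- xml2::xml_new_root("nex:nexml",
    version = "0.9",
    "xmlns" = NEXML_NS,
    "xmlns:nex" = NEXML_NS,
    "xmlns:xsi" = XSI_NS,
    "xmlns:xsd" = "http://www.w3.org/2001/XMLSchema#",
    "xmlns:pa" = PA_NS
  )

  ## document-level metadata, keys sorted for determinism
  for (key in sort(names(doc@sourceMetadata))) {
    value <- doc@sourceMetadata[[key]]
    if (startsWith(key, "foreign_")) {
      foreign <- xml2::read_xml(value)
      xml2::xml_add_child(root, foreign)
    } else {
      addLiteralMeta(root, nextId, paste0("pa:", key), value)
    }
  }

  ## taxa
  otus <- xml2::xml_add_child(root, "otus", id = "otus1")
  for (i in seq_along(doc@taxa)) {
    tx <- doc@taxa[[i]]
    otu <- xml2::xml_add_child(otus, "otu",
                               id = sprintf("t%d", i),
                               label = tx@publicationLabel)
    if (!is.null(tx@taxonomyRef)) {
      addTermRefMeta(otu, nextId, "pa:taxon", tx@taxonomyRef, prefixMap)
    }
  }

  ## characters block (standard category data)
  chars <- xml2::xml_add_child(root, "characters",
                               id = "chars1", otus = "otus1",
                               "xsi:type" = "nex:StandardCells")
  fmt <- xml2::xml_add_child(chars, "format")

  ## per-character state ids; polymorphic sets discovered from the cells
  state_id <- list()   # [[ci]][[symbol]] -> xml id
  poly_id <- list()    # [[ci]][[polyKey]] -> xml id
  for (ci in seq_along(doc@characters)) {
    ch <- doc@characters[[ci]]
    states <- xml2::xml_add_child(fmt, "states", id = sprintf("states%d", ci))
    ids <- character(0)
    for (si in seq_along(ch@states)) {
      st <- ch@states[[si]]
      sid <- sprintf("s%d_%d", ci, si)
      ids[[st@symbol]] <- sid
      node <- xml2::xml_add_child(states, "state", id = sid, symbol = st@symbol)
      if (!is.na(st@label)) xml2::xml_set_attr(node, "label", st@label)
      for (ann in st@annotations) {
        ph <- xml2::xml_add_child(node, "meta",
          id = nextId(), "xsi:type" = "nex:ResourceMeta", rel = "pa:phenotype")
        if (!is.null(ann@entity)) {
          addTermRefMeta(ph, nextId, "pa:entity", ann@entity, prefixMap)
        }
        if (!is.null(ann@quality)) {
          addTermRefMeta(ph, nextId, "pa:quality", ann@quality, prefixMap)
        }
        if (!is.null(ann@relatedEntity)) {
          addTermRefMeta(ph, nextId, "pa:related_entity", ann@relatedEntity,
                         prefixMap)
        }
        if (!is.na(ann@comment)) {
          addLiteralMeta(ph, nextId, "pa:comment", ann@comment)
        }
      }
    }
    state_id[[ci]] <- ids

    ## polymorphic sets used by this character's cells, sorted by members
    used <- doc@cells[vapply(names(doc@cells), function(k)
      endsWith(k, sprintf("_%d", ci)), logical(1))]
    polys <- unique(lapply(used[lengths(used) > 1L], identity))
    keys <- vapply(polys, polyKey, character(1))
    ord <- order(keys)
    pids <- character(0)
    for (k in seq_along(ord)) {
      members <- polys[[ord[k]]]
      pid <- sprintf("p%d_%d", ci, k)
      pids[[polyKey(members)]] <- pid
      pnode <- xml2::xml_add_child(states, "polymorphic_state_set",
                                   id = pid, symbol = sprintf("P%d", k))
      for (m in members) {
        xml2::xml_add_child(pnode, "member", state = ids[[m]])
      }
    }
    poly_id[[ci]] <- pids
  }
  for (ci in seq_along(doc@characters)) {
    node <- xml2::xml_add_child(fmt, "char",
                                id = sprintf("c%d", ci),
                                states = sprintf("states%d", ci))
    if (!is.na(doc@characters[[ci]]@label)) {
      xml2::xml_set_attr(node, "label", doc@characters[[ci]]@label)
    }
  }

  mat <- xml2::xml_add_child(chars, "matrix")
  for (ti in seq_along(doc@taxa)) {
    row <- xml2::xml_add_child(mat, "row",
                               id = sprintf("r%d", ti),
                               otu = sprintf("t%d", ti))
    for (ci in seq_along(doc@characters)) {
      syms <- doc@cells[[sprintf("%d_%d", ti, ci)]]
      if (is.null(syms)) next
      ref <- if (length(syms) == 1L) state_id[[ci]][[syms]]
             else poly_id[[ci]][[polyKey(syms)]]
      xml2::xml_add_child(row, "cell",
                          char = sprintf("c%d", ci), state = ref)
    }
  }

  as.character(root)
}

#' Write a StudyDocument as NeXML
#'
#' Serialization is deterministic, so writing the same document twice
#' produces byte-identical files. The write is atomic (temp file + rename).
#'
#' @inheritParams nexmlString
#' @param path destination file path.
#' @return the written bytes' MD5, invisibly (the self-save token used by
#'   \code{\link{classifyFileChange}}).
#' @export
writeNexml <- function(doc, path, prefixMap = NULL) {
  bytes <- charToRaw(nexmlString(doc, prefixMap))
  atomicWriteBytes(bytes, path)
  invisible(md5Bytes(bytes))
}
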