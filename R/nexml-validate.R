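## Structural NeXML validation.
##
## Checks the constraints the NeXML schema imposes on the document subset
## this package writes: correct root element and namespace, unique element
## ids, resolvable internal references (otu/char/state/states), and
## well-formed meta elements. It is a structural validator, not a full XSD
## validation (the NeXML schema is a multi-file XSD with imports).

#' Structurally validate a NeXML document
#'
#' @param source path to a NeXML file, or a literal XML string.
#' @return a list with \code{valid} (logical) and \code{problems}
#'   (character vector of findings; empty when valid).
#' @export
#' @examples
#' doc <- studyDocument(list(taxon("Danio rerio")),
#'                      list(matrixCharacter("fin", c("0", "1"))))
#' validateNexml(nexmlString(doc))$valid
validateNexml <- function(source) {
  problems <- character(0)
  x <- tryCatch(xml2::read_xml(source), error = function(e) e)
  if (inherits(x, "error")) {
    return(list(valid = FALSE,
                problems = paste("not well-formed XML:",
                                 conditionMessage(x))))
  }
  root <- xml2::xml_root(x)
  nsMap <- as.list(xml2::xml_ns(x))
  if (xml2::xml_name(root) != "nexml") {
    problems <- c(problems, "root element must be <nexml>")
  }
  if (!NEXML_NS %in% unlist(nsMap, use.names = FALSE)) {
    problems <- c(problems,
                  sprintf("NeXML namespace %s not declared", NEXML_NS))
  }
  if (is.na(xml2::xml_attr(root, "version"))) {
    problems <- c(problems, "<nexml> must carry a version attribute")
  }

  ## global id uniqueness
  ids <- xml2::xml_attr(xml2::xml_find_all(x, "//*[@id]"), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    problems <- c(problems,
                  paste("duplicate element id(s):", paste(dup, collapse = ", ")))
  }

  ## meta well-formedness
  for (m in xml2::xml_find_all(x, "//*[local-name() = 'meta']")) {
    type <- resolveQName(xml2::xml_attr(m, "type"), nsMap)
    if (is.null(type)) {
      problems <- c(problems, "meta element without xsi:type")
    } else if (type$local == "LiteralMeta") {
      if (is.na(xml2::xml_attr(m, "property")) ||
          is.na(xml2::xml_attr(m, "content"))) {
        problems <- c(problems, "LiteralMeta needs property and content")
      }
    } else if (type$local == "ResourceMeta") {
      if (is.na(xml2::xml_attr(m, "rel"))) {
        problems <- c(problems, "ResourceMeta needs rel")
      }
    } else {
      problems <- c(problems, paste("unknown meta xsi:type:", type$local))
    }
  }

  otuIds <- xml2::xml_attr(xml2::xml_find_all(root,
    "./*[local-name() = 'otus']/*[local-name() = 'otu']"), "id")

  for (chars in xml2::xml_find_all(root, "./*[local-name() = 'characters']")) {
    otusRef <- xml2::xml_attr(chars, "otus")
    if (is.na(otusRef)) {
      problems <- c(problems, "<characters> must reference an otus block")
    }
    fmt <- xml2::xml_find_first(chars, "./*[local-name() = 'format']")
    if (inherits(fmt, "xml_missing")) {
      problems <- c(problems, "<characters> without <format>")
      next
    }
    statesIds <- xml2::xml_attr(xml2::xml_find_all(fmt,
      "./*[local-name() = 'states']"), "id")
    stateIds <- character(0)
    for (sn in xml2::xml_find_all(fmt, "./*[local-name() = 'states']")) {
      single <- xml2::xml_find_all(sn, "./*[local-name() = 'state']")
      sids <- xml2::xml_attr(single, "id")
      if (anyNA(xml2::xml_attr(single, "symbol"))) {
        problems <- c(problems, "state without symbol attribute")
      }
      for (pn in xml2::xml_find_all(sn,
          "./*[local-name() = 'polymorphic_state_set' or local-name() = 'uncertain_state_set']")) {
        mrefs <- xml2::xml_attr(xml2::xml_find_all(pn,
          "./*[local-name() = 'member']"), "state")
        if (!length(mrefs)) {
          problems <- c(problems, "state set without members")
        }
        bad <- setdiff(mrefs, sids)
        if (length(bad)) {
          problems <- c(problems,
                        paste("state-set member references unknown state:",
                              paste(bad, collapse = ", ")))
        }
        sids <- c(sids, xml2::xml_attr(pn, "id"))
      }
      stateIds <- c(stateIds, sids)
    }
    charNodes <- xml2::xml_find_all(fmt, "./*[local-name() = 'char']")
    charIds <- xml2::xml_attr(charNodes, "id")
    bad <- setdiff(xml2::xml_attr(charNodes, "states"), statesIds)
    if (length(bad)) {
      problems <- c(problems,
                    paste("char references unknown states block:",
                          paste(bad, collapse = ", ")))
    }
    for (row in xml2::xml_find_all(chars,
        "./*[local-name() = 'matrix']/*[local-name() = 'row']")) {
      if (!xml2::xml_attr(row, "otu") %in% otuIds) {
        problems <- c(problems,
                      paste("row references unknown otu:",
                            xml2::xml_attr(row, "otu")))
      }
      cells <- xml2::xml_find_all(row, "./*[local-name() = 'cell']")
      badc <- setdiff(xml2::xml_attr(cells, "char"), charIds)
      if (length(badc)) {
        problems <- c(problems, paste("cell references unknown char:",
                                      paste(badc, collapse = ", ")))
      }
      bads <- setdiff(xml2::xml_attr(cells, "state"), stateIds)
      if (length(bads)) {
        problems <- c(problems, paste("cell references unknown state:",
                                      paste(bads, collapse = ", ")))
      }
    }
  }
  list(valid = length(problems) == 0L, problems = problems)
}
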