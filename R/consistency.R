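## Annotation consistency rules.
##
## The rules encode the Entity-Quality curation constraints: every
## annotation needs both an entity and a quality; a relational quality (one
## holding between two entities rather than inhering in one) needs a
## related entity, and a related entity is only meaningful with a
## relational quality; entities under 'biological process' (GO:0008150)
## pair only with qualities under 'process quality' (PATO:0001236);
## obsolete term references are flagged; and a character where some but
## not all states carry annotations is noted as incompletely annotated.

RULES <- data.frame(
  rule_id = c("E_MISSING_ENTITY", "E_MISSING_QUALITY",
              "E_RELATIONAL_NEEDS_RELATED", "E_NONRELATIONAL_HAS_RELATED",
              "E_PROCESS_NEEDS_PROCESS_QUALITY",
              "W_OBSOLETE_REFERENCE", "W_UNKNOWN_TERM",
              "N_INCOMPLETE_CHARACTER"),
  severity = c("error", "error", "error", "error", "error",
               "warning", "warning", "note"),
  stringsAsFactors = FALSE
)

#' Consistency rule ids
#' @return character vector of all rule ids, with severity derived from the
#'   prefix (\code{E_} error, \code{W_} warning, \code{N_} note).
#' @export
allRules <- function() RULES$rule_id

ruleSeverity <- function(rule_id) {
  RULES$severity[match(rule_id, RULES$rule_id)]
}

#' Build a rule configuration
#'
#' @param processEntityRoot entity root of the process rule; default the
#'   Gene Ontology \emph{biological process} id \code{"GO:0008150"}.
#' @param processQualityRoot quality root of the process rule; default the
#'   PATO \emph{process quality} id \code{"PATO:0001236"}.
#' @param relationalQualityRoot root of the relational-quality branch. No
#'   default exists — supplying a made-up id would be worse than requiring
#'   one — so the relational rules error without it.
#' @param enabledRules character vector of rule ids to evaluate.
#' @return a \code{\linkS4class{RuleConfig}}.
#' @export
ruleConfig <- function(processEntityRoot = "GO:0008150",
                       processQualityRoot = "PATO:0001236",
                       relationalQualityRoot = NA_character_,
                       enabledRules = allRules()) {
  bad <- setdiff(enabledRules, allRules())
  if (length(bad)) {
    eqStop("eq_config_error", "unknown rule id(s): %s",
           paste(bad, collapse = ", "))
  }
  new("RuleConfig",
      processEntityRoot = processEntityRoot,
      processQualityRoot = processQualityRoot,
      relationalQualityRoot = as.character(relationalQualityRoot),
      enabledRules = enabledRules)
}

## verify that the roots of the enabled rules resolve in the graph
assertConfig <- function(graph, config) {
  enabled <- config@enabledRules
  if ("E_PROCESS_NEEDS_PROCESS_QUALITY" %in% enabled) {
    for (root in c(config@processEntityRoot, config@processQualityRoot)) {
      if (!root %in% names(graph@terms)) {
        eqStop("eq_config_error",
               "process-rule root '%s' not present in the loaded graph", root)
      }
    }
  }
  if (any(c("E_RELATIONAL_NEEDS_RELATED", "E_NONRELATIONAL_HAS_RELATED")
          %in% enabled)) {
    root <- config@relationalQualityRoot
    if (is.na(root)) {
      eqStop("eq_config_error",
             "relationalQualityRoot must be configured for the relational rules")
    }
    if (!root %in% names(graph@terms)) {
      eqStop("eq_config_error",
             "relational-quality root '%s' not present in the loaded graph",
             root)
    }
  }
  invisible(TRUE)
}

emptyIssues <- function() {
  data.frame(rule_id = character(0), severity = character(0),
             character = integer(0), state = character(0),
             annotation = integer(0), message = character(0),
             stringsAsFactors = FALSE)
}

issueRow <- function(rule_id, message) {
  data.frame(rule_id = rule_id, severity = ruleSeverity(rule_id),
             character = NA_integer_, state = NA_character_,
             annotation = NA_integer_, message = message,
             stringsAsFactors = FALSE)
}

#' Check one EQ annotation against the rules
#'
#' Rules are independent: one annotation can yield several issues. Rules
#' that reason over the ontology (relational, process) are evaluated only
#' when the terms they inspect are present in the graph; a reference to an
#' id the graph does not contain yields a \code{W_UNKNOWN_TERM} warning
#' instead of failing the check (curators routinely work against ontology
#' slices).
#'
#' @param ann an \code{\linkS4class{EQAnnotation}}.
#' @param graph the loaded \code{\linkS4class{OntologyGraph}} (typically a
#'   \code{\link{combineGraphs}} union of anatomy, quality, process and
#'   taxonomy ontologies).
#' @param config a \code{\link{ruleConfig}}; roots of enabled rules must
#'   resolve in \code{graph} (configuration error otherwise).
#' @return a data frame of issues: \code{rule_id}, \code{severity},
#'   \code{character}, \code{state}, \code{annotation}, \code{message}
#'   (location columns \code{NA} at annotation scope).
#' @export
checkAnnotation <- function(ann, graph, config = ruleConfig()) {
  stopifnot(is(ann, "EQAnnotation"), is(graph, "OntologyGraph"))
  assertConfig(graph, config)
  enabled <- config@enabledRules
  known <- function(ref) !is.null(ref) && ref@id %in% names(graph@terms) &&
    !graph@terms[[ref@id]]@isPlaceholder
  issues <- list()
  add <- function(rule_id, message) {
    issues[[length(issues) + 1L]] <<- issueRow(rule_id, message)
  }

  if ("E_MISSING_ENTITY" %in% enabled && is.null(ann@entity)) {
    add("E_MISSING_ENTITY", "annotation lacks an entity term")
  }
  if ("E_MISSING_QUALITY" %in% enabled && is.null(ann@quality)) {
    add("E_MISSING_QUALITY", "annotation lacks a quality term")
  }

  relationalQuality <- NA
  if (known(ann@quality) && !is.na(config@relationalQualityRoot) &&
      config@relationalQualityRoot %in% names(graph@terms)) {
    relationalQuality <- isDescendant(graph, ann@quality@id,
                                      config@relationalQualityRoot)
  }
  if ("E_RELATIONAL_NEEDS_RELATED" %in% enabled &&
      isTRUE(relationalQuality) && is.null(ann@relatedEntity)) {
    add("E_RELATIONAL_NEEDS_RELATED",
        sprintf("relational quality '%s' needs a related entity",
                ann@quality@id))
  }
  if ("E_NONRELATIONAL_HAS_RELATED" %in% enabled &&
      !is.null(ann@relatedEntity) && isFALSE(relationalQuality)) {
    add("E_NONRELATIONAL_HAS_RELATED",
        sprintf("quality '%s' is not relational but a related entity is set",
                ann@quality@id))
  }
  if ("E_PROCESS_NEEDS_PROCESS_QUALITY" %in% enabled &&
      known(ann@entity) && known(ann@quality) &&
      isDescendant(graph, ann@entity@id, config@processEntityRoot) &&
      !isDescendant(graph, ann@quality@id, config@processQualityRoot)) {
    add("E_PROCESS_NEEDS_PROCESS_QUALITY",
        sprintf("process entity '%s' must pair with a process quality, not '%s'",
                ann@entity@id, ann@quality@id))
  }

  refs <- list(entity = ann@entity, quality = ann@quality,
               `related entity` = ann@relatedEntity)
  for (pos in names(refs)) {
    ref <- refs[[pos]]
    if (is.null(ref)) next
    if ("W_OBSOLETE_REFERENCE" %in% enabled && known(ref) &&
        graph@terms[[ref@id]]@isObsolete) {
      add("W_OBSOLETE_REFERENCE",
          sprintf("%s term '%s' is obsolete", pos, ref@id))
    }
    if ("W_UNKNOWN_TERM" %in% enabled && !known(ref)) {
      add("W_UNKNOWN_TERM",
          sprintf("%s term '%s' not found in the loaded ontologies", pos,
                  ref@id))
    }
  }
  if (!length(issues)) return(emptyIssues())
  out <- do.call(rbind, issues)
  ## deterministic order: by rule id, stable within (several W_ rows keep
  ## their entity/quality/related evaluation order)
  out <- out[order(out$rule_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check every annotation of a document
#'
#' Runs \code{\link{checkAnnotation}} over every annotation (locations
#' filled in: 1-based character index, state symbol, 1-based annotation
#' index) and additionally emits one \code{N_INCOMPLETE_CHARACTER} note for
#' each character where at least one state carries annotations and at least
#' one non-missing state carries none. A character with no annotations at
#' all is not incomplete — it simply has not been annotated yet. States
#' with the reserved missing symbol \code{"?"} are excluded from the
#' census. Issue ordering is deterministic: character, state, annotation,
#' rule id, with character-scope notes after that character's annotation
#' issues.
#'
#' @param doc a \code{\linkS4class{StudyDocument}}.
#' @inheritParams checkAnnotation
#' @return a data frame of issues (see \code{\link{checkAnnotation}}).
#' @export
checkDocument <- function(doc, graph, config = ruleConfig()) {
  stopifnot(is(doc, "StudyDocument"))
  assertConfig(graph, config)
  chunks <- list(emptyIssues())
  for (ci in seq_along(doc@characters)) {
    ch <- doc@characters[[ci]]
    annotated <- 0L
    unannotated <- 0L
    for (st in ch@states) {
      if (st@symbol == "?") next
      if (length(st@annotations)) annotated <- annotated + 1L
      else unannotated <- unannotated + 1L
    }
    for (st in ch@states) {
      for (ai in seq_along(st@annotations)) {
        found <- checkAnnotation(st@annotations[[ai]], graph, config)
        if (nrow(found)) {
          found$character <- ci
          found$state <- st@symbol
          found$annotation <- ai
          chunks[[length(chunks) + 1L]] <- found
        }
      }
    }
    if ("N_INCOMPLETE_CHARACTER" %in% config@enabledRules &&
        annotated > 0L && unannotated > 0L) {
      row <- issueRow("N_INCOMPLETE_CHARACTER",
                      sprintf("character %d ('%s'): %d of %d states lack annotations",
                              ci, ch@label, unannotated,
                              annotated + unannotated))
      row$character <- ci
      chunks[[length(chunks) + 1L]] <- row
    }
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}

#' Tabulate issues by rule
#' @param issues a data frame from \code{\link{checkDocument}}.
#' @return named integer vector over \code{\link{allRules}}.
#' @export
issueCounts <- function(issues) {
  counts <- table(factor(issues$rule_id, levels = allRules()))
  structure(as.integer(counts), names = allRules())
}

#' Render issues as TSV
#' @param issues a data frame from \code{\link{checkDocument}}.
#' @param path optional output path; when \code{NULL} the TSV lines are
#'   returned.
#' @return character vector of TSV lines (invisibly when written).
#' @export
issuesToTSV <- function(issues, path = NULL) {
  header <- paste(c("rule_id", "severity", "character", "state",
                    "annotation", "message"), collapse = "\t")
  body <- apply(issues, 1L, function(row) {
    paste(ifelse(is.na(row), "", trimws(row)), collapse = "\t")
  })
  lines <- c(header, if (length(body)) body)
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}
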