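## Deterministic generator of mini-ontologies and annotated matrices with
## recorded ground truth. Ground truth is written down at injection time,
## independently of the consistency checker; that the two agree exactly is
## the property the rest of the test suite leans on.

FIXTURE_IDS <- list(
  anatomyObsolete = "ANAT:0000999",
  relationalRoot = "PATO:9100000",
  plainRoot = "PATO:9200000",
  unknownTerm = "NOPE:0000001"
)

fixtureWords <- list(
  anatomy = c("basipterygium", "dorsal fin", "anal fin ray", "pectoral girdle",
              "opercle", "cleithrum", "hyomandibula", "parietal bone",
              "vertebral centrum", "neural arch", "scapula", "coracoid",
              "premaxilla", "dentary", "quadrate", "ceratobranchial",
              "epibranchial", "urohyal", "supraorbital", "lateral ethmoid",
              "pterygiophore", "radial element", "hypural plate", "caudal ray"),
  quality = c("rounded", "elongated", "serrated", "ossified", "bifurcated",
              "flattened"),
  relational = c("fused with", "in contact with", "overlapping", "attached to",
                 "separated from"),
  process_quality = c("arrested", "accelerated", "delayed", "prolonged",
                      "truncated process quality"),
  process = c("ossification", "fin regeneration", "scale development",
              "cartilage condensation", "suture closure",
              "segment patterning", "myogenesis", "chondrogenesis"),
  genus = c("Danio", "Ictalurus", "Amia", "Polyodon", "Gasterosteus",
            "Oryzias", "Salmo", "Perca")
)

mkTerm <- function(id, label, ...) new("Term", id = id, label = label, ...)

## random extra is_a edges among indices (child > parent keeps acyclicity)
randomDagEdges <- function(ids, backbone, extraProb = 0.15) {
  edges <- backbone
  for (i in seq(2L, length(ids))) {
    if (stats::runif(1) < extraProb) {
      p <- sample.int(i - 1L, 1L)
      edges <- rbind(edges, c(ids[i], ids[p]))
    }
  }
  unique(edges)
}

#' Generate the four fixture mini-ontologies
#'
#' Deterministic in the seed. The quality graph contains a root quality
#' with three disjoint branches: process qualities under
#' \code{PATO:0001236}, relational qualities under a minted root
#' (\code{PATO:9100000} — the rules take this root from configuration, so
#' the fixture supplies its own), and plain monadic qualities. The process
#' graph is rooted at \code{GO:0008150}; the anatomy graph has >= 20 terms
#' at depth >= 3 plus one obsolete term (with \code{replaced_by}) for
#' obsolete-reference scenarios; the taxonomy has >= 10 terms.
#'
#' @param seed integer RNG seed.
#' @return named list of \code{\linkS4class{OntologyGraph}}:
#'   \code{anatomy}, \code{quality}, \code{process}, \code{taxonomy}.
#' @export
#' @examples
#' g <- makeOntologies(7)
#' "GO:0008150" %in% termIds(g$process)
makeOntologies <- function(seed) {
  withSeed(as.integer(seed), {
    ## anatomy: 24 named terms, chain backbone of depth 4, random extra edges
    n <- 24L
    aids <- sprintf("ANAT:%07d", seq_len(n))
    labels <- sample(fixtureWords$anatomy, n)
    terms <- Map(mkTerm, aids, labels)
    names(terms) <- aids
    backbone <- cbind(aids[2:5], aids[1:4])
    for (i in 6:n) {
      backbone <- rbind(backbone, c(aids[i], aids[sample.int(i - 1L, 1L)]))
    }
    edges <- randomDagEdges(aids, backbone)
    obs <- FIXTURE_IDS$anatomyObsolete
    terms[[obs]] <- new("Term", id = obs, label = "vestigial structure",
                        isObsolete = TRUE, replacedBy = aids[2L])
    colnames(edges) <- c("child", "parent")
    anatomy <- new("OntologyGraph", terms = terms, edges = edges)

    ## quality: root + process-quality, relational and plain branches
    qterms <- list()
    qedges <- NULL
    addBranch <- function(rootId, rootLabel, childIds, childLabels) {
      qterms[[rootId]] <<- mkTerm(rootId, rootLabel)
      qedges <<- rbind(qedges, c(rootId, "PATO:0000001"))
      for (i in seq_along(childIds)) {
        qterms[[childIds[i]]] <<- mkTerm(childIds[i], childLabels[i])
        qedges <<- rbind(qedges, c(childIds[i], rootId))
      }
    }
    qterms[["PATO:0000001"]] <- mkTerm("PATO:0000001", "quality")
    addBranch("PATO:0001236", "process quality",
              sprintf("PATO:%07d", 1501:1505), fixtureWords$process_quality)
    addBranch(FIXTURE_IDS$relationalRoot, "relational quality",
              sprintf("PATO:%07d", 9100001:9100005), fixtureWords$relational)
    addBranch(FIXTURE_IDS$plainRoot, "monadic quality",
              sprintf("PATO:%07d", 9200001:9200006), fixtureWords$quality)
    ## a little depth inside two branches
    qedges <- rbind(qedges,
                    c("PATO:9200006", "PATO:9200001"),
                    c("PATO:0001505", "PATO:0001501"))
    colnames(qedges) <- c("child", "parent")
    quality <- new("OntologyGraph", terms = qterms, edges = unique(qedges))

    ## process: biological_process root with 8 descendants
    pids <- c("GO:0008150", sprintf("GO:%07d", 9000001:9000008))
    pterms <- Map(mkTerm, pids, c("biological process", fixtureWords$process))
    names(pterms) <- pids
    pbackbone <- cbind(pids[2:3], pids[1:2])
    for (i in 4:length(pids)) {
      pbackbone <- rbind(pbackbone, c(pids[i], pids[sample.int(i - 1L, 1L)]))
    }
    pedges <- randomDagEdges(pids, pbackbone)
    colnames(pedges) <- c("child", "parent")
    process <- new("OntologyGraph", terms = pterms, edges = pedges)

    ## taxonomy: a 12-term tree
    tids <- sprintf("TAX:%07d", seq_len(12L))
    tlabels <- c("Teleostei",
                 paste(sample(fixtureWords$genus, 11L, replace = TRUE),
                       sprintf("clade %d", 2:12)))
    tterms <- Map(mkTerm, tids, tlabels)
    names(tterms) <- tids
    tedges <- NULL
    for (i in 2:12) {
      tedges <- rbind(tedges, c(tids[i], tids[sample.int(i - 1L, 1L)]))
    }
    colnames(tedges) <- c("child", "parent")
    taxonomy <- new("OntologyGraph", terms = tterms, edges = tedges)

    list(anatomy = anatomy, quality = quality, process = process,
         taxonomy = taxonomy)
  })
}

#' Describe a fixture bundle to generate
#'
#' @param seed integer RNG seed.
#' @param nTaxa,nCharacters,statesPerCharacter matrix dimensions (defaults:
#'   8 taxa, 10 characters, 2 states — the scale of a small systematics
#'   study fragment).
#' @param annotatedFraction fraction of characters receiving clean EQ
#'   annotations on every state (default 0.8). Annotation is all-or-none
#'   per character so that incomplete-character ground truth can be planted
#'   exactly.
#' @param injectedViolations named integer vector, rule id -> count of
#'   violations to plant (see \code{\link{allRules}}).
#' @return a \code{\linkS4class{FixtureSpec}}.
#' @export
fixtureSpec <- function(seed, nTaxa = 8L, nCharacters = 10L,
                        statesPerCharacter = 2L, annotatedFraction = 0.8,
                        injectedViolations = integer(0)) {
  if (length(injectedViolations)) {
    bad <- setdiff(names(injectedViolations), allRules())
    if (length(bad)) {
      eqStop("eq_fixture_error", "unknown rule id(s) in injections: %s",
             paste(bad, collapse = ", "))
    }
  }
  new("FixtureSpec", seed = as.integer(seed), nTaxa = as.integer(nTaxa),
      nCharacters = as.integer(nCharacters),
      statesPerCharacter = as.integer(statesPerCharacter),
      annotatedFraction = annotatedFraction,
      injectedViolations = vapply(injectedViolations, as.integer, integer(1)))
}

injectionCount <- function(spec, rule) {
  v <- spec@injectedViolations
  if (rule %in% names(v)) v[[rule]] else 0L
}

#' Generate a fixture bundle
#'
#' Builds the four mini-ontologies, populates an annotated matrix with
#' clean EQ annotations (anatomy entity + plain monadic quality, satisfying
#' every rule), then plants exactly the requested violations at recorded
#' locations: annotation-level violations replace the clean annotation of a
#' distinct (character, state) slot each; incomplete characters are planted
#' by stripping the annotations of one state of an annotated character.
#' \code{expectedIssues} is recorded from this plan, never by running the
#' checker.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return a \code{\linkS4class{FixtureBundle}}.
#' @section Errors: an injection plan that does not fit the matrix
#'   dimensions (too few annotated slots, or incomplete characters with a
#'   single state) is a fixture error.
#' @export
#' @examples
#' b <- makeBundle(fixtureSpec(11, injectedViolations = c(E_MISSING_QUALITY = 3)))
#' expectedIssues(b)[["E_MISSING_QUALITY"]]
makeBundle <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  graphs <- makeOntologies(spec@seed)
  merged <- combineGraphs(graphs)
  config <- ruleConfig(relationalQualityRoot = FIXTURE_IDS$relationalRoot)

  cleanEntities <- setdiff(
    Filter(function(id) {
      t <- graphs$anatomy@terms[[id]]
      !t@isObsolete && !t@isPlaceholder
    }, termIds(graphs$anatomy)),
    character(0))
  plainQualities <- descendants(graphs$quality, FIXTURE_IDS$plainRoot)
  relationalQualities <- descendants(graphs$quality, FIXTURE_IDS$relationalRoot)
  processEntities <- descendants(graphs$process, "GO:0008150")
  taxonomyIds <- termIds(graphs$taxonomy)

  refTo <- function(graph, id) termRef(id, graph@terms[[id]]@label)

  withSeed(spec@seed + 104729L, {
    ## document skeleton
    taxa <- lapply(seq_len(spec@nTaxa), function(i) {
      tid <- sample(taxonomyIds, 1L)
      taxon(sprintf("%s specimen %d", sample(fixtureWords$genus, 1L), i),
            refTo(graphs$taxonomy, tid))
    })
    syms <- as.character(seq_len(spec@statesPerCharacter) - 1L)
    characters <- lapply(seq_len(spec@nCharacters), function(j) {
      anat <- graphs$anatomy@terms[[sample(cleanEntities, 1L)]]@label
      states <- lapply(syms, function(s)
        characterState(s, sprintf("%s form %s", anat, s)))
      new("MatrixCharacter", label = sprintf("%d. %s", j, anat),
          states = states)
    })
    doc <- studyDocument(taxa, characters,
                         sourceMetadata = list(
                           publication = "synthetic fixture matrix",
                           curators = "fixture generator"))
    for (ti in seq_len(spec@nTaxa)) {
      for (ci in seq_len(spec@nCharacters)) {
        if (length(syms) >= 2L && stats::runif(1) < 0.1) {
          doc <- setCell(doc, ti, ci, sample(syms, 2L))
        } else {
          doc <- setCell(doc, ti, ci, sample(syms, 1L))
        }
      }
    }

    cleanAnnotation <- function() {
      eqAnnotation(entity = refTo(merged, sample(cleanEntities, 1L)),
                   quality = refTo(merged, sample(plainQualities, 1L)))
    }

    ## clean annotations: all-or-none per character
    nAnn <- round(spec@annotatedFraction * spec@nCharacters)
    annotatedChars <- sort(sample.int(spec@nCharacters, nAnn))
    for (ci in annotatedChars) {
      for (s in syms) {
        if (s == "?") next
        doc <- annotateState(doc, ci, s, cleanAnnotation())
      }
    }

    ## plant incomplete characters: strip one state's annotations
    incN <- injectionCount(spec, "N_INCOMPLETE_CHARACTER")
    if (incN > length(annotatedChars)) {
      eqStop("eq_fixture_error",
             "cannot plant %d incomplete characters with only %d annotated",
             incN, length(annotatedChars))
    }
    if (incN > 0L && spec@statesPerCharacter < 2L) {
      eqStop("eq_fixture_error",
             "incomplete characters need at least two states")
    }
    incChars <- if (incN) {
      annotatedChars[sample.int(length(annotatedChars), incN)]
    } else integer(0)
    strippedSlots <- character(0)
    for (ci in incChars) {
      s <- sample(syms, 1L)
      doc <- setStateAnnotations(doc, ci, s, list())
      strippedSlots <- c(strippedSlots, sprintf("%d_%s", ci, s))
    }

    ## annotation-level violations replace clean annotations, one slot each
    violation <- function(rule) {
      switch(rule,
        E_MISSING_ENTITY = eqAnnotation(
          quality = refTo(merged, sample(plainQualities, 1L))),
        E_MISSING_QUALITY = eqAnnotation(
          entity = refTo(merged, sample(cleanEntities, 1L))),
        E_RELATIONAL_NEEDS_RELATED = eqAnnotation(
          entity = refTo(merged, sample(cleanEntities, 1L)),
          quality = refTo(merged, sample(relationalQualities, 1L))),
        E_NONRELATIONAL_HAS_RELATED = eqAnnotation(
          entity = refTo(merged, sample(cleanEntities, 1L)),
          quality = refTo(merged, sample(plainQualities, 1L)),
          relatedEntity = refTo(merged, sample(cleanEntities, 1L))),
        E_PROCESS_NEEDS_PROCESS_QUALITY = eqAnnotation(
          entity = refTo(merged, sample(processEntities, 1L)),
          quality = refTo(merged, sample(plainQualities, 1L))),
        W_OBSOLETE_REFERENCE = eqAnnotation(
          entity = termRef(FIXTURE_IDS$anatomyObsolete, "vestigial structure"),
          quality = refTo(merged, sample(plainQualities, 1L))),
        W_UNKNOWN_TERM = eqAnnotation(
          entity = termRef(FIXTURE_IDS$unknownTerm),
          quality = refTo(merged, sample(plainQualities, 1L))),
        eqStop("eq_fixture_error", "rule '%s' is not injectable", rule)
      )
    }
    annRules <- setdiff(names(spec@injectedViolations),
                        "N_INCOMPLETE_CHARACTER")
    annRules <- annRules[spec@injectedViolations[annRules] > 0L]
    plan <- rep(annRules, spec@injectedViolations[annRules])
    slots <- character(0)
    for (ci in annotatedChars) {
      for (s in syms) {
        key <- sprintf("%d_%s", ci, s)
        if (!key %in% strippedSlots) slots <- c(slots, key)
      }
    }
    if (length(plan) > length(slots)) {
      eqStop("eq_fixture_error",
             "injection plan needs %d annotated slots, only %d available",
             length(plan), length(slots))
    }
    chosen <- if (length(plan)) sample(slots, length(plan)) else character(0)
    for (k in seq_along(plan)) {
      parts <- strsplit(chosen[k], "_", fixed = TRUE)[[1L]]
      doc <- setStateAnnotations(doc, as.integer(parts[1L]), parts[2L],
                                 list(violation(plan[k])))
    }

    expected <- structure(integer(length(allRules())), names = allRules())
    for (rule in names(spec@injectedViolations)) {
      expected[[rule]] <- spec@injectedViolations[[rule]]
    }

    new("FixtureBundle",
        anatomyGraph = graphs$anatomy, qualityGraph = graphs$quality,
        processGraph = graphs$process, taxonomyGraph = graphs$taxonomy,
        document = doc, expectedIssues = expected, ruleConfig = config)
  })
}

#' Write a fixture bundle to a directory
#'
#' Emits \code{anatomy.obo}, \code{quality.obo}, \code{process.obo},
#' \code{taxonomy.obo}, \code{matrix.xml}, \code{rule-config.json} and
#' \code{expected-issues.tsv}.
#'
#' @param bundle a \code{\linkS4class{FixtureBundle}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeFixtureBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeOBO(bundle@anatomyGraph, file.path(dir, "anatomy.obo"))
  writeOBO(bundle@qualityGraph, file.path(dir, "quality.obo"))
  writeOBO(bundle@processGraph, file.path(dir, "process.obo"))
  writeOBO(bundle@taxonomyGraph, file.path(dir, "taxonomy.obo"))
  writeNexml(bundle@document, file.path(dir, "matrix.xml"))
  cfg <- bundle@ruleConfig
  jsonlite::write_json(
    list(process_entity_root = cfg@processEntityRoot,
         process_quality_root = cfg@processQualityRoot,
         relational_quality_root = cfg@relationalQualityRoot,
         enabled_rules = cfg@enabledRules),
    file.path(dir, "rule-config.json"), auto_unbox = TRUE, pretty = TRUE)
  exp <- bundle@expectedIssues
  writeLines(c("rule_id\tcount",
               sprintf("%s\t%d", names(exp), exp)),
             file.path(dir, "expected-issues.tsv"))
  invisible(dir)
}

#' Read a rule configuration from JSON
#'
#' Inverse of the \code{rule-config.json} written by
#' \code{\link{writeFixtureBundle}}; also the CLI \code{--config} format.
#'
#' @param path JSON file with keys \code{process_entity_root},
#'   \code{process_quality_root}, \code{relational_quality_root},
#'   \code{enabled_rules}.
#' @return a \code{\linkS4class{RuleConfig}}.
#' @export
readRuleConfigJSON <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ruleConfig(
    processEntityRoot = cfg$process_entity_root %||% "GO:0008150",
    processQualityRoot = cfg$process_quality_root %||% "PATO:0001236",
    relationalQualityRoot = cfg$relational_quality_root %||% NA_character_,
    enabledRules = cfg$enabled_rules %||% allRules()
  )
}
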