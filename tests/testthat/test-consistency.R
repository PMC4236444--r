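## shared fixture graph/config for rule tests
ruleWorld <- local({
  graphs <- makeOntologies(1)
  list(graph = combineGraphs(graphs),
       config = ruleConfig(relationalQualityRoot = "PATO:9100000"))
})

entityRef <- termRef("ANAT:0000003")
plainQ <- termRef("PATO:9200002")
relationalQ <- termRef("PATO:9100001")
processE <- termRef("GO:9000001")
processQ <- termRef("PATO:0001501")

ruleIdsOf <- function(ann) {
  checkAnnotation(ann, ruleWorld$graph, ruleWorld$config)$rule_id
}

test_that("EQ completeness: both an entity and a quality are required", {
  expect_equal(ruleIdsOf(eqAnnotation(entity = entityRef)),
               "E_MISSING_QUALITY")
  expect_equal(ruleIdsOf(eqAnnotation(quality = plainQ)),
               "E_MISSING_ENTITY")
  expect_length(ruleIdsOf(eqAnnotation(entity = entityRef, quality = plainQ)),
                0L)
})

test_that("relational qualities need a related entity, and only they may have one", {
  expect_equal(ruleIdsOf(eqAnnotation(entity = entityRef, quality = relationalQ)),
               "E_RELATIONAL_NEEDS_RELATED")
  expect_length(
    ruleIdsOf(eqAnnotation(entity = entityRef, quality = relationalQ,
                           relatedEntity = termRef("ANAT:0000004"))),
    0L)
  expect_equal(
    ruleIdsOf(eqAnnotation(entity = entityRef, quality = plainQ,
                           relatedEntity = termRef("ANAT:0000004"))),
    "E_NONRELATIONAL_HAS_RELATED")
})

test_that("process entities pair only with process qualities", {
  expect_equal(ruleIdsOf(eqAnnotation(entity = processE, quality = plainQ)),
               "E_PROCESS_NEEDS_PROCESS_QUALITY")
  expect_length(ruleIdsOf(eqAnnotation(entity = processE, quality = processQ)),
                0L)
  ## non-process entity with a process quality is fine under this rule
  expect_length(ruleIdsOf(eqAnnotation(entity = entityRef, quality = processQ)),
                0L)
})

test_that("obsolete and unknown references warn without aborting", {
  expect_equal(
    ruleIdsOf(eqAnnotation(entity = termRef("ANAT:0000999"), quality = plainQ)),
    "W_OBSOLETE_REFERENCE")
  expect_equal(
    ruleIdsOf(eqAnnotation(entity = termRef("NOPE:1"), quality = plainQ)),
    "W_UNKNOWN_TERM")
})

test_that("rules are independent: one annotation can earn several issues", {
  ids <- ruleIdsOf(eqAnnotation(quality = relationalQ,
                                comment = "missing entity AND relational"))
  expect_setequal(ids, c("E_MISSING_ENTITY", "E_RELATIONAL_NEEDS_RELATED"))
})

test_that("enabled roots must resolve in the loaded graph", {
  g <- parseOBO(chainOBO())  # contains neither GO:0008150 nor any PATO root
  expect_error(checkAnnotation(eqAnnotation(entity = termRef("A")), g,
                               ruleConfig(relationalQualityRoot = "A")),
               class = "eq_config_error")
  expect_error(checkDocument(studyDocument(), g, ruleConfig()),
               class = "eq_config_error")
  ## with the ontology-dependent rules disabled, a slice graph is fine
  slim <- ruleConfig(enabledRules = c("E_MISSING_ENTITY", "E_MISSING_QUALITY"))
  expect_length(checkAnnotation(eqAnnotation(entity = termRef("A")), g,
                                slim)$rule_id, 1L)
})

test_that("incomplete characters: some but not all states annotated, '?' exempt", {
  doc <- studyDocument(
    list(taxon("T")),
    list(matrixCharacter("mixed", c("0", "1")),
         matrixCharacter("untouched", c("0", "1")),
         matrixCharacter("full", c("0", "1")),
         matrixCharacter("missing exempt", c("0", "1", "?")))
  )
  clean <- function() eqAnnotation(entity = entityRef, quality = plainQ)
  doc <- annotateState(doc, 1, "0", clean())
  doc <- annotateState(doc, 3, "0", clean())
  doc <- annotateState(doc, 3, "1", clean())
  doc <- annotateState(doc, 4, "0", clean())
  doc <- annotateState(doc, 4, "1", clean())

  issues <- checkDocument(doc, ruleWorld$graph, ruleWorld$config)
  notes <- issues[issues$rule_id == "N_INCOMPLETE_CHARACTER", ]
  expect_equal(notes$character, 1L)   # only the mixed character
  expect_equal(nrow(issues), 1L)      # clean annotations add nothing
})

test_that("document check equals per-annotation checks plus located issues", {
  doc <- studyDocument(list(taxon("T")),
                       list(matrixCharacter("c", c("0", "1"))))
  bad <- eqAnnotation(entity = processE, quality = plainQ)
  doc <- annotateState(doc, 1, "1", bad)
  doc <- annotateState(doc, 1, "0",
                       eqAnnotation(entity = entityRef, quality = plainQ))
  issues <- checkDocument(doc, ruleWorld$graph, ruleWorld$config)
  located <- issues[!is.na(issues$annotation), ]
  expect_equal(located$character, 1L)
  expect_equal(located$state, "1")
  expect_equal(located$annotation, 1L)
  expect_identical(located[, c("rule_id", "severity", "message")],
                   checkAnnotation(bad, ruleWorld$graph,
                                   ruleWorld$config)[, c("rule_id", "severity",
                                                         "message")])
})

test_that("adding an annotation never removes another annotation's issues", {
  doc <- studyDocument(list(taxon("T")),
                       list(matrixCharacter("c", c("0", "1"))))
  doc <- annotateState(doc, 1, "0", eqAnnotation(entity = entityRef))
  before <- checkDocument(doc, ruleWorld$graph, ruleWorld$config)
  doc2 <- annotateState(doc, 1, "1",
                        eqAnnotation(quality = relationalQ))
  after <- checkDocument(doc2, ruleWorld$graph, ruleWorld$config)
  key <- function(x) paste(x$rule_id, x$character, x$state, x$annotation)
  expect_true(all(key(before[before$rule_id != "N_INCOMPLETE_CHARACTER", ])
                  %in% key(after)))
})

test_that("issue severities derive from the rule-id prefix", {
  doc <- studyDocument(list(taxon("T")),
                       list(matrixCharacter("c", c("0", "1"))))
  doc <- annotateState(doc, 1, "0", eqAnnotation(entity = entityRef))  # error
  doc <- annotateState(doc, 1, "0",
                       eqAnnotation(entity = termRef("ANAT:0000999"),
                                    quality = plainQ))                 # warning
  ## state "1" unannotated -> note
  issues <- checkDocument(doc, ruleWorld$graph, ruleWorld$config)
  got <- unique(issues[, c("rule_id", "severity")])
  expect_setequal(
    paste(got$rule_id, got$severity),
    c("E_MISSING_QUALITY error", "W_OBSOLETE_REFERENCE warning",
      "N_INCOMPLETE_CHARACTER note"))
})

test_that("issuesToTSV renders a header plus one row per issue", {
  doc <- annotateState(
    studyDocument(list(taxon("T")), list(matrixCharacter("c", c("0", "1")))),
    1, "0", eqAnnotation(entity = entityRef))
  issues <- checkDocument(doc, ruleWorld$graph, ruleWorld$config)
  tsv <- issuesToTSV(issues)
  expect_equal(length(tsv), nrow(issues) + 1L)
  expect_match(tsv[1], "^rule_id\t")
  expect_match(tsv[2], "^E_MISSING_QUALITY\terror\t1\t0\t1\t")
})
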