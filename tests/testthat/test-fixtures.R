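test_that("generated ontologies are deterministic and contain the rule roots", {
  g1 <- makeOntologies(3)
  g2 <- makeOntologies(3)
  for (name in names(g1)) {
    expect_identical(writeOBO(g1[[name]]), writeOBO(g2[[name]]),
                     info = name)
  }
  expect_false(identical(writeOBO(makeOntologies(4)$anatomy),
                         writeOBO(g1$anatomy)))

  cfg <- bundleRuleConfig(makeBundle(fixtureSpec(3)))
  expect_true(cfg@processEntityRoot %in% termIds(g1$process))
  expect_true(cfg@processQualityRoot %in% termIds(g1$quality))
  expect_true(cfg@relationalQualityRoot %in% termIds(g1$quality))
})

test_that("generated graphs meet the documented size and shape floors", {
  g <- makeOntologies(12)
  expect_gte(length(ontologyTerms(g$anatomy)), 20L)
  expect_gte(length(ontologyTerms(g$taxonomy)), 10L)
  expect_gte(length(descendants(g$process, "GO:0008150")), 5L)
  q <- g$quality
  for (root in c("PATO:0001236", "PATO:9100000", "PATO:9200000")) {
    expect_gte(length(descendants(q, root)), 4L)
  }
  ## the three quality branches are disjoint
  expect_length(intersect(descendants(q, "PATO:9100000"),
                          descendants(q, "PATO:9200000")), 0L)
  ## anatomy depth >= 3: a chain of length 4 exists from the root
  a <- g$anatomy
  depth <- function(graph, id) {
    kids <- descendants(graph, id)
    if (!length(kids)) return(0L)
    e <- isaEdges(graph)
    direct <- e[e[, "parent"] == id, "child"]
    1L + max(vapply(direct, function(k) depth(graph, k), integer(1)))
  }
  expect_gte(depth(a, "ANAT:0000001"), 3L)
})

test_that("generated closures match the naive oracle", {
  g <- makeOntologies(9)
  for (graph in g) {
    oracle <- naiveClosure(graph)
    for (id in termIds(graph)) {
      expect_equal(sort(descendants(graph, id, includeSelf = TRUE)),
                   oracle[[id]])
    }
  }
})

test_that("planted violations are reproduced exactly by the checker", {
  spec <- fixtureSpec(11, nTaxa = 8, nCharacters = 10, statesPerCharacter = 2,
                      annotatedFraction = 0.8,
                      injectedViolations = c(
                        E_MISSING_QUALITY = 3L,
                        E_RELATIONAL_NEEDS_RELATED = 2L,
                        E_PROCESS_NEEDS_PROCESS_QUALITY = 1L,
                        N_INCOMPLETE_CHARACTER = 2L))
  b <- makeBundle(spec)
  issues <- checkDocument(bundleDocument(b), combineGraphs(bundleGraphs(b)),
                          bundleRuleConfig(b))
  expect_identical(issueCounts(issues), expectedIssues(b))
})

test_that("a bundle with no injections is perfectly clean", {
  b <- makeBundle(fixtureSpec(2))
  issues <- checkDocument(bundleDocument(b), combineGraphs(bundleGraphs(b)),
                          bundleRuleConfig(b))
  expect_equal(nrow(issues), 0L)
})

test_that("expected issues survive a NeXML round trip of the bundle document", {
  b <- makeBundle(fixtureSpec(13, injectedViolations = c(
    E_MISSING_ENTITY = 1L, E_NONRELATIONAL_HAS_RELATED = 2L,
    W_OBSOLETE_REFERENCE = 1L, N_INCOMPLETE_CHARACTER = 1L)))
  doc2 <- readNexml(nexmlString(bundleDocument(b)))
  expect_identical(doc2, bundleDocument(b))
  issues <- checkDocument(doc2, combineGraphs(bundleGraphs(b)),
                          bundleRuleConfig(b))
  expect_identical(issueCounts(issues), expectedIssues(b))
})

test_that("infeasible injection plans are rejected", {
  expect_error(
    makeBundle(fixtureSpec(1, nCharacters = 2, annotatedFraction = 0.5,
                           injectedViolations = c(N_INCOMPLETE_CHARACTER = 2L))),
    class = "eq_fixture_error")
  expect_error(
    makeBundle(fixtureSpec(1, nCharacters = 2, statesPerCharacter = 2,
                           annotatedFraction = 1,
                           injectedViolations = c(E_MISSING_QUALITY = 40L))),
    class = "eq_fixture_error")
  expect_error(fixtureSpec(1, injectedViolations = c(BOGUS_RULE = 1L)),
               class = "eq_fixture_error")
})

test_that("writeFixtureBundle emits a loadable, consistent set of files", {
  dir <- tempfile()
  b <- makeBundle(fixtureSpec(21, injectedViolations = c(E_MISSING_QUALITY = 2L)))
  writeFixtureBundle(b, dir)
  expect_setequal(list.files(dir),
                  c("anatomy.obo", "quality.obo", "process.obo",
                    "taxonomy.obo", "matrix.xml", "rule-config.json",
                    "expected-issues.tsv"))
  suppressMessages({
    graph <- combineGraphs(lapply(file.path(dir, c("anatomy.obo", "quality.obo",
                                                   "process.obo", "taxonomy.obo")),
                                  readOBO))
  })
  cfg <- readRuleConfigJSON(file.path(dir, "rule-config.json"))
  doc <- readNexml(file.path(dir, "matrix.xml"))
  issues <- checkDocument(doc, graph, cfg)
  exp <- read.delim(file.path(dir, "expected-issues.tsv"))
  expect_equal(issueCounts(issues)[exp$rule_id], setNames(exp$count, exp$rule_id))
})
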