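test_that("requestTerm mints unique namespaced pending requests", {
  store <- tmpStore()
  req <- requestTerm(store, "basipterygium", "fin support bone",
                     superclass = termRef("ANAT:0000001"),
                     synonyms = c("basal pterygiophore"), submitter = "team")
  expect_true(isPending(req))
  expect_match(provisionalId(req), "^http://example.org/provisional/[0-9a-f-]+$")

  expect_error(requestTerm(store, "", submitter = "team"),
               class = "eq_validation_error")
  expect_error(requestTerm(store, "x", submitter = ""),
               class = "eq_validation_error")

  ## duplicate labels allowed, but warned about
  expect_warning(requestTerm(store, "basipterygium", submitter = "team"),
                 class = "eq_duplicate_label_warning")
})

test_that("listRequests returns a submitter's records in creation order", {
  store <- tmpStore()
  ids <- vapply(1:3, function(i)
    provisionalId(requestTerm(store, paste0("term ", i), submitter = "team")),
    character(1))
  got <- listRequests(store, "team")
  expect_length(got, 3L)
  expect_equal(vapply(got, provisionalId, character(1)), ids)
  expect_length(listRequests(store, "nobody"), 0L)

  ## a shared submitter id makes requests visible across call sites
  store2 <- brokerStore(store@path)
  expect_length(listRequests(store2, "team"), 3L)
  requestTerm(store2, "from elsewhere", submitter = "team")
  expect_length(listRequests(store, "team"), 4L)
})

test_that("resolveRequest sets the permanent id exactly once", {
  store <- tmpStore()
  pid <- provisionalId(requestTerm(store, "t", submitter = "team"))
  uri <- "http://purl.obolibrary.org/obo/UBERON_0000001"
  req <- resolveRequest(store, pid, uri)
  expect_false(isPending(req))
  expect_equal(permanentId(req), uri)

  expect_error(resolveRequest(store, pid, uri),
               class = "eq_already_resolved_error")
  expect_error(resolveRequest(store, "urn:missing", uri),
               class = "eq_missing_request_error")
  pid2 <- provisionalId(requestTerm(store, "t2", submitter = "team"))
  expect_error(resolveRequest(store, pid2, pid2),
               class = "eq_validation_error")

  ## resolution to an already-existing ontology term's URI is accepted
  req2 <- resolveRequest(store, pid2, expandTermId("ANAT:0000002"))
  expect_s4_class(req2, "ProvisionalRequest")
})

test_that("store survives close/reopen with an identical record set", {
  store <- tmpStore()
  for (i in 1:5) requestTerm(store, paste0("term ", i), submitter = "team")
  pid <- provisionalId(listRequests(store, "team")[[2]])
  resolveRequest(store, pid, "http://example.org/perm/1")
  before <- listRequests(store, "team")
  reopened <- brokerStore(store@path)
  expect_identical(listRequests(reopened, "team"), before)
})

test_that("sync_and_migrate rewrites resolved ids, leaves pending ones, and is idempotent", {
  store <- tmpStore()
  graphs <- makeOntologies(7)
  graph <- combineGraphs(graphs)
  p1 <- provisionalId(requestTerm(store, "still pending", submitter = "team"))
  p2 <- provisionalId(requestTerm(store, "now resolved", submitter = "team"))

  doc <- studyDocument(list(taxon("T")),
                       list(matrixCharacter("c", c("0", "1"))))
  doc <- annotateState(doc, 1, "0",
                       eqAnnotation(entity = termRef(p1),
                                    quality = termRef("PATO:9200001")))
  for (i in 1:4) {
    doc <- annotateState(doc, 1, "1",
                         eqAnnotation(entity = termRef(p2),
                                      quality = termRef("PATO:9200002")))
  }
  resolveRequest(store, p2, expandTermId("ANAT:0000002"))

  res <- syncAndMigrate(store, "team", graph, doc)
  reps <- replacements(res$report)
  expect_equal(names(reps), p2)
  expect_equal(reps[[p2]]$count, 4L)
  expect_equal(reps[[p2]]$new_id, expandTermId("ANAT:0000002"))
  expect_equal(untouchedProvisional(res$report), p1)
  expect_true(p1 %in% documentTermIds(res$document))
  ## pending term usable: merged into the session graph as provisional
  expect_true(getTerm(res$graph, p1)@isProvisional)

  ## no reference resolves further after the sync
  for (id in documentTermIds(res$document)) {
    if (id %in% termIds(res$graph)) {
      expect_equal(resolveReplacement(res$graph, id), id)
    }
  }

  ## second sync is a no-op
  res2 <- syncAndMigrate(store, "team", res$graph, res$document)
  expect_length(replacements(res2$report), 0L)
  expect_identical(res2$document, res$document)
})

test_that("migration chains through ordinary obsolescence after resolution", {
  ## P resolved to Y:1, which is itself obsolete with replaced_by Z:2
  g <- parseOBO(c("[Term]", "id: Y:1", "is_obsolete: true",
                  "replaced_by: Z:2", "", "[Term]", "id: Z:2"))
  store <- tmpStore()
  p <- provisionalId(requestTerm(store, "chained", submitter = "team"))
  doc <- annotateState(
    studyDocument(list(taxon("T")), list(matrixCharacter("c", c("0", "1")))),
    1, "0", eqAnnotation(entity = termRef(p), quality = termRef("Q:0")))
  resolveRequest(store, p, "Y:1")
  res <- syncAndMigrate(store, "team", g, doc)
  expect_equal(replacements(res$report)[[p]]$new_id, "Z:2")
  expect_true("Z:2" %in% documentTermIds(res$document))
  expect_false("Y:1" %in% documentTermIds(res$document))
})
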