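test_that("parseOBO transcribes stanzas, edges and obsolescence metadata", {
  g <- parseOBO(chainOBO())
  expect_setequal(termIds(g), c("A", "B", "C"))
  expect_equal(nrow(isaEdges(g)), 2L)
  expect_equal(getTerm(g, "B")@label, "beta")

  obs <- parseOBO(c("[Term]", "id: X:1", "name: old", "is_obsolete: true",
                    "replaced_by: X:2", "",
                    "[Term]", "id: X:2", "name: new"))
  expect_true(getTerm(obs, "X:1")@isObsolete)
  expect_equal(getTerm(obs, "X:1")@replacedBy, "X:2")

  syn <- parseOBO(c("[Term]", "id: X:1", "name: n",
                    'def: "a bone" [ref:1]',
                    'synonym: "leg bone" EXACT []',
                    "namespace: anatomy"))
  t <- getTerm(syn, "X:1")
  expect_equal(t@definition, "a bone")
  expect_equal(t@synonyms[[1]], list(text = "leg bone", scope = "EXACT"))
  expect_equal(t@namespace, "anatomy")
})

test_that("parseOBO rejects duplicate ids, cycles and malformed lines", {
  expect_error(parseOBO(c("[Term]", "id: X:1", "", "[Term]", "id: X:1")),
               class = "eq_parse_error")
  expect_error(parseOBO(c("[Term]", "id: A", "is_a: B", "",
                          "[Term]", "id: B", "is_a: A")),
               class = "eq_cycle_error")
  expect_error(parseOBO(c("[Term]", "id: A", "not a tag line")),
               class = "eq_parse_error")
})

test_that("unknown tags and dangling parents are kept, with notices", {
  expect_message(
    g <- parseOBO(c("[Term]", "id: A", "xref: DB:1", "is_a: GHOST:1")),
    "placeholder")
  expect_true("GHOST:1" %in% termIds(g))
  expect_true(getTerm(g, "GHOST:1")@isPlaceholder)
})

test_that("descendants walks is_a chains and excludes obsolete terms", {
  g <- parseOBO(chainOBO())
  expect_setequal(descendants(g, "A", includeSelf = TRUE), c("A", "B", "C"))
  expect_setequal(descendants(g, "A"), c("B", "C"))
  expect_length(descendants(g, "C"), 0L)
  expect_error(descendants(g, "NOPE"), class = "eq_missing_term_error")

  obs <- parseOBO(c("[Term]", "id: A", "",
                    "[Term]", "id: B", "is_a: A", "is_obsolete: true", "",
                    "[Term]", "id: C", "is_a: B"))
  d <- descendants(obs, "A", includeSelf = TRUE)
  expect_false("B" %in% d)
  expect_false("C" %in% d)  # reachable only through an obsolete term
})

test_that("descendants equals the naive fixed-point closure on random DAGs", {
  set.seed(7)
  g <- randomDagGraph(20, 0.15)
  oracle <- naiveClosure(g)
  for (id in termIds(g)) {
    expect_equal(sort(descendants(g, id, includeSelf = TRUE)), oracle[[id]],
                 info = id)
  }
})

test_that("isDescendant agrees with descendants on random pairs", {
  set.seed(7)
  g <- randomDagGraph(20, 0.15)
  oracle <- naiveClosure(g)
  ids <- termIds(g)
  for (k in seq_len(100)) {
    a <- sample(ids, 1)
    b <- sample(ids, 1)
    expect_identical(isDescendant(g, a, b), a %in% oracle[[b]],
                     info = paste(a, "under", b))
  }
  expect_true(isDescendant(g, ids[1], ids[1]))
})

test_that("resolveReplacement follows chains, detects cycles and dangling ids", {
  g <- parseOBO(c("[Term]", "id: a", "is_obsolete: true", "replaced_by: b", "",
                  "[Term]", "id: b", "is_obsolete: true", "replaced_by: c", "",
                  "[Term]", "id: c"))
  expect_equal(resolveReplacement(g, "a"), "c")
  expect_equal(resolveReplacement(g, "c"), "c")
  ## idempotence
  expect_equal(resolveReplacement(g, resolveReplacement(g, "a")),
               resolveReplacement(g, "a"))

  cyc <- parseOBO(c("[Term]", "id: a", "is_obsolete: true", "replaced_by: b", "",
                    "[Term]", "id: b", "is_obsolete: true", "replaced_by: a"))
  expect_error(resolveReplacement(cyc, "a"), class = "eq_cycle_error")

  dang <- parseOBO(c("[Term]", "id: a", "is_obsolete: true",
                     "replaced_by: GONE:1"))
  expect_error(resolveReplacement(dang, "a"),
               class = "eq_dangling_replacement_error")

  multi <- parseOBO(c("[Term]", "id: a", "is_obsolete: true",
                      "replaced_by: b", "replaced_by: c", "",
                      "[Term]", "id: b", "", "[Term]", "id: c"))
  expect_warning(out <- resolveReplacement(multi, "a"),
                 class = "eq_multiple_replacements_warning")
  expect_equal(out, "b")
})

test_that("mergeProvisional adds pending terms with edges and obsoletes resolved ones", {
  g <- parseOBO(chainOBO())
  pending <- new("ProvisionalRequest", provisionalId = "urn:prov/1",
                 label = "new bone", definition = "d",
                 suggestedSuperclass = termRef("A"), submitter = "team",
                 created = "2026-01-01T00:00:00Z")
  merged <- mergeProvisional(g, list(pending))
  expect_equal(length(ontologyTerms(merged)), length(ontologyTerms(g)) + 1L)
  expect_equal(nrow(isaEdges(merged)), nrow(isaEdges(g)) + 1L)
  expect_true(getTerm(merged, "urn:prov/1")@isProvisional)
  expect_true("urn:prov/1" %in% descendants(merged, "A"))

  resolved <- new("ProvisionalRequest", provisionalId = "urn:prov/2",
                  label = "found", submitter = "team",
                  created = "2026-01-01T00:00:00Z", permanentId = "C")
  merged2 <- mergeProvisional(g, list(resolved))
  t <- getTerm(merged2, "urn:prov/2")
  expect_true(t@isObsolete)
  expect_equal(t@replacedBy, "C")

  ## resolution to an id outside the graph materialises a placeholder
  external <- new("ProvisionalRequest", provisionalId = "urn:prov/3",
                  label = "external", submitter = "team",
                  created = "2026-01-01T00:00:00Z",
                  permanentId = "http://example.org/elsewhere/1")
  merged3 <- mergeProvisional(g, list(external))
  expect_true(getTerm(merged3, "http://example.org/elsewhere/1")@isPlaceholder)
  expect_equal(resolveReplacement(merged3, "urn:prov/3"),
               "http://example.org/elsewhere/1")

  ## identity on the empty list; idempotence on re-merge
  expect_identical(mergeProvisional(g, list()), g)
  expect_identical(mergeProvisional(merged, list(pending)), merged)

  ## collision with a non-provisional term
  clash <- new("ProvisionalRequest", provisionalId = "A", label = "x",
               submitter = "team", created = "2026-01-01T00:00:00Z")
  expect_error(mergeProvisional(g, list(clash)), class = "eq_collision_error")
})

test_that("OBO serialization round-trips the parsed graph", {
  g <- parseOBO(c(chainOBO(), "", "[Term]", "id: D", "name: delta",
                  'def: "a \\"quoted\\" def" []',
                  'synonym: "syn" NARROW []',
                  "is_a: A", "is_a: GHOST:9", "is_obsolete: true",
                  "replaced_by: A"))
  expect_message(g2 <- parseOBO(writeOBO(g)), "placeholder")
  expect_identical(g2, g)
  ## deterministic: serialize twice, byte-equal
  expect_identical(writeOBO(g), writeOBO(g))

  set.seed(42)
  r <- randomDagGraph(15, 0.2, nObsolete = 2L)
  expect_identical(parseOBO(writeOBO(r)), r)
})
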