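test_that("a state's annotations appear as pa:phenotype metadata", {
  doc <- studyDocument(
    taxa = list(taxon("A"), taxon("B")),
    characters = list(matrixCharacter("c", c("0", "1")))
  )
  doc <- annotateState(doc, 1, "1",
                       eqAnnotation(entity = termRef("UBERON:0000001"),
                                    quality = termRef("PATO:0000460")))
  s <- nexmlString(doc)
  x <- xml2::read_xml(s)
  ph <- xml2::xml_find_all(x, "//*[@rel = 'pa:phenotype']")
  expect_length(ph, 1L)
  expect_equal(
    xml2::xml_attr(xml2::xml_find_first(x, "//*[@rel = 'pa:entity']"), "href"),
    "http://purl.obolibrary.org/obo/UBERON_0000001")
})

test_that("an empty document serializes to a structurally valid file", {
  s <- nexmlString(studyDocument())
  v <- validateNexml(s)
  expect_true(v$valid)
  expect_identical(readNexml(s), studyDocument())
})

test_that("writing is byte-deterministic", {
  set.seed(99)
  doc <- randomDocument()
  f1 <- tempfile(); f2 <- tempfile()
  writeNexml(doc, f1)
  writeNexml(doc, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("read(write(doc)) is the identity on random documents", {
  set.seed(4242)
  for (k in seq_len(50)) {
    doc <- randomDocument()
    expect_identical(readNexml(nexmlString(doc)), doc, info = paste("doc", k))
  }
})

test_that("output validates structurally for random documents", {
  set.seed(77)
  for (k in seq_len(10)) {
    v <- validateNexml(nexmlString(randomDocument()))
    expect_true(v$valid, info = paste(v$problems, collapse = "; "))
  }
})

test_that("foreign document metadata survives a read/write cycle byte-preserved", {
  doc <- studyDocument(list(taxon("T")),
                       list(matrixCharacter("c", c("0", "1"))))
  s <- nexmlString(doc)
  x <- xml2::read_xml(s)
  foreign <- xml2::read_xml(paste0(
    '<meta xmlns="http://www.nexml.org/2009"',
    ' xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"',
    ' xmlns:dc="http://purl.org/dc/terms/"',
    ' id="fm1" xsi:type="LiteralMeta" property="dc:creator" content="someone else"/>'))
  xml2::xml_add_child(x, foreign, .where = 0)
  withForeign <- as.character(x)

  doc2 <- readNexml(withForeign)
  keys <- names(sourceMetadata(doc2))
  expect_true(any(startsWith(keys, "foreign_")))
  reread <- readNexml(nexmlString(doc2))
  expect_identical(sourceMetadata(reread), sourceMetadata(doc2))
  ## the foreign element's bytes are preserved across the cycle
  fkey <- keys[startsWith(keys, "foreign_")][1]
  expect_identical(sourceMetadata(reread)[[fkey]], sourceMetadata(doc2)[[fkey]])
  expect_match(sourceMetadata(reread)[[fkey]], "someone else", fixed = TRUE)
  ## write is a fixed point on what the tool produced
  expect_identical(nexmlString(readNexml(nexmlString(doc2))),
                   nexmlString(doc2))
})

test_that("a cell referencing an undeclared state id is an integrity error", {
  doc <- setCell(studyDocument(list(taxon("T")),
                               list(matrixCharacter("c", c("0", "1")))),
                 1, 1, "0")
  s <- nexmlString(doc)
  broken <- sub('state="s1_1"', 'state="s1_99"', s, fixed = TRUE)
  expect_error(readNexml(broken), class = "eq_integrity_error")
  expect_error(readNexml(broken), "r1.*c1")
})

test_that("non-NeXML input is a format error", {
  expect_error(readNexml("<notnexml/>"), class = "eq_format_error")
  expect_error(readNexml("not xml at all <"), class = "eq_format_error")
})

test_that("CURIE expansion and contraction are inverse on the default map", {
  expect_equal(expandTermId("UBERON:0000001"),
               "http://purl.obolibrary.org/obo/UBERON_0000001")
  expect_equal(contractTermId(expandTermId("PATO:0001236")), "PATO:0001236")
  uri <- "http://example.org/provisional/abc"
  expect_equal(contractTermId(expandTermId(uri)), uri)
  pm <- c(MYO = "http://example.org/myontology#")
  expect_equal(contractTermId(expandTermId("MYO:12", pm), pm), "MYO:12")
})
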