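baseDoc <- function() {
  studyDocument(list(taxon("Danio rerio"), taxon("Amia calva")),
                list(matrixCharacter("fin", c("0", "1")),
                     matrixCharacter("barbel", c("0", "1"))))
}

randomEdit <- function(doc) {
  if (runif(1) < 0.5) {
    editSetCell(doc, sample(1:2, 1), sample(1:2, 1),
                sample(c("0", "1"), sample(1:2, 1)))
  } else {
    editAnnotateState(doc, sample(1:2, 1), sample(c("0", "1"), 1),
                      eqAnnotation(entity = termRef(sprintf("X:%d",
                                                            sample.int(99, 1)))))
  }
}

test_that("undo-all restores the initial document, redo-all the final one", {
  set.seed(5)
  for (rep in 1:5) {
    s <- editSession(baseDoc())
    n <- sample.int(30, 1)
    for (i in seq_len(n)) s <- applyEdit(s, randomEdit(sessionDocument(s)))
    final <- sessionDocument(s)
    for (i in seq_len(n)) s <- undo(s)
    expect_identical(sessionDocument(s), baseDoc())
    for (i in seq_len(n)) s <- redo(s)
    expect_identical(sessionDocument(s), final)
  }
})

test_that("a new edit clears the redo stack and failures leave the session intact", {
  s <- editSession(baseDoc())
  s <- applyEdit(s, editSetCell(sessionDocument(s), 1, 1, "0"))
  s <- undo(s)
  expect_length(s@redoStack, 1L)
  s <- applyEdit(s, editSetCell(sessionDocument(s), 2, 2, "1"))
  expect_length(s@redoStack, 0L)
  expect_error(redo(s), class = "eq_edit_error")

  bad <- makeEdit("bad", function(d) stop("nope"), identity)
  before <- s
  expect_error(applyEdit(s, bad), class = "eq_edit_error")
  expect_identical(before, s)
})

test_that("autosave keeps the bound file equal to the in-memory document", {
  path <- tempfile(fileext = ".xml")
  s <- editSession(baseDoc(), path, autosave = TRUE)
  set.seed(6)
  for (i in 1:10) {
    s <- applyEdit(s, randomEdit(sessionDocument(s)))
    expect_false(isDirty(s))
    expect_identical(readNexml(path), sessionDocument(s))
  }
  s <- undo(s)
  expect_identical(readNexml(path), sessionDocument(s))
})

test_that("a session's own save classifies as self_save, then unchanged", {
  path <- tempfile(fileext = ".xml")
  s <- editSession(baseDoc(), path, autosave = TRUE)
  s <- applyEdit(s, editSetCell(sessionDocument(s), 1, 1, "1"))
  r <- classifyFileChange(s)
  expect_equal(r$event, "self_save")
  r2 <- classifyFileChange(r$session)
  expect_equal(r2$event, "unchanged")
})

test_that("foreign writes classify as external_change; deletion is flagged", {
  path <- tempfile(fileext = ".xml")
  s <- editSession(baseDoc(), path, autosave = TRUE)
  invisible(classifyFileChange(s))
  writeNexml(setCell(baseDoc(), 2, 2, "0"), path)  # another process
  r <- classifyFileChange(s)
  expect_equal(r$event, "external_change")
  expect_false(r$deleted)
  unlink(path)
  r2 <- classifyFileChange(s)
  expect_equal(r2$event, "external_change")
  expect_true(r2$deleted)
})

test_that("reload refuses to discard unsaved edits unless forced", {
  path <- tempfile(fileext = ".xml")
  writeNexml(baseDoc(), path)
  s <- editSession(path = path)           # autosave off
  external <- setCell(baseDoc(), 1, 2, "1")
  s <- applyEdit(s, editSetCell(sessionDocument(s), 1, 1, "0"))
  expect_true(isDirty(s))
  writeNexml(external, path)
  expect_error(reloadSession(s), class = "eq_unsaved_changes_error")
  expect_true(isDirty(s))

  s2 <- reloadSession(s, force = TRUE)
  expect_identical(sessionDocument(s2), external)
  expect_false(isDirty(s2))
  expect_length(s2@undoStack, 0L)

  ## with autosave on, a session is never dirty, so reload always succeeds
  s3 <- editSession(path = path, autosave = TRUE)
  s3 <- applyEdit(s3, editSetCell(sessionDocument(s3), 2, 1, "0"))
  writeNexml(baseDoc(), path)
  expect_identical(sessionDocument(reloadSession(s3)), baseDoc())
})

test_that("watchFile reports events through its callback", {
  path <- tempfile(fileext = ".xml")
  s <- editSession(baseDoc(), path, autosave = TRUE)
  seen <- character(0)
  s <- applyEdit(s, editSetCell(sessionDocument(s), 1, 1, "0"))
  watchFile(s, times = 2, interval = 0,
            callback = function(event, deleted) seen <<- c(seen, event))
  expect_equal(seen, "self_save")  # second poll is unchanged, not reported
})
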