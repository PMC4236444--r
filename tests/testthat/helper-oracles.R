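## Independent oracles and random-object generators shared by the suite.

## Naive fixed-point transitive closure over is_a edges, kept deliberately
## independent of the package's BFS: relax a boolean reachability matrix
## (parent -> child) until nothing changes, then read off each node's
## descendant set.
naiveClosure <- function(graph, includeSelf = TRUE) {
  ids <- termIds(graph)
  obsolete <- vapply(ontologyTerms(graph), function(t) t@isObsolete,
                     logical(1))
  n <- length(ids)
  reach <- diag(n) > 0
  dimnames(reach) <- list(ids, ids)
  e <- isaEdges(graph)
  ## reasoning ignores is_a edges leaving an obsolete child
  if (nrow(e)) e <- e[!obsolete[e[, "child"]], , drop = FALSE]
  direct <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(e))) {
    direct[e[k, "parent"], e[k, "child"]] <- TRUE
  }
  repeat {
    nxt <- reach | (reach %*% direct > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  out <- lapply(ids, function(root) {
    d <- ids[reach[root, ]]
    if (!includeSelf) d <- setdiff(d, root)
    sort(d[!obsolete[d]])
  })
  names(out) <- ids
  out
}

## Random DAG as an OntologyGraph: edges only from higher to lower index,
## acyclic by construction.
randomDagGraph <- function(n, edgeProb, nObsolete = 0L) {
  ids <- sprintf("N:%03d", seq_len(n))
  terms <- lapply(ids, function(id) new("Term", id = id, label = id))
  names(terms) <- ids
  edges <- matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("child", "parent")))
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(i - 1L)) {
      if (runif(1) < edgeProb) {
        edges <- rbind(edges, c(ids[i], ids[j]))
      }
    }
  }
  if (nObsolete > 0L) {
    for (id in sample(ids, nObsolete)) {
      terms[[id]]@isObsolete <- TRUE
    }
  }
  new("OntologyGraph", terms = terms, edges = edges)
}

## Random annotated StudyDocument exercising the full NeXML surface:
## polymorphic cells, taxonomy refs, multi-annotation states, XML-hostile
## characters in labels and comments.
randomDocument <- function() {
  rword <- function() {
    pool <- c(letters, LETTERS, " ", "'", "\"", "<", "&", ">", "-", "(", ")")
    paste(sample(pool, sample(3:12, 1), replace = TRUE), collapse = "")
  }
  maybe <- function(x, p = 0.5) if (runif(1) < p) x else NULL
  rref <- function() {
    id <- sprintf("%s:%07d", sample(c("UBERON", "PATO", "GO", "TAX"), 1),
                  sample.int(999999L, 1))
    termRef(id, if (runif(1) < 0.5) rword() else NA_character_)
  }
  nt <- sample(1:5, 1)
  nc <- sample(1:5, 1)
  taxa <- lapply(seq_len(nt), function(i)
    taxon(paste0(rword(), " ", i), maybe(rref())))
  characters <- lapply(seq_len(nc), function(j) {
    k <- sample(2:4, 1)
    states <- lapply(as.character(seq_len(k) - 1L), function(s) {
      anns <- lapply(seq_len(sample(0:2, 1)), function(a) {
        eqAnnotation(
          entity = maybe(rref(), 0.8),
          quality = rref(),
          relatedEntity = maybe(rref(), 0.3),
          comment = if (runif(1) < 0.4) rword() else NA_character_
        )
      })
      characterState(s, if (runif(1) < 0.8) rword() else NA_character_, anns)
    })
    new("MatrixCharacter", label = rword(), states = states)
  })
  doc <- studyDocument(taxa, characters,
                       sourceMetadata = list(publication = rword(),
                                             curators = rword()))
  for (ti in seq_len(nt)) {
    for (ci in seq_len(nc)) {
      if (runif(1) < 0.8) {
        syms <- as.character(seq_len(length(characters[[ci]]@states)) - 1L)
        doc <- setCell(doc, ti, ci,
                       sample(syms, sample(1:min(2, length(syms)), 1)))
      }
    }
  }
  doc
}

## small OBO text used across ontology tests
chainOBO <- function() {
  c("format-version: 1.4", "",
    "[Term]", "id: A", "name: alpha", "",
    "[Term]", "id: B", "name: beta", "is_a: A", "",
    "[Term]", "id: C", "name: gamma", "is_a: B")
}

tmpStore <- function() brokerStore(tempfile(fileext = ".jsonl"))
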