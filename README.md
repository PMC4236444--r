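# eqmatrix

Semantic annotation of phenotypic character matrices for evolutionary
biology, in R.

Comparative morphologists publish their evidence as character matrices:
taxa in rows, discrete phenotypic characters in columns ("dorsal fin:
absent/present"). To make those data computable across studies, each
character state is annotated with **Entity–Quality (EQ)** expressions —
an anatomical or process *entity* term paired with a *quality* term from
the quality ontology, e.g. *femur* (UBERON) + *curved* (PATO); relational
qualities such as *fused with* additionally carry a *related entity* —
and each taxon is linked to a taxonomy ontology identifier. Annotated
matrices are stored as [NeXML](http://www.nexml.org/), which attaches
metadata to any data element.

`eqmatrix` is a library plus command-line tool for the curation workflow
around this model, aimed at phenotype curators and tool builders:

* **Ontology store** — parse an OBO tag subset into an in-memory graph
  (`parseOBO`, `readOBO`); subsumption queries over `is_a`
  (`descendants`, `isDescendant`) with obsolete terms excluded from
  reasoning; transitive `replaced_by` resolution (`resolveReplacement`).
* **Matrix model and NeXML I/O** — `StudyDocument` objects with
  polymorphic cells and per-state EQ annotations; deterministic,
  round-trip-safe NeXML reading and writing (`readNexml`, `writeNexml`),
  foreign metadata preserved verbatim; structural validation
  (`validateNexml`).
* **Ontology Request Broker** — mint provisional term URIs usable in
  annotations immediately (`requestTerm`), resolve them to permanent
  identifiers later (`resolveRequest`), and let `syncAndMigrate` rewrite
  every affected reference in a document, following replacement chains to
  their terminus whether they stem from provisional resolution or
  ordinary ontology obsolescence.
* **Consistency checking** — `checkAnnotation`/`checkDocument` evaluate
  EQ completeness, relational-quality, process-entity/process-quality
  (GO:0008150 entities must pair with PATO:0001236 qualities), obsolete-
  and unknown-reference rules, plus a note for incompletely annotated
  characters; severity-tagged issues with a TSV report.
* **Editing sessions** — reversible edits with undo/redo (`applyEdit`,
  `undo`, `redo`), continual atomic autosave, and content-hash file
  change classification that tells a session's own saves apart from a
  collaborator's (`classifyFileChange`, `reloadSession`, `watchFile`).
* **Fixture generator** — deterministic mini-ontologies and annotated
  matrices with violations planted at recorded locations
  (`makeOntologies`, `makeBundle`), so every property above is testable
  offline against independent ground truth.

## A worked example

```r
library(eqmatrix)
set.seed(42)

## a reasoning graph: anatomy + quality + process + taxonomy ontologies
graphs <- makeOntologies(1)
graph  <- combineGraphs(graphs)
config <- ruleConfig(relationalQualityRoot = "PATO:9100000")

## a two-taxon, one-character matrix with one annotated state
doc <- studyDocument(
  taxa = list(taxon("Danio rerio", termRef("TAX:0000002")),
              taxon("Amia calva",  termRef("TAX:0000003"))),
  characters = list(matrixCharacter("dorsal fin", c("0", "1")))
)
doc <- setCell(doc, 1, 1, "1")
doc <- setCell(doc, 2, 1, "0")
doc <- annotateState(doc, 1, "1",
  eqAnnotation(entity = termRef("ANAT:0000002"),
               quality = termRef("PATO:9200001")))
doc
#> StudyDocument: 2 taxa x 1 characters, 2 scored cells, 1 EQ annotations

writeLines(issuesToTSV(checkDocument(doc, graph, config)))
#> rule_id	severity	character	state	annotation	message
#> N_INCOMPLETE_CHARACTER	note	1			character 1 ('dorsal fin'): 1 of 2 states lack annotations
```

State `1` is annotated but state `0` is not, so the checker notes an
*incompletely annotated character*. Now annotate state `0` with a term
the anatomy ontology does not have yet, via the request broker:

```r
store <- brokerStore(tempfile(fileext = ".jsonl"))
req <- requestTerm(store, "basipterygium", "a fin support element",
                   superclass = termRef("ANAT:0000001"), submitter = "team")
req
#> ProvisionalRequest 'basipterygium' (pending)
#>   http://example.org/provisional/04089319-0fe7-4638-8d39-1e288a34ec43 [2026-09-27T19:56:01.782Z]

doc <- annotateState(doc, 1, "0",
  eqAnnotation(entity = termRef(provisionalId(req)),
               quality = termRef("PATO:9200002")))

## ... an ontology editor later assigns the permanent identifier ...
resolveRequest(store, provisionalId(req), "ANAT:0000005")

## at next launch, the sync migrates the annotation automatically
synced <- syncAndMigrate(store, "team", graph, doc)
synced$report
#> MigrationReport: 1 id(s) rewritten, 0 pending provisional id(s) untouched
#>   http://example.org/provisional/04089319-0fe7-4638-8d39-1e288a34ec43 -> ANAT:0000005 (1 reference(s))

nrow(checkDocument(synced$document, synced$graph, config))
#> [1] 0
```

The one reference to the provisional id was rewritten to the permanent
id (count `1`), and the fully annotated, fully migrated document now
checks clean. `writeNexml(synced$document, "matrix.xml")` stores it as
deterministic, schema-shaped NeXML.

The same workflow is available from a shell through the bundled script
(`system.file("cli", "eqmatrix", package = "eqmatrix")`) with the
subcommands `validate`, `check`, `request`, `list-requests`, `resolve`,
`sync`, `watch` and `fixtures`.

For the model, the rule semantics, and the design decisions (canonical
orderings, hash-based change detection, fixture ground-truth planting),
see the methods vignette in `vignettes/eqmatrix-methods.Rmd`.

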