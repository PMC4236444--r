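Package: eqmatrix
Title: Entity-Quality Annotation of Phenotypic Character Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for semantic annotation of the phenotypic character
    matrices used in evolutionary biology. Character states are annotated
    with Entity-Quality (EQ) phenotype expressions drawn from OBO
    ontologies, and taxa with taxonomy ontology identifiers; annotated
    matrices are stored as NeXML with embedded metadata. The package
    parses an OBO tag subset into an in-memory ontology graph with
    subsumption, obsolescence and replaced_by reasoning; mints and
    resolves provisional ontology term requests through a local request
    broker and automatically migrates annotations from provisional to
    permanent identifiers; evaluates ontology-aware annotation
    consistency rules (EQ completeness, relational qualities, process
    entities with process qualities, obsolete references, incompletely
    annotated characters); and supports collaboration-safe editing with
    undo/redo, continual autosave and content-hash based file-change
    classification. A deterministic fixture generator produces
    mini-ontologies and annotated matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, tools, utils, xml2, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'obo.R'
    'ontology-reasoning.R'
    'matrix-model.R'
    'nexml-write.R'
    'nexml-read.R'
    'nexml-validate.R'
    'broker.R'
    'consistency.R'
    'session.R'
    'fixtures.R'
    'cli-support.R'
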