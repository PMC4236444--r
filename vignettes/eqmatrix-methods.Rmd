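---
title: "Methods: Entity–Quality annotation of character matrices"
author: "eqmatrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Entity–Quality annotation of character matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqmatrix)
```

## The curation problem

Comparative morphology produces character matrices: taxa in rows,
phenotypic characters in columns, each cell scoring a taxon for one of the
character's discrete states ("dorsal fin: present/absent"). To make these
data computable across studies, curators attach semantics: each character
state is annotated with one or more Entity–Quality (EQ) expressions — an
anatomical or process *entity* term paired with a *quality* term from the
quality ontology (e.g. *femur* + *curved*) — and each taxon is linked to a
taxonomy ontology identifier. `eqmatrix` implements the machinery around
this workflow: an ontology store with subsumption reasoning, NeXML
serialization of annotated matrices, a provisional-term request broker
with automatic identifier migration, ontology-aware consistency checking,
and collaboration-safe editing.

Three recurring bottlenecks shape the design:

1. **Missing terms.** Mid-annotation, a curator needs a term the ontology
   does not yet have. Pausing to negotiate a formal term request stalls
   curation, so the broker mints a *provisional* identifier immediately
   usable in annotations, and migrates the data automatically once a
   permanent identifier exists.
2. **Annotation quality.** EQ composition has conventions that are easy to
   violate (a relational quality without its second entity, a process
   entity paired with a structural quality). Rule-based checking catches
   these during curation rather than in later review.
3. **Collaboration.** Teams share matrix files through folder-sync
   services. Undo/redo, continual autosave, and self-save-aware file
   change detection make concurrent-ish editing survivable without a
   version control system.

## The ontology store

`parseOBO()` reads a documented OBO 1.2/1.4 tag subset (`id`, `name`,
`def`, `synonym`, `is_a`, `is_obsolete`, `replaced_by`, `namespace` in
`[Term]` stanzas); unknown tags are skipped with a notice. Reasoning is
deliberately minimal: only `is_a` transitivity.

Semantics worth stating precisely:

* **Obsolete terms take no part in subsumption.** `descendants()` never
  returns an obsolete term, and never traverses an obsolete term's own
  `is_a` edges — rules must not fire on retired branches.
* **Dangling parents become placeholders.** Curators routinely load
  ontology slices; an `is_a` parent that is not defined in the file is
  materialised as a placeholder term flagged incomplete, reported but
  never silently dropped. The consistency checker treats a placeholder
  like an unknown term (warning, not error).
* **Replacement following.** `resolveReplacement()` follows `replaced_by`
  transitively to a terminal id, erroring on cycles and on targets missing
  from the graph. When a term lists several replacements, the first is
  followed with a warning: the provisional workflow produces exactly one
  permanent id per term, so multiplicity is an out-of-band ontology event.
* **Identifiers are exact strings.** CURIEs and full URIs are both
  accepted; no expansion happens inside the store. Expansion and
  contraction (`PREFIX:LOCAL` ↔ OBO Library PURLs, plus a configurable
  prefix map) live in the NeXML layer, whose canonical internal form is
  the CURIE wherever one exists.

A deterministic writer (`writeOBO()`, stanzas sorted by id) exists for
round-trip testing; placeholder terms are not written because re-parsing
the surviving `is_a` lines recreates them.

## The request broker

`requestTerm()` mints `<namespace><UUID>` URIs and persists records in a
JSON-lines file (append on create, atomic whole-file rewrite on update;
only `permanent_id` may ever change). This local backend implements
exactly the three capabilities the workflow needs from any server —
unique id generation, metadata storage, permanent-id update — so the REST
shape (create = `POST`, list = `GET` by submitter, update = `PATCH`) is
documented as a contract but not required for operation. Duplicate labels
are allowed with a warning; duplicate avoidance is social, via a shared
submitter id under which a team sees each other's requests.

`syncAndMigrate()` composes the pieces: all of a submitter's requests are
merged into the ontology session (`mergeProvisional()`), pending requests
as usable provisional terms (with an `is_a` edge to the suggested
superclass when that superclass is loaded), resolved requests as obsolete
terms with `replaced_by`. Every document reference is then rewritten
through `resolveReplacement()`, so chains are followed to their terminus
whether the hops come from provisional resolution or ordinary ontology
obsolescence. A permanent id absent from the loaded graph is materialised
as a placeholder first: review legitimately resolves requests to
pre-existing terms that were simply not discovered, and those may live
outside the loaded slice. Resolved-but-unmigrated references persist in
saved files until a sync runs; the sync is idempotent.

## NeXML serialization

Annotated matrices are stored as NeXML (namespace
`http://www.nexml.org/2009`) with annotations as `meta` elements in a
package-defined vocabulary bound to the `pa:` prefix
(`http://example.org/phenotype-annotation#`): `pa:taxon` on `otu`
elements, `pa:phenotype` containers on `state` elements holding
`pa:entity`, `pa:quality`, `pa:related_entity` resource metas and a
`pa:comment` literal, with cached display labels as nested `pa:label`
literals. The vocabulary is declared, not reverse-engineered from any
existing tool's files: the contract is this documented mapping.

Choices that matter:

* **Determinism.** Fixed element ordering, fixed prefixes, and meta ids
  assigned in emission order make serialization a pure function of the
  document: identical documents produce byte-identical files, which is
  what makes content-hash change detection and the self-save token sound.
* **Polymorphism.** Cells hold sets of state symbols; multi-symbol cells
  are serialized as `polymorphic_state_set` elements declared per
  character. The set key joins member symbols, which assumes single-token
  symbols do not concatenate ambiguously — true of conventional numeric
  symbols.
* **Round-trip safety.** Unknown document-level `meta` elements are
  preserved verbatim in `sourceMetadata` under `foreign_NNN` keys and
  re-emitted on write. `read ∘ write` is the identity on the model;
  `write ∘ read ∘ write = write` on files the package produced.
* **Validation.** `validateNexml()` is a structural validator (root and
  namespace, global id uniqueness, resolvable otu/char/state references,
  well-formed meta elements) rather than full XSD validation: the NeXML
  schema is a multi-file XSD whose imports are not bundled here. The
  checks cover the constraints the writer can actually violate.
* **Canonical ordering.** The cell map and `sourceMetadata` are kept in
  sorted key order so that documents reached by different edit orders
  compare deep-equal — deep equality underpins the undo/redo and
  round-trip properties.
* Indices are 1-based throughout the R API; NeXML element ids (`t1`,
  `c1`, `s1_2`) are opaque strings and state ids use state *positions*,
  which keeps them valid XML NCNames even for symbols like `?`.

## Consistency rules

`checkAnnotation()` evaluates independent rules, so one annotation can
earn several issues; severities derive from the rule-id prefix (`E_`
error, `W_` warning, `N_` note — errors and warnings for rule violations,
a note for the softer incompleteness signal):

| rule | fires when |
|---|---|
| `E_MISSING_ENTITY` / `E_MISSING_QUALITY` | an annotation lacks the entity or the quality term |
| `E_RELATIONAL_NEEDS_RELATED` | the quality descends from the relational-quality root but no related entity is given |
| `E_NONRELATIONAL_HAS_RELATED` | a related entity is given but the quality is not relational |
| `E_PROCESS_NEEDS_PROCESS_QUALITY` | the entity descends from `GO:0008150` (biological process) and the quality does not descend from `PATO:0001236` (process quality) |
| `W_OBSOLETE_REFERENCE` | any referenced term is obsolete |
| `W_UNKNOWN_TERM` | a referenced id is not in the loaded graph (a warning, not an abort — slices again) |
| `N_INCOMPLETE_CHARACTER` | some but not all of a character's non-missing states carry annotations |

The process-rule roots default to the ontology ids the rule is defined
against. The relational-quality root has **no default**: no authoritative
id is hard-coded, so it must be supplied in configuration, and enabling
the relational rules without it is a configuration error (as is any
enabled-rule root missing from the loaded graph). Ontology-dependent
rules are evaluated only when the inspected terms are known to the graph;
`E_NONRELATIONAL_HAS_RELATED` is classified as an error here, and is
configurable by disabling it. A character with *no* annotated states is
not "incomplete" — it simply has not been annotated yet — and states with
the reserved missing symbol `?` (never annotatable) are exempt from the
census. Document-level output is deterministically ordered by character,
state, annotation, rule id.

## Editing sessions

An `EditSession` holds the document plus undo/redo stacks of reversible
edits (forward/inverse closure pairs that capture prior values at
construction). With autosave enabled, every edit, undo and redo is
followed by an atomic save — write a sibling temp file, then rename — so
a folder-sync service never observes a half-written matrix and the
session is never dirty at a quiescent point, which is exactly what makes
reload-on-external-change safe.

Change classification is content-hash based (MD5 of the file bytes), not
mtime based: sync services may rewrite identical bytes and clocks skew
across machines. The session keeps the hash of the last bytes it wrote
(the self-save token) and the last hash it acknowledged: matching the
token classifies as `self_save` (once; afterwards `unchanged`), anything
else as `external_change`, with deletion flagged. A dirty session refuses
to reload unless forced, because reloading discards unsaved edits.
Autosave fires on every edit with no debounce interval — at matrix-editing
rates a save per edit is cheap, and a quiescence window would reopen the
unsaved-edit loss window the feature exists to close.

## The fixture generator

`makeOntologies(seed)` builds four deterministic mini-ontologies: an
anatomy DAG (24 terms, chain backbone of depth 4, random extra parents,
one obsolete term with `replaced_by`), a quality ontology whose root has
disjoint process-quality (`PATO:0001236`), relational-quality
(`PATO:9100000`, a minted fixture id supplied through configuration) and
monadic branches, a process graph under `GO:0008150`, and a 12-term
taxonomy tree. `makeBundle()` populates a matrix (defaults: 8 taxa × 10
characters × 2 states, roughly a small study fragment) with clean
annotations — anatomy entity + monadic quality, constructed to satisfy
every rule simultaneously — and then plants violations.

Two design points carry the weight:

* **Ground truth is recorded at injection time**, from the plan, never by
  running the checker. The generator and the checker are two independent
  encodings of the same rules; their exact agreement (zero false
  positives on clean annotations, zero misses on planted violations,
  across ≥ 20 seeds in the suite) is the property the test suite exists
  to establish.
* **Annotation is all-or-none per character.** The `annotatedFraction`
  parameter (default 0.8) selects whole characters rather than individual
  states; incomplete characters are then planted exactly, by stripping one
  state of an annotated character, and annotation-level violations
  replace the clean annotation of a distinct still-annotated slot each.
  Sampling states independently would make incompleteness a random
  by-product and exact ground truth impossible.

What the fixtures do *not* emulate: real anatomical vocabularies,
realistic matrix shapes or missing-data patterns, post-composed ontology
expressions, or multi-relation ontologies (`part_of` etc. are out of
scope everywhere). Passing tests demonstrate the machinery's correctness
on the documented semantics, not robustness to arbitrary real-world OBO
or NeXML files.

## Problem sizes and determinism in the shipped checks

The test suite and the acceptance script regenerate everything from code:
20 random DAGs of up to 50 nodes for the closure-oracle comparison
(against an independent naive fixed-point closure), 50 random documents
for round-trip identity, 20 fixture seeds for rule exactness, random edit
sequences of up to 30 edits for undo/redo, and 1000 broker requests for
id uniqueness — sizes at which every property is exercised densely while
the whole suite stays fast. All randomness flows from explicit seeds; the
acceptance script takes its seed on the command line.

## Known limitations

* OWL, relationship types other than `is_a`, cross-ontology imports, and
  reasoning beyond transitive closure are out of scope.
* Tree blocks, NEXUS/phylip interchange, and streaming parses of very
  large matrices are not supported.
* `validateNexml()` is structural, not schematic (see above).
* Taxonomic-applicability checking (a term used in a clade where it
  cannot apply) is motivation, not an implemented rule.
* Merge/conflict resolution of truly concurrent edits is out of scope;
  the session machinery detects and reports divergence, it does not merge.
* No state-level counts or measurements accompany EQ annotations.
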