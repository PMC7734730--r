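---
title: "From biomedical text to ontology-linked knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From biomedical text to ontology-linked knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litkg)
```

## The problem

Scientific prose in biomedicine encodes facts — *a disease causes a
condition*, *a study confirms a prevalence* — that are hard to query, compare
or aggregate while they stay buried in sentences. litkg turns a chunk of
unstructured text into a set of RDF triples `(subject, predicate, object)`
and assembles them into a connected knowledge graph whose nodes can be
linked, via UMLS Concept Unique Identifiers (CUIs), to the classes of a
biomedical ontology. The method is deliberately *semi-automatic*: every stage
persists a plain-text intermediate that a domain expert can edit, and the
pipeline consumes edited intermediates instead of overwriting them.

## The pipeline and its assumptions

Four stages run in a fixed order.

**1. Preprocessing.** The document is split into sentences; coreferent
pronouns (`it`, `they`, `this`, ...) are replaced by their representative
mention; abbreviations defined as `long form (SHORT)` are detected with the
Schwartz–Hearst character-alignment conditions and expanded document-wide;
and sentences bound by a coordinating conjunction are split into smaller,
self-contained ones using the constituency parse. Two coordination patterns
are handled: verb phrases sharing a subject (the subject is copied into each
conjunct) and coordinated pre-modifiers of a shared head noun (each modifier
is distributed over the head and its trailing material). Deeper
constructions — relative clauses, appositions — are deliberately out of
scope in this version. The sub-step order (coreference, then abbreviations,
then simplification) is part of the contract: permuting it changes the
token spans the later stages see. Whether abbreviation expansion should
re-run after simplification is genuinely ambiguous; we fix the order above
and note that simplification never introduces new parentheticals, so a
second pass would be a no-op on well-formed input.

**2. Triple extraction.** Semantic role labeling (SRL) identifies each
verb's arguments (`A0`, `A1`, modifier labels such as `AM-LOC`). A
PropBank/VerbNet-style *roleset* inventory maps argument labels of a verb
sense to role names (`confirm.01: A0=Agent, A1=Theme`); when several senses
match the frame's core labels, the lowest sense number wins. The *reified*
form emits one triple per argument with the inflected verb surface as the
subject and the role as the predicate:

```
("confirms", role:Agent, "study")
("confirms", role:Theme, "high prevalence of poststroke cognitive impairment")
```

Labels without a roleset role keep their label as a local predicate
(`local:AM-LOC`). A plain (non-reified) mode produces the familiar
subject–verb–object shape instead, composing a predicate like
`"warrant attention in"` when a modifier argument opens with a preposition.
Argument phrases pass through `strip_phrase()`, which removes leading
determiners and phrase-initial auxiliaries and lower-cases a
sentence-initial capital.

*Secondary* triples come from the dependency parse, restricted to the SRL
argument spans. For a head noun with `k` pre-modifiers (`amod`/`compound`
edges) the leftmost modifier is peeled one at a time, giving `k`
`rdfs:subClassOf` triples that form a path from the full phrase to the bare
head (`poststroke cognitive impairment` → `cognitive impairment` →
`impairment`). The peel order is a design choice: the printed examples are
consistent with leftmost-first peeling, which also keeps the chain a path
rather than a tree. For a nominal `X prep Y` construction inside an argument
phrase `F`, two local-predicate triples are emitted,
`(F, local:<prep>_<slug(Y)>, X)` and `(F, local:<slug(X)>_<prep>, Y)`, so the
secondary material stays anchored to the argument phrase that the main
triple already mentions — which is what makes the final graph connected.
The preposition list defaults to `of, in, for, with, on` and is
configurable. An optional flag adds `local:hasAdjective` /
`local:hasCompound` triples so that peeled modifiers themselves become
queryable nodes.

**3. Ontology linking (optional).** Candidate terms are the entity-mention
surfaces plus the lemmas of verbs. Each candidate gets its top-scoring CUI
from a lexicon (ties break by lexicographic CUI order), and each CUI is
looked up in the target ontology as a SPARQL `SELECT` over classes whose
CUI annotation property carries that value; offline, the same semantics run
as a scan over a local Turtle store. The funnel is monotone by
construction: terms identified ≥ CUIs found ≥ ontology links. A second,
direct-annotator link source can be unioned in (deduplicating on surface ×
class IRI); the union never shrinks either source. The CUI annotation
property is mandatory configuration because it differs per ontology.

**4. Graph assembly.** Every literal phrase is minted a deterministic local
URI (case-folded, whitespace-collapsed, slugged), so that re-used phrases
collapse onto shared nodes; each minted URI receives exactly one
`rdfs:label` with the original phrase, and each ontology link becomes an
`owl:sameAs` triple (to the target class and, when known, to the `umls:`
CUI). Verbs become nodes too, which puts the main relation at the centre of
the drawn graph. The result serializes to Turtle (the pipeline's final
artifact) and to DOT for rendering.

## The annotation provider

The pipeline never calls an NLP engine directly. All linguistic analyses
come through one contract, `analyze_sentence(provider, sentence, kinds)`,
returning tokens, constituency and dependency parses, SRL frames and entity
mentions with candidate CUIs. The package ships a *replay provider* that
answers from a JSON fixture byte-identically on every call; a live provider
is any object implementing the same generic (the annotations it returns are
validated by `new_annotation()`). Conventions are fixed package-wide:
0-based token indices, half-open spans, Penn-style part-of-speech tags,
`head = -1` on the root dependency edge. Detokenization joins tokens with
spaces and then removes the space before closing punctuation and clitics.

The packaged fixture covers the handful of sentences used throughout the
documentation and tests, with hand-checked parses in the style of a
CoreNLP/SENNA stack. This is what passing tests demonstrate: that the
*rules* — preprocessing, extraction, linking, assembly — behave exactly as
specified on correct analyses. They do not exercise the failure modes of a
live parser (mis-attached modifiers, wrong frames), which in production are
exactly what the semi-automatic editing loop is for.

## Synthetic fixtures and what they stand for

The CUI lexicon (`synthetic_cui_lexicon.tsv`) and the mini target ontology
(`synthetic_mini_ontology.ttl`) are synthetic stand-ins: small, hand-made
tables shaped like a biomedical NER vocabulary and a CUI-annotated
thesaurus. Their IRIs and mappings are made up and should never be read as
real terminology; they exist so the linking chain (term → CUI → class) runs
offline and deterministically, including its negative cases (a term with no
CUI, a CUI absent from the ontology).

## Evaluation

`diff_triple_sets()` compares two triple sets — typically an automatic
extraction against a manually curated one — after canonical normalization
(case-fold, whitespace-collapse, leading-determiner strip). The matching
criterion is exact string equality on that canonical form; a relaxed
containment mode exists but is off by default, because substring matching
silently inflates agreement. The Jaccard coefficient
`|A ∩ B| / |A ∪ B|` is reported alongside the only-A / only-B / both
counts; both-empty sets score 1 by convention. Report rounding is two
decimals; half-even rounding is the default and truncation is available,
since published comparison tables mix both.

## Numerical and degenerate-input choices

- Phrases that normalize to nothing (all stop words, no alphanumerics)
  raise an error at URI minting; extraction simply drops empty argument
  texts.
- Plain-mode extraction skips frames lacking `A0` or `A1` with a warning —
  passive constructions often have no agent, and inventing one would be
  worse than omitting the triple.
- The Turtle writer emits one statement per triple and declares exactly the
  prefixes used; the reader additionally accepts `;`/`,` lists, the `a`
  keyword, and language/datatype tags (dropped). Round-tripping is part of
  the test contract.
- Stage skipping in `run_pipeline()` compares file modification times:
  outputs at least as new as all inputs are consumed, not recomputed. The
  manifest records an MD5 digest per artifact so a run is auditable.
- Problem sizes throughout the tests and the acceptance script are small —
  single sentences and two-sentence documents from the fixture, set
  cardinalities in the tens — which is the package's chosen scale for a
  deterministic, fully offline verification of the rules.

## A worked run

```{r}
provider <- replay_provider(system.file("extdata", "annotations.json",
                                        package = "litkg"))
sentence <- "This study confirms the high prevalence of poststroke cognitive impairment."
ann <- analyze_sentence(provider, sentence)
triples <- extract_triples(ann)
triples[, c("subject", "predicate", "object", "provenance")]
```

```{r}
kg <- enrich(triples)
glance(kg)
cat(substr(serialize_turtle(kg), 1, 400))
```

## Known limitations

- Coreference chain *discovery* is delegated to the provider or the caller;
  the package only substitutes given chains.
- Simplification handles exactly the two coordination patterns described;
  nested or multi-conjunct coordinations fall through unchanged.
- Word-sense disambiguation is top-score selection only; a compound noun
  that the parser splits (a known failure for multi-word disease names)
  will be peeled like any other modifier chain.
- No inference: triples that require domain reasoning rather than surface
  evidence are out of scope, by design.
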