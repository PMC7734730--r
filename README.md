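# litkg — ontology-linked knowledge graphs from biomedical text

Biomedical literature grows faster than anyone can read it, and the facts
it contains stay locked in prose. **litkg** is an R package for turning
unstructured biomedical text into an RDF knowledge graph whose nodes are
linked to a biomedical ontology, through a semi-automatic, rule-based
pipeline aimed at researchers who want queryable representations of
abstracts and conclusions — and who want to be able to inspect and edit
every intermediate artifact along the way.

## The method

A document runs through four stages:

1. **Preprocessing** — sentence splitting; pronoun coreference substitution;
   Schwartz–Hearst abbreviation detection and document-wide expansion
   (`long form (SHORT)` definitions validated by right-to-left character
   alignment); conjunction-based sentence simplification over the
   constituency parse.
2. **Triple extraction** — from each SRL frame, *reified* main triples
   `(verb, role:RoleName, argument)` using a PropBank/VerbNet-style roleset
   inventory (e.g. `confirm.01: A0=Agent, A1=Theme`), or plain
   `(A0, verb, A1)` triples; plus *secondary* triples from the dependency
   parse — `rdfs:subClassOf` chains peeling noun pre-modifiers
   (`poststroke cognitive impairment ⊑ cognitive impairment ⊑ impairment`)
   and prepositional-modification triples anchored to the argument phrase.
3. **Ontology linking** (optional) — entity surfaces and verb lemmas are
   mapped to UMLS Concept Unique Identifiers, and each CUI is mapped to the
   classes of a target ontology that carry it on an annotation property
   (a SPARQL `SELECT`; evaluated offline over a local Turtle store). Link
   sets from two sources can be unioned.
4. **Graph assembly** — deterministic local URIs for every phrase,
   `rdfs:label` for every minted node, `owl:sameAs` to ontology classes and
   UMLS concepts; serialized to Turtle and DOT.

Extracted triple sets can be compared against manually curated ones with
set differences and the Jaccard coefficient `J(A,B) = |A∩B| / |A∪B|`.

All linguistic analyses arrive through a pluggable provider contract; the
package ships a deterministic **replay provider** (JSON fixtures), so the
whole pipeline runs offline and byte-reproducibly.

## A worked example

```r
library(litkg)

provider <- replay_provider(system.file("extdata", "annotations.json",
                                        package = "litkg"))
ann <- analyze_sentence(provider,
  "This study confirms the high prevalence of poststroke cognitive impairment.")
extract_triples(ann)[, c("subject", "predicate", "object", "provenance")]
#> # A tibble: 7 × 4
#>   subject                                        predicate              object                                        provenance
#>   <chr>                                          <chr>                  <chr>                                         <chr>
#> 1 confirms                                       role:Agent             study                                         main
#> 2 confirms                                       role:Theme             high prevalence of poststroke cognitive imp… main
#> 3 high prevalence                                rdfs:subClassOf        prevalence                                    secondary
#> 4 poststroke cognitive impairment                rdfs:subClassOf        cognitive impairment                          secondary
#> 5 cognitive impairment                           rdfs:subClassOf        impairment                                    secondary
#> 6 high prevalence of poststroke cognitive impa… local:of_poststrokeco… high prevalence                               secondary
#> 7 high prevalence of poststroke cognitive impa… local:highprevalence_… poststroke cognitive impairment               secondary
```

The two `main` rows are the reified relation of the sentence's verb; the
five `secondary` rows break its Theme down into sub-concepts, so a query
for `impairment` also reaches the sentence that mentioned
`poststroke cognitive impairment`. Enriching and serializing:

```r
kg <- enrich(extract_triples(ann))
glance(kg)
#> # A tibble: 1 × 5
#>   n_triples n_nodes n_local_uris n_labels n_links
#> 1        15      16            8        8       0
cat(serialize_turtle(kg))   # Turtle; export_dot(kg) for Graphviz
```

A full run over a document, with linking against the packaged synthetic
mini-ontology and editable intermediates under `out/`:

```r
cfg <- pipeline_config(
  system.file("extdata", "example_abstract.txt", package = "litkg"),
  "out", provider,
  linking = TRUE, lexicon = default_cui_lexicon(),
  ontology = synthetic_mini_ontology(), cui_property = "thes:umlsCui")
run_pipeline(cfg)
#> <litkg_manifest>
#>   preprocess: run
#>   extract: run
#>   link: run
#>   graph: run
```

Edit `out/triples.tsv` by hand and re-run: the edited file is consumed and
only the graph stage recomputes. A thin command-line wrapper lives at
`inst/scripts/litkg.R` (`run` and `compare` subcommands).

## Package layout

- `R/` — provider contract and replay backend, preprocessing, triple
  extraction, ontology linking, graph assembly (Turtle/DOT), evaluation,
  pipeline orchestration.
- `inst/extdata/` — replay annotations, roleset inventory, synthetic CUI
  lexicon and synthetic mini-ontology, example document.
- `vignettes/building-knowledge-graphs.Rmd` — the methods vignette: the
  model, its assumptions, parameters and limitations.
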