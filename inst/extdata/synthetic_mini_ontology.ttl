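# Synthetic miniature target ontology for tests and examples.
# Classes carry a UMLS CUI on the thes:umlsCui annotation property, in the
# style of CUI-annotated biomedical thesauri; IRIs and mappings are made up.
@prefix thes: <http://example.org/thesaurus#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .

thes:Study a owl:Class ;
  rdfs:label "Study" ;
  thes:umlsCui "C0008972" .

thes:Prevalence a owl:Class ;
  rdfs:label "Prevalence" ;
  thes:umlsCui "C0033105" .

thes:CognitiveImpairment a owl:Class ;
  rdfs:label "Cognitive Impairment" ;
  thes:umlsCui "C0338656" .

thes:PopulationGroup a owl:Class ;
  rdfs:label "Population Group" ;
  thes:umlsCui "C0032659" .

thes:Attention a owl:Class ;
  rdfs:label "Attention" ;
  thes:umlsCui "C0004268" .

thes:RiskFactor a owl:Class ;
  rdfs:label "Risk Factor" ;
  thes:umlsCui "C0035648" .

thes:Dementia a owl:Class ;
  rdfs:label "Dementia" ;
  thes:umlsCui "C0011265" .
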