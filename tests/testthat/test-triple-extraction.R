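# Main (reified and plain) and secondary triple extraction against the
# golden sets transcribed from the worked examples, plus the structural
# laws of the extraction rules.

GOLDEN_MAIN_CONFIRMS <- c(
  "confirms | role:Agent | study",
  "confirms | role:Theme | high prevalence of poststroke cognitive impairment")

GOLDEN_SECONDARY_CONFIRMS <- c(
  "high prevalence | rdfs:subClassOf | prevalence",
  "cognitive impairment | rdfs:subClassOf | impairment",
  "poststroke cognitive impairment | rdfs:subClassOf | cognitive impairment",
  "high prevalence of poststroke cognitive impairment | local:of_poststrokecognitiveimpairment | high prevalence",
  "high prevalence of poststroke cognitive impairment | local:highprevalence_of | poststroke cognitive impairment")

GOLDEN_MAIN_WARRANT <- c(
  "warrant | role:Agent | ethnoracial differences",
  "warrant | role:Theme | attention",
  "warrant | local:AM-LOC | development of prevention strategies")

GOLDEN_PLAIN_WARRANT <- c(
  "ethnoracial differences | warrant | attention",
  "ethnoracial differences | warrant attention in | development of prevention strategies")

GOLDEN_SECONDARY_WARRANT <- c(
  "prevention strategies | rdfs:subClassOf | strategies",
  "ethnoracial differences | rdfs:subClassOf | differences",
  "development of prevention strategies | local:of_preventionstrategies | development",
  "development of prevention strategies | local:development_of | prevention strategies")

test_that("phrase stripping removes leading determiners and stop words only", {
  expect_identical(strip_phrase("the high prevalence of poststroke cognitive impairment"),
                   "high prevalence of poststroke cognitive impairment")
  expect_identical(strip_phrase("this study"), "study")
  expect_identical(strip_phrase("attention"), "attention")
  expect_identical(strip_phrase("Ethnoracial differences", sentence_initial = TRUE),
                   "ethnoracial differences")
  # interior stop words untouched
  expect_identical(strip_phrase("development of the strategies"),
                   "development of the strategies")
  # all-stop-word phrase collapses to empty; caller decides
  expect_identical(strip_phrase("the those"), "")
})

test_that("roleset resolution covers core labels and prefers the lowest sense", {
  inv <- default_rolesets()
  rs <- resolve_roleset("confirm", c("A0", "A1"), inv)
  expect_identical(rs$sense_id, "confirm.01")
  expect_identical(unname(rs$roles[c("A0", "A1")]), c("Agent", "Theme"))
  # AM-* labels do not constrain the match
  rs2 <- resolve_roleset("warrant", c("A0", "A1", "AM-LOC"), inv)
  expect_identical(rs2$sense_id, "warrant.01")
  expect_false("AM-LOC" %in% names(rs2$roles))
  # multiple matching senses: lowest sense number wins
  rs3 <- resolve_roleset("point", c("A0", "A1"), inv)
  expect_identical(rs3$sense_id, "point.01")
  expect_null(resolve_roleset("zzzfakeverb", "A0", inv))
})

test_that("reified extraction reproduces the printed main triples", {
  p <- fixture_provider()
  main_a <- extract_main_triples(analyze_sentence(p, SENT_CONFIRMS_SHORT))
  expect_triple_set(main_a, GOLDEN_MAIN_CONFIRMS)
  expect_true(all(main_a$provenance == "main"))
  # ordering: A0, A1, then AM-* labels
  main_e <- extract_main_triples(analyze_sentence(p, SENT_WARRANT))
  expect_identical(main_e$predicate,
                   c("role:Agent", "role:Theme", "local:AM-LOC"))
  expect_triple_set(main_e, GOLDEN_MAIN_WARRANT)
})

test_that("every argument yields exactly one reified triple", {
  p <- fixture_provider()
  for (s in c(SENT_CONFIRMS_SHORT, SENT_CONFIRMS_LONG, SENT_WARRANT,
              SENT_HIGHLIGHTS_RESOLVED)) {
    ann <- analyze_sentence(p, s, c("tokens", "srl"))
    n_args <- sum(lengths(lapply(ann$srl, function(f) f$args)))
    main <- extract_main_triples(ann)
    expect_identical(nrow(main), n_args)
    has_core <- any(vapply(ann$srl, function(f) {
      all(c("A0", "A1") %in% names(f$args))
    }, logical(1)))
    if (has_core) expect_gte(nrow(main), 2L)
  }
})

test_that("plain extraction reproduces the printed non-reified triples", {
  p <- fixture_provider()
  plain_e <- extract_main_triples_plain(analyze_sentence(p, SENT_WARRANT))
  expect_triple_set(plain_e, GOLDEN_PLAIN_WARRANT)
  plain_a <- extract_main_triples_plain(analyze_sentence(p, SENT_CONFIRMS_SHORT))
  expect_triple_set(plain_a, c(
    "study | confirms | high prevalence of poststroke cognitive impairment"))
  # a frame lacking A0 is skipped with a warning (passive construction)
  ann_h <- analyze_sentence(
    p, "Prevention strategies are required to reduce the prevalence of poststroke cognitive impairment.")
  expect_warning(plain_h <- extract_main_triples_plain(ann_h),
                 "lacks A0 or A1")
  expect_false("required" %in% plain_h$predicate)
})

test_that("secondary extraction reproduces the printed dependency triples", {
  p <- fixture_provider()
  sec_a <- extract_secondary_triples(analyze_sentence(p, SENT_CONFIRMS_SHORT))
  expect_triple_set(sec_a, GOLDEN_SECONDARY_CONFIRMS)
  sec_e <- extract_secondary_triples(analyze_sentence(p, SENT_WARRANT))
  expect_triple_set(sec_e, GOLDEN_SECONDARY_WARRANT)
  expect_true(all(sec_a$provenance == "secondary"))
})

test_that("peel chains form a path of k subclass triples for k pre-modifiers", {
  p <- fixture_provider()
  for (s in c(SENT_CONFIRMS_SHORT, SENT_CONFIRMS_LONG, SENT_WARRANT,
              SENT_HIGHLIGHTS_RESOLVED)) {
    ann <- analyze_sentence(p, s, c("tokens", "dependency", "srl"))
    sec <- extract_secondary_triples(ann)
    peel <- sec[sec$predicate == "rdfs:subClassOf", , drop = FALSE]
    # each peel step removes exactly the leftmost modifier: subject text is
    # "<modifier> <object text>" up to stripping
    for (i in seq_len(nrow(peel))) {
      expect_identical(
        peel$subject[i],
        strip_phrase(paste(tolower(peel$modifier[i]), peel$object[i])))
    }
    # no branching: each subject peels to exactly one parent
    expect_identical(anyDuplicated(peel$subject), 0L)
  }
})

test_that("secondary subjects anchor to main argument texts or earlier peels", {
  p <- fixture_provider()
  for (s in c(SENT_CONFIRMS_SHORT, SENT_WARRANT)) {
    ann <- analyze_sentence(p, s)
    main <- extract_main_triples(ann)
    sec <- extract_secondary_triples(ann, main)
    anchors <- c(main$object, sec$object)
    expect_true(all(sec$subject %in% c(anchors, sec$subject[
      sec$predicate == "rdfs:subClassOf"])))
    # every prepositional-rule subject is a main-triple argument text
    prep <- sec[grepl("^local:", sec$predicate), , drop = FALSE]
    expect_true(all(prep$subject %in% main$object))
  }
})

test_that("modifier-term triples classify adjectives and compounds", {
  p <- fixture_provider()
  sec <- extract_secondary_triples(analyze_sentence(p, SENT_HIGHLIGHTS_RESOLVED))
  extra <- emit_modifier_term_triples(sec)
  expect_triple_set(extra, c(
    "common risk factors | local:hasAdjective | common",
    "risk factors | local:hasCompound | risk"))
  # purely adjectival modifier
  sec_b <- extract_secondary_triples(analyze_sentence(p, SENT_CONFIRMS_LONG))
  extra_b <- emit_modifier_term_triples(sec_b)
  expect_true("diverse populations | local:hasAdjective | diverse" %in%
                triple_set(extra_b))
  # a bare-noun sentence yields nothing
  expect_identical(nrow(emit_modifier_term_triples(new_triples())), 0L)
})

test_that("annotations without frames or nouns yield empty triple sets", {
  toks <- tibble::tibble(index = 0:1, surface = c("Indeed", "."),
                         pos = c("RB", "."), lemma = c("indeed", "."))
  ann <- new_annotation(toks, dependencies = tibble::tibble(
    head = c(-1L, 0L), dep = c(0L, 1L), rel = c("root", "punct")),
    srl = list())
  expect_identical(nrow(extract_main_triples(ann)), 0L)
  expect_identical(nrow(extract_secondary_triples(ann)), 0L)
})
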