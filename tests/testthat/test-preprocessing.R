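# Preprocessing: splitting, coreference substitution, Schwartz-Hearst
# abbreviation handling and conjunction-based simplification.

test_that("sentence splitting finds boundaries at terminal punctuation", {
  two <- paste(SENT_CONFIRMS_LONG, SENT_HIGHLIGHTS_PRONOUN)
  out <- split_sentences(two)
  expect_identical(out, c(SENT_CONFIRMS_LONG, SENT_HIGHLIGHTS_PRONOUN))
  expect_identical(split_sentences("Alzheimer's Disease causes dementia."),
                   "Alzheimer's Disease causes dementia.")
  expect_identical(split_sentences(""), character(0))
  # concatenation preserves all non-whitespace characters
  expect_identical(gsub("\\s", "", paste(out, collapse = " ")),
                   gsub("\\s", "", two))
})

test_that("pronoun coreference substitution reproduces the worked example", {
  sents <- c(SENT_CONFIRMS_LONG, SENT_HIGHLIGHTS_PRONOUN)
  chain <- coref_chain(list(list(sentence = 1, span = c(0, 2)),
                            list(sentence = 2, span = c(0, 1))),
                       representative = 1)
  out <- resolve_coreferences(sents, list(chain))
  expect_identical(out[1], SENT_CONFIRMS_LONG)
  expect_identical(out[2], SENT_HIGHLIGHTS_RESOLVED)
  # empty chain list is the identity
  expect_identical(resolve_coreferences(sents), sents)
  # an all-pronoun chain is skipped with a warning and changes nothing
  bad <- coref_chain(list(list(sentence = 2, span = c(0, 1)),
                          list(sentence = 2, span = c(0, 1))),
                     representative = 1)
  expect_warning(out2 <- resolve_coreferences(sents, list(bad)),
                 "pronominal")
  expect_identical(out2, sents)
})

test_that("abbreviation detection matches the printed example and rejects non-letters", {
  sents <- c(
    "This study confirms the high prevalence of poststroke cognitive impairment (PSCI) in diverse populations.",
    "Prevention strategies are required to reduce the prevalence of PSCI.")
  pairs <- detect_abbreviations(sents)
  expect_identical(pairs$short_form, "PSCI")
  expect_identical(pairs$long_form, "poststroke cognitive impairment")
  mr <- detect_abbreviations("magnetic resonance (MR) imaging")
  expect_identical(mr$long_form, "magnetic resonance")
  expect_identical(nrow(detect_abbreviations("in the cohort (2019) we")), 0L)
})

test_that("abbreviation detection agrees with the brute-force alignment oracle", {
  candidates <- list(
    c("PSCI", "confirms the high prevalence of poststroke cognitive impairment"),
    c("MR", "for magnetic resonance"),
    c("MRI", "uses magnetic resonance imaging"),
    c("AD", "such as Alzheimer's Disease"),
    c("UMLS", "the Unified Medical Language System"),
    c("NCIT", "the National Cancer Institute Thesaurus"),
    c("CUI", "a Concept Unique Identifier"),
    c("KG", "a knowledge graph"),
    c("SRL", "semantic role labeling"),
    c("NER", "named entity recognition"),
    c("XYZ", "completely unrelated words here")
  )
  for (cand in candidates) {
    expected <- sh_oracle(cand[1], cand[2])
    sentence <- paste0(cand[2], " (", cand[1], ") follows.")
    got <- detect_abbreviations(sentence)
    if (is.null(expected)) {
      expect_identical(nrow(got), 0L, label = cand[1])
    } else {
      expect_identical(got$long_form, expected, label = cand[1])
    }
  }
})

test_that("expansion replaces whole tokens everywhere and is idempotent", {
  sents <- c(
    "This study confirms the high prevalence of poststroke cognitive impairment (PSCI) in diverse populations.",
    "Prevention strategies are required to reduce the prevalence of PSCI.")
  pairs <- detect_abbreviations(sents)
  out <- expand_abbreviations(sents, pairs)
  expect_identical(out[1], SENT_CONFIRMS_LONG)
  expect_identical(
    out[2],
    "Prevention strategies are required to reduce the prevalence of poststroke cognitive impairment.")
  expect_false(any(grepl("PSCI", out)))
  # idempotence
  expect_identical(expand_abbreviations(out, pairs), out)
  # identity on an empty pair list
  expect_identical(expand_abbreviations(sents, detect_abbreviations("none")),
                   sents)
  # a short form occurring only at its definition site: parenthetical removed
  solo <- "We measured magnetic resonance (MR) imaging."
  out3 <- expand_abbreviations(solo, detect_abbreviations(solo))
  expect_identical(out3, "We measured magnetic resonance imaging.")
  # conflicting long forms are an error
  clash <- tibble::tibble(short_form = c("AD", "AD"),
                          long_form = c("Alzheimer's Disease", "adverse drug"),
                          sentence = c(1L, 1L), start = c(0L, 0L),
                          end = c(1L, 1L))
  expect_error(expand_abbreviations(solo, clash),
               class = "litkg_ambiguity_error")
})

test_that("VP coordination splits into subject-copied sentences", {
  ann <- analyze_sentence(fixture_provider(), SENT_CONJUNCTION, "constituency")
  out <- simplify_sentence(SENT_CONJUNCTION, ann$constituency)
  expect_identical(out, c("This study confirms cognitive impairment in populations.",
                          "This study points to ethnoracial differences."))
})

test_that("coordinated NP pre-modifiers distribute over the head", {
  ann <- analyze_sentence(fixture_provider(), SENT_SULCI, "constituency")
  out <- simplify_sentence(SENT_SULCI, ann$constituency)
  expect_identical(out, c(
    "High-convexity tight sulci may confound clinical interpretation in Alzheimer's Disease clinical trials.",
    "High-convexity tight sulci may confound biomarker interpretation in Alzheimer's Disease clinical trials."))
})

test_that("sentences without a conjunction pass through as singletons", {
  ann <- analyze_sentence(fixture_provider(), SENT_CONFIRMS_SHORT, "constituency")
  expect_identical(simplify_sentence(SENT_CONFIRMS_SHORT, ann$constituency),
                   SENT_CONFIRMS_SHORT)
  expect_error(
    simplify_sentence("Totally different words.", ann$constituency),
    class = "litkg_inconsistency_error")
})

test_that("simplification only reuses source and copied tokens", {
  p <- fixture_provider()
  for (s in c(SENT_CONJUNCTION, SENT_SULCI, SENT_CONFIRMS_SHORT)) {
    ann <- analyze_sentence(p, s, "constituency")
    src_tokens <- simple_tokenize(s)
    for (out in simplify_sentence(s, ann$constituency)) {
      extra <- setdiff(simple_tokenize(out), c(src_tokens, "."))
      expect_identical(extra, character(0))
    }
  }
})

test_that("preprocess_document composes the sub-steps in the fixed order", {
  p <- fixture_provider()
  doc <- paste(
    "This study confirms the high prevalence of poststroke cognitive impairment (PSCI) in diverse populations.",
    "It also highlights common risk factors.")
  chain <- coref_chain(list(list(sentence = 1, span = c(0, 2)),
                            list(sentence = 2, span = c(0, 1))),
                       representative = 1)
  pre <- preprocess_document(doc, p, chains = list(chain))
  expect_identical(pre$sentence,
                   c(SENT_CONFIRMS_LONG, SENT_HIGHLIGHTS_RESOLVED))
  expect_true("abbrev" %in% pre$transforms[[1]])
  expect_true("coref" %in% pre$transforms[[2]])
  expect_identical(pre$source, c(1L, 2L))
  pairs <- attr(pre, "abbreviations")
  expect_identical(pairs$short_form, "PSCI")

  # empty input
  empty <- preprocess_document("", p)
  expect_identical(nrow(empty), 0L)

  # text needing no transform equals the split output
  plain <- preprocess_document(SENT_CONFIRMS_SHORT, p)
  expect_identical(plain$sentence, SENT_CONFIRMS_SHORT)
  expect_identical(plain$transforms[[1]], character(0))
})
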