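# Candidate collection, UMLS mapping, CUI -> ontology class lookup, link-set
# union and the funnel report.

test_that("link candidates are entity surfaces plus verb lemmas, deduplicated", {
  p <- fixture_provider()
  ann <- analyze_sentence(p, SENT_CONFIRMS_LONG)
  cand <- extract_link_candidates(list(ann))
  for (term in c("study", "prevalence", "impairment", "cognitive impairment",
                 "populations")) {
    expect_true(term %in% cand, label = term)
  }
  expect_true("confirm" %in% cand)  # lemma of "confirms"
  # duplicates across sentences collapse to the first occurrence
  cand2 <- extract_link_candidates(list(ann, ann))
  expect_identical(cand2, cand)
  expect_identical(anyDuplicated(tolower(cand)), 0L)
})

test_that("UMLS mapping partitions candidates and picks the top-scoring CUI", {
  lex <- default_cui_lexicon()
  res <- map_to_umls(c("cognitive impairment", "qwertyplasm", "study"), lex)
  expect_identical(res$mappings$cui[res$mappings$surface == "cognitive impairment"],
                   "C0338656")
  expect_identical(res$unmatched, "qwertyplasm")
  expect_identical(nrow(res$mappings) + length(res$unmatched), 3L)
  # score ties break by lexicographic CUI order
  tie <- map_to_umls("dementia", lex)
  expect_identical(tie$mappings$cui, "C0011265")
  # partition law on a larger candidate set
  cand <- c(lex$term, "nonsenseword", "anothermiss")
  res2 <- map_to_umls(cand, lex)
  expect_identical(nrow(res2$mappings) + length(res2$unmatched), length(cand))
})

test_that("CUI to ontology lookup returns annotated classes, sorted", {
  onto <- synthetic_mini_ontology()
  hit <- map_cui_to_ontology("C0338656", onto, "thes:umlsCui")
  expect_identical(hit, "http://example.org/thesaurus#CognitiveImpairment")
  expect_identical(map_cui_to_ontology("C9999999", onto, "thes:umlsCui"),
                   character(0))
  expect_error(map_cui_to_ontology("C0338656", onto, NULL),
               class = "litkg_invalid_input")

  # a CUI annotated on two classes returns both, sorted; verified against a
  # brute-force scan of every statement in the store
  ttl <- paste(
    '@prefix t: <http://example.org/t#> .',
    't:B t:umlsCui "C0000001" .',
    't:A t:umlsCui "C0000001" .',
    't:C t:umlsCui "C0000002" .', sep = "\n")
  f <- tempfile(fileext = ".ttl"); writeLines(ttl, f)
  store <- read_ontology(f)
  got <- map_cui_to_ontology("C0000001", store, "t:umlsCui")
  brute <- character(0)
  for (i in seq_len(nrow(store$triples))) {
    row <- store$triples[i, ]
    if (grepl("umlsCui$", row$predicate) && row$object == "C0000001") {
      brute <- c(brute, sub("^t:", "http://example.org/t#", row$subject))
    }
  }
  expect_identical(got, sort(brute))
  expect_identical(got, c("http://example.org/t#A", "http://example.org/t#B"))
})

test_that("the SPARQL query text carries the CUI and property", {
  q <- sparql_cui_query("C0338656", "http://example.org/thesaurus#umlsCui")
  expect_match(q, "SELECT DISTINCT \\?class")
  expect_match(q, "C0338656", fixed = TRUE)
  expect_match(q, "http://example.org/thesaurus#umlsCui", fixed = TRUE)
  # an endpoint adapter is any function of the query
  fake_endpoint <- function(query) c("http://x/B", "http://x/A")
  expect_identical(
    map_cui_to_ontology("C1", fake_endpoint, "http://x/p"),
    c("http://x/A", "http://x/B"))
})

test_that("combining link sets is a union that dominates both sources", {
  mk <- function(surfaces) {
    tibble::tibble(surface = surfaces, cui = paste0("C", seq_along(surfaces)),
                   class_iri = paste0("http://x/", surfaces),
                   label = surfaces, source = "x")
  }
  primary <- mk(c("l1", "l2", "l3", "l4", "l5", "l6"))
  fallback <- mk(c("l5", "l6", "f1", "f2"))
  combined <- combine_link_sets(primary, fallback)
  # |A| = 6, |B| = 4, overlap 2 -> |A u B| = 8
  expect_identical(nrow(combined), 8L)
  expect_true(all(combined$source == "combined"))
  key <- function(x) paste(x$surface, x$class_iri)
  expect_true(all(key(primary) %in% key(combined)))
  expect_true(all(key(fallback) %in% key(combined)))
  # empty fallback leaves the primary links unchanged (sources aside)
  same <- combine_link_sets(primary, primary[0, ])
  expect_identical(key(same), key(primary))
  # mismatched target ontologies are rejected
  a <- primary; attr(a, "ontology") <- "http://onto/1"
  b <- fallback; attr(b, "ontology") <- "http://onto/2"
  expect_error(combine_link_sets(a, b), class = "litkg_invalid_combination")
})

test_that("the linking funnel is monotone on fixture documents", {
  p <- fixture_provider()
  for (s in c(SENT_CONFIRMS_LONG, SENT_WARRANT, SENT_HIGHLIGHTS_RESOLVED)) {
    ann <- analyze_sentence(p, s)
    res <- link_terms(list(ann), cui_property = "thes:umlsCui")
    rep <- res$report
    expect_lte(rep$ontology_links, rep$cuis_found)
    expect_lte(rep$cuis_found, rep$terms_identified)
  }
  # and on random subsets of the lexicon vocabulary
  set.seed(42)
  lex <- default_cui_lexicon()
  onto <- synthetic_mini_ontology()
  vocab <- c(lex$term, paste0("unknown", 1:5))
  for (i in 1:10) {
    cand <- sample(vocab, sample(3:8, 1))
    cand <- cand[!duplicated(tolower(cand))]
    um <- map_to_umls(cand, lex)
    links <- do.call(rbind, lapply(seq_len(nrow(um$mappings)), function(j) {
      iris <- map_cui_to_ontology(um$mappings$cui[j], onto, "thes:umlsCui")
      if (length(iris) == 0) return(NULL)
      data.frame(surface = um$mappings$surface[j], cui = um$mappings$cui[j],
                 class_iri = iris, label = NA, source = "umls_sparql")
    }))
    if (is.null(links)) {
      links <- tibble::tibble(surface = character(), cui = character(),
                              class_iri = character(), label = character(),
                              source = character())
    }
    rep <- build_link_report(cand, um$mappings, links)
    expect_lte(rep$ontology_links, rep$cuis_found)
    expect_lte(rep$cuis_found, rep$terms_identified)
  }
})

test_that("link report counting matches the chain outputs", {
  rep <- build_link_report(
    candidates = paste0("t", 1:5),
    mappings = tibble::tibble(surface = paste0("t", 1:3)),
    links = tibble::tibble(surface = paste0("t", 1:2)))
  expect_identical(unlist(rep, use.names = FALSE), c(5L, 3L, 2L))
  zero <- build_link_report(character(0),
                            tibble::tibble(surface = character(0)),
                            tibble::tibble(surface = character(0)))
  expect_identical(unlist(zero, use.names = FALSE), c(0L, 0L, 0L))
  expect_error(
    build_link_report(character(0),
                      tibble::tibble(surface = "a"),
                      tibble::tibble(surface = "a")),
    class = "litkg_invalid_input")
})
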