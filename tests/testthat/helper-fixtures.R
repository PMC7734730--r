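# Shared fixtures and independent oracles.

fixture_provider <- local({
  prov <- NULL
  function() {
    if (is.null(prov)) {
      prov <<- replay_provider(system.file("extdata", "annotations.json",
                                           package = "litkg"))
    }
    prov
  }
})

SENT_CONFIRMS_SHORT <-
  "This study confirms the high prevalence of poststroke cognitive impairment."
SENT_CONFIRMS_LONG <-
  "This study confirms the high prevalence of poststroke cognitive impairment in diverse populations."
SENT_WARRANT <-
  "Ethnoracial differences warrant attention in the development of prevention strategies."
SENT_HIGHLIGHTS_PRONOUN <- "It also highlights common risk factors."
SENT_HIGHLIGHTS_RESOLVED <- "This study also highlights common risk factors."
SENT_CONJUNCTION <-
  "This study confirms cognitive impairment in populations, and points to ethnoracial differences."
SENT_SULCI <-
  "High-convexity tight sulci may confound clinical and biomarker interpretation in Alzheimer's Disease clinical trials."

# Order-insensitive view of a triple set.
triple_set <- function(triples) {
  sort(paste(triples$subject, triples$predicate, triples$object, sep = " | "))
}

expect_triple_set <- function(triples, expected) {
  expect_setequal(triple_set(triples), sort(expected))
}

# Quickly build a triple tibble from s/p/o vectors (evaluation tests).
spo <- function(s, p, o) new_triples(subject = s, predicate = p, object = o)

# ---- Schwartz-Hearst brute-force oracle -------------------------------------
# Enumerates word suffixes of the candidate (shortest first) and searches for
# any monotone right-to-left character alignment whose first short-form
# character sits at the start of the suffix.

sh_oracle <- function(short, candidate) {
  words <- strsplit(stringr::str_squish(candidate), " ")[[1]]
  schars <- strsplit(tolower(gsub("[^A-Za-z0-9]", "", short)), "")[[1]]
  if (length(schars) == 0L) return(NULL)
  max_words <- min(nchar(short) + 5L, 2L * nchar(short))
  for (start in rev(seq_along(words))) {
    if (length(words) - start + 1L > max_words) break
    suffix <- paste(words[start:length(words)], collapse = " ")
    if (nchar(suffix) <= nchar(short)) next
    if (sh_alignment_exists(schars, strsplit(tolower(suffix), "")[[1]])) {
      return(suffix)
    }
  }
  NULL
}

sh_alignment_exists <- function(schars, lchars) {
  if (length(lchars) < length(schars)) return(FALSE)
  rec <- function(si, li) {
    if (si > length(schars)) return(TRUE)
    if (si == 1L) {
      return(lchars[1] == schars[1] && rec(2L, 2L))
    }
    if (li > length(lchars)) return(FALSE)
    for (j in li:length(lchars)) {
      if (lchars[j] == schars[si] && rec(si + 1L, j + 1L)) return(TRUE)
    }
    FALSE
  }
  rec(1L, 1L)
}

# ---- Jaccard brute-force oracle ---------------------------------------------
# Pairwise membership count over the raw (already normalized) key strings.

jaccard_oracle <- function(keys_a, keys_b) {
  keys_a <- unique(keys_a)
  keys_b <- unique(keys_b)
  if (length(keys_a) == 0L && length(keys_b) == 0L) return(1)
  inter <- sum(vapply(keys_a, function(k) any(keys_b == k), logical(1)))
  inter / (length(keys_a) + length(keys_b) - inter)
}

# Deterministic synthetic triple sets of given cardinalities and overlap,
# used for table-arithmetic checks.
synthetic_sets <- function(n_a, n_b, n_overlap) {
  shared <- sprintf("shared concept %02d", seq_len(n_overlap))
  a_only <- sprintf("manual concept %02d", seq_len(n_a - n_overlap))
  b_only <- sprintf("automatic concept %02d", seq_len(n_b - n_overlap))
  list(
    a = spo(c(shared, a_only), "relates to", paste(c(shared, a_only), "object")),
    b = spo(c(shared, b_only), "relates to", paste(c(shared, b_only), "object"))
  )
}
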