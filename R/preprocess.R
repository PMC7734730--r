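# Preprocessing: raw text -> simplified, self-contained sentences.
# Sub-steps run in a fixed order: sentence splitting, pronoun coreference
# substitution, abbreviation detection + expansion, conjunction-based
# sentence simplification.

PRONOUN_INVENTORY <- c("it", "its", "they", "them", "their",
                       "this", "these", "that", "those")

#' Split a document into sentences
#'
#' Rule-based splitter: boundaries occur at terminal punctuation (`.`, `!`,
#' `?`) followed by whitespace and an upper-case or opening character.
#' Concatenating the outputs with single spaces preserves every
#' non-whitespace character of the input.
#'
#' @param document Input text (may be empty).
#' @return Character vector of sentences (empty for empty input).
#' @export
split_sentences <- function(document) {
  stopifnot(is.character(document), length(document) == 1L)
  document <- stringr::str_squish(document)
  if (!nzchar(document)) return(character(0))
  out <- strsplit(document, "(?<=[.!?])\\s+(?=[A-Z(\\[\"'])", perl = TRUE)[[1]]
  stringr::str_squish(out)
}

#' Construct a coreference chain
#'
#' @param mentions List of mentions, each a list with `sentence` (1-based
#'   sentence index) and `span` (0-based half-open token span within that
#'   sentence).
#' @param representative 1-based index into `mentions` of the representative
#'   (non-pronominal) mention.
#' @return A `litkg_coref_chain` object.
#' @export
coref_chain <- function(mentions, representative = 1L) {
  if (length(mentions) < 2L) {
    abort_litkg("a coreference chain needs at least two mentions",
                "litkg_invalid_input")
  }
  structure(list(mentions = mentions, representative = representative),
            class = "litkg_coref_chain")
}

is_pronominal <- function(tokens) {
  length(tokens) > 0L && all(tolower(tokens) %in% PRONOUN_INVENTORY)
}

#' Substitute coreferent pronouns
#'
#' Replaces each pronominal mention of a chain with the representative
#' mention's text. Chains whose every mention is pronominal are skipped with
#' a warning. Sentence-initial replacements are capitalized; elsewhere the
#' representative keeps its original casing.
#'
#' @param sentences Character vector of sentence texts.
#' @param chains List of [coref_chain()] objects.
#' @return Character vector of the same length with pronouns substituted.
#' @export
resolve_coreferences <- function(sentences, chains = list()) {
  if (length(chains) == 0L) return(sentences)
  toks <- lapply(sentences, simple_tokenize)
  edits <- list()  # per sentence: list of list(span, replacement_tokens)
  for (chain in chains) {
    rep_i <- chain$representative
    rep_m <- chain$mentions[[rep_i]]
    rep_tokens <- toks[[rep_m$sentence]][(rep_m$span[1] + 1L):rep_m$span[2]]
    if (is_pronominal(rep_tokens)) {
      rlang::warn(paste0("coreference chain skipped: representative mention '",
                         detokenize(rep_tokens), "' is pronominal"))
      next
    }
    for (j in seq_along(chain$mentions)) {
      if (j == rep_i) next
      m <- chain$mentions[[j]]
      m_tokens <- toks[[m$sentence]][(m$span[1] + 1L):m$span[2]]
      if (!is_pronominal(m_tokens)) next
      edits[[length(edits) + 1L]] <- list(sentence = m$sentence,
                                          span = m$span,
                                          replacement = rep_tokens)
    }
  }
  if (length(edits) == 0L) return(sentences)
  out <- sentences
  for (si in unique(vapply(edits, function(e) e$sentence, numeric(1)))) {
    sent_edits <- Filter(function(e) e$sentence == si, edits)
    ord <- order(vapply(sent_edits, function(e) e$span[1], numeric(1)),
                 decreasing = TRUE)
    tt <- toks[[si]]
    for (e in sent_edits[ord]) {
      repl <- e$replacement
      if (e$span[1] == 0L) repl[1] <- capitalize_first(repl[1])
      before <- if (e$span[1] > 0L) tt[1:e$span[1]] else character(0)
      after <- if (e$span[2] < length(tt)) tt[(e$span[2] + 1L):length(tt)] else character(0)
      tt <- c(before, repl, after)
    }
    out[si] <- detokenize(tt)
  }
  out
}

# ---- abbreviations (Schwartz-Hearst) ----------------------------------------

#' Detect abbreviation definitions
#'
#' Finds `long form (SHORT)` definition sites and validates the pairing with
#' the Schwartz-Hearst character-alignment conditions: every short-form
#' character aligns (right to left) to a character of the long-form
#' candidate, the first short-form character starts a long-form word, and
#' the long form has at most `min(|short| + 5, 2 * |short|)` words.
#'
#' @param sentences Character vector of sentence texts.
#' @return Tibble with columns `short_form`, `long_form`, `sentence`
#'   (1-based index), `start`, `end` (0-based half-open token span covering
#'   "long form ( short form )").
#' @export
detect_abbreviations <- function(sentences) {
  rows <- list()
  for (si in seq_along(sentences)) {
    tt <- simple_tokenize(sentences[si])
    opens <- which(tt == "(")
    for (oi in opens) {
      close <- which(tt == ")" & seq_along(tt) > oi)
      if (length(close) == 0L) next
      ci <- close[1]
      inner <- tt[seq_len(ci - oi - 1L) + oi]
      if (length(inner) < 1L || length(inner) > 2L) next
      sf <- detokenize(inner)
      if (nchar(sf) < 2L || nchar(sf) > 10L) next
      if (!grepl("[A-Za-z]", sf)) next
      if (!grepl("^[A-Za-z0-9]", sf)) next
      if (oi < 2L) next
      max_words <- min(nchar(sf) + 5L, 2L * nchar(sf))
      cand_lo <- max(1L, oi - max_words)
      cand_tokens <- tt[cand_lo:(oi - 1L)]
      cand_tokens <- cand_tokens[grepl("[A-Za-z0-9]", cand_tokens)]
      if (length(cand_tokens) == 0L) next
      candidate <- detokenize(cand_tokens)
      lf <- find_best_long_form(sf, candidate)
      if (is.null(lf)) next
      lf_words <- length(strsplit(lf, "\\s+")[[1]])
      if (lf_words > max_words) next
      if (nchar(lf) <= nchar(sf)) next
      # token span of "long form ( short form )"
      n_lf <- lf_words
      start <- oi - 1L
      seen <- 0L
      while (start > 0L && seen < n_lf) {
        if (grepl("[A-Za-z0-9]", tt[start])) seen <- seen + 1L
        if (seen < n_lf) start <- start - 1L
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        short_form = sf, long_form = lf, sentence = si,
        start = start - 1L, end = ci)
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(short_form = character(), long_form = character(),
                          sentence = integer(), start = integer(),
                          end = integer()))
  }
  dplyr::distinct(dplyr::bind_rows(rows), .data$short_form, .data$long_form,
                  .keep_all = TRUE)
}

# Right-to-left character alignment of the short form against the candidate
# string; returns the long form (suffix of the candidate starting at the
# word whose first character matches the short form's first character), or
# NULL when no alignment exists.
find_best_long_form <- function(short, long) {
  schars <- strsplit(tolower(short), "")[[1]]
  lchars <- strsplit(tolower(long), "")[[1]]
  s_i <- length(schars)
  l_i <- length(lchars)
  while (s_i >= 1L) {
    ch <- schars[s_i]
    if (!grepl("[a-z0-9]", ch)) {
      s_i <- s_i - 1L
      next
    }
    while (l_i >= 1L &&
           (lchars[l_i] != ch ||
            (s_i == 1L && l_i > 1L && grepl("[a-z0-9]", lchars[l_i - 1L])))) {
      l_i <- l_i - 1L
    }
    if (l_i < 1L) return(NULL)
    s_i <- s_i - 1L
    l_i <- l_i - 1L
  }
  trimws(substr(long, l_i + 1L, nchar(long)))
}

#' Expand abbreviations throughout a document
#'
#' Removes each defining parenthetical `(SHORT)` and replaces every
#' standalone (whole-token) occurrence of the short form by its long form,
#' across all sentences.
#'
#' @param sentences Character vector of sentence texts.
#' @param pairs Tibble from [detect_abbreviations()].
#' @return Character vector with abbreviations expanded.
#' @export
expand_abbreviations <- function(sentences, pairs) {
  if (nrow(pairs) == 0L) return(sentences)
  dup <- pairs |>
    dplyr::distinct(.data$short_form, .data$long_form) |>
    dplyr::count(.data$short_form) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    offending <- pairs[pairs$short_form %in% dup$short_form, ]
    abort_litkg(
      paste0("ambiguous abbreviation '", dup$short_form[1], "': ",
             paste(unique(offending$long_form), collapse = " | ")),
      "litkg_ambiguity_error")
  }
  out <- sentences
  for (i in seq_len(nrow(pairs))) {
    sf <- pairs$short_form[i]
    lf <- pairs$long_form[i]
    esc <- rx_escape(sf)
    out <- stringr::str_replace_all(out, paste0("\\s*\\(\\s*", esc, "\\s*\\)"), "")
    out <- stringr::str_replace_all(out, paste0("\\b", esc, "\\b"), lf)
  }
  stringr::str_squish(out)
}

rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# ---- sentence simplification -------------------------------------------------

MODIFIER_LABELS <- c("JJ", "JJR", "JJS", "NN", "NNS", "NNP", "ADJP", "NML", "VBN")

#' Simplify a sentence using its constituency parse
#'
#' Two constructions are handled: a coordinating conjunction joining two (or
#' more) verb phrases under a shared subject yields one sentence per verb
#' phrase with the subject copied; a conjunction joining two pre-modifiers
#' of a shared head noun phrase yields one sentence per distributed
#' modifier. Anything else passes through as a singleton. Derived sentences
#' end with a period.
#'
#' @param sentence Sentence text.
#' @param parse Root constituency node covering the sentence.
#' @return Character vector of one or more sentences.
#' @export
simplify_sentence <- function(sentence, parse) {
  toks <- simple_tokenize(sentence)
  leaves <- constituency_leaves(parse)
  if (!identical(leaves, toks)) {
    abort_litkg("constituency parse does not cover the sentence tokens",
                "litkg_inconsistency_error")
  }
  out <- simplify_vp_coordination(parse)
  if (is.null(out)) out <- simplify_np_modifiers(parse, toks)
  if (is.null(out)) return(ensure_terminal(sentence))
  vapply(out, ensure_terminal, character(1))
}

child_labels <- function(node) {
  vapply(node$children, function(c) c$label, character(1))
}

# VP coordination under a shared subject: (S (NP subj) (VP (VP ...) , CC (VP ...)) .)
simplify_vp_coordination <- function(root) {
  labs <- child_labels(root)
  np_i <- which(labs == "NP")
  vp_i <- which(labs == "VP")
  if (length(np_i) < 1L || length(vp_i) < 1L || np_i[1] > vp_i[1]) return(NULL)
  vp <- root$children[[vp_i[1]]]
  inner <- child_labels(vp)
  conj_vps <- vp$children[inner == "VP"]
  if (length(conj_vps) < 2L || !any(inner == "CC")) return(NULL)
  subject <- constituency_leaves(root$children[[np_i[1]]])
  lapply(conj_vps, function(cv) detokenize(c(subject, constituency_leaves(cv))))
}

# Coordinated pre-modifiers of a shared head NP:
# (NP ... (JJ clinical) (CC and) (NN biomarker) (NN interpretation))
simplify_np_modifiers <- function(root, toks) {
  np <- find_coordinated_np(root)
  if (is.null(np)) return(NULL)
  labs <- child_labels(np)
  cc <- which(labs == "CC")[1]
  if (cc < 2L || cc > length(labs) - 2L) return(NULL)
  prefix <- if (cc > 2L) np$children[seq_len(cc - 2L)] else list()
  mod1 <- np$children[[cc - 1L]]
  mod2 <- np$children[[cc + 1L]]
  head_children <- np$children[(cc + 2L):length(np$children)]
  head_labs <- vapply(head_children, function(c) c$label, character(1))
  if (!any(grepl("^NN", head_labs[length(head_labs)]))) return(NULL)
  span <- np$span
  before <- if (span[1] > 0L) toks[1:span[1]] else character(0)
  after <- if (span[2] < length(toks)) toks[(span[2] + 1L):length(toks)] else character(0)
  prefix_toks <- unlist(lapply(prefix, constituency_leaves), use.names = FALSE)
  head_toks <- unlist(lapply(head_children, constituency_leaves), use.names = FALSE)
  lapply(list(mod1, mod2), function(m) {
    detokenize(c(before, prefix_toks, constituency_leaves(m), head_toks, after))
  })
}

find_coordinated_np <- function(node) {
  if (node$label == "NP") {
    labs <- child_labels(node)
    cc <- which(labs == "CC")
    if (length(cc) == 1L && cc > 1L && cc < length(labs) - 0L) {
      before_ok <- labs[cc - 1L] %in% MODIFIER_LABELS
      after <- labs[(cc + 1L):length(labs)]
      if (before_ok && length(after) >= 2L &&
          after[1] %in% MODIFIER_LABELS && grepl("^NN", after[length(after)])) {
        return(node)
      }
    }
  }
  for (ch in node$children) {
    hit <- find_coordinated_np(ch)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

# ---- orchestration -----------------------------------------------------------

#' Preprocess a document into simplified sentences
#'
#' Applies, in this fixed order: sentence splitting, coreference
#' substitution, abbreviation detection + expansion, and per-sentence
#' simplification (which needs a constituency parse from the provider).
#' The result records, per output sentence, the source sentence index and
#' the transforms applied.
#'
#' @param document Input text.
#' @param provider Annotation provider (needed when `simplify = TRUE`).
#' @param chains List of [coref_chain()] objects (chain discovery is
#'   delegated to the caller or an external engine).
#' @param simplify Run the constituency-based simplification sub-step.
#' @param expand_abbrev Run abbreviation detection/expansion.
#' @return A tibble of class `litkg_pretext` with columns `sentence`,
#'   `source` (input sentence index) and `transforms` (list of character
#'   vectors); detected abbreviation pairs are kept in the
#'   `"abbreviations"` attribute.
#' @export
preprocess_document <- function(document, provider = NULL, chains = list(),
                                simplify = TRUE, expand_abbrev = TRUE) {
  sents <- split_sentences(document)
  transforms <- rep(list(character(0)), length(sents))
  if (length(sents) == 0L) {
    out <- tibble::tibble(sentence = character(), source = integer(),
                          transforms = list())
    class(out) <- c("litkg_pretext", class(out))
    attr(out, "abbreviations") <- detect_abbreviations(character(0))
    return(out)
  }

  resolved <- resolve_coreferences(sents, chains)
  changed <- resolved != sents
  transforms[changed] <- lapply(transforms[changed], c, "coref")
  sents <- resolved

  pairs <- if (expand_abbrev) detect_abbreviations(sents) else
    detect_abbreviations(character(0))
  if (nrow(pairs) > 0L) {
    expanded <- expand_abbreviations(sents, pairs)
    changed <- expanded != sents
    transforms[changed] <- lapply(transforms[changed], c, "abbrev")
    sents <- expanded
  }

  out_sent <- character(0)
  out_src <- integer(0)
  out_tf <- list()
  for (i in seq_along(sents)) {
    pieces <- sents[i]
    tf <- transforms[[i]]
    if (simplify) {
      if (is.null(provider)) {
        abort_litkg("simplification requires an annotation provider",
                    "litkg_invalid_input")
      }
      ann <- tryCatch(
        analyze_sentence(provider, sents[i], "constituency"),
        litkg_error = function(e) {
          abort_litkg(paste0("preprocessing failed at sentence ", i, " ('",
                             sents[i], "'): ", conditionMessage(e)),
                      "litkg_stage_error", parent = e)
        })
      pieces <- simplify_sentence(sents[i], ann$constituency)
      if (length(pieces) > 1L) tf <- c(tf, "simplify")
    } else {
      pieces <- ensure_terminal(pieces)
    }
    out_sent <- c(out_sent, pieces)
    out_src <- c(out_src, rep(i, length(pieces)))
    out_tf <- c(out_tf, rep(list(tf), length(pieces)))
  }

  out <- tibble::tibble(sentence = out_sent, source = out_src,
                        transforms = out_tf)
  class(out) <- c("litkg_pretext", class(out))
  attr(out, "abbreviations") <- pairs
  out
}
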