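# Triple extraction. Main triples come from SRL frames with roleset-based
# reification: the (inflected) verb is the subject and role URIs are the
# predicates. Secondary triples come from the dependency parse: subclass
# chains peeling noun pre-modifiers, and prepositional modification inside
# argument phrases. All phrase texts pass through strip_phrase().

STOP_DETERMINERS <- c("the", "a", "an", "this", "these", "that", "those")
STOP_AUXILIARIES <- c("is", "are", "was", "were", "be", "been", "being",
                      "am", "has", "have", "had", "do", "does", "did",
                      "will", "would", "shall", "should", "may", "might",
                      "can", "could", "must")
DEFAULT_PREPOSITIONS <- c("of", "in", "for", "with", "on")
PREMOD_RELS <- c("amod", "compound")

TERM_KINDS <- c("literal", "local_uri", "role_uri", "external_uri", "builtin_uri")

#' Construct a triple tibble
#'
#' The package-wide tabular triple representation: one row per triple with
#' term kinds and provenance. Extra columns (`modifier`, `modifier_rel`)
#' carry peel metadata on subclass rows.
#'
#' @param subject,predicate,object Character vectors of term values
#'   (literal text or prefixed IRIs).
#' @param subject_kind,predicate_kind,object_kind Term kinds, one of
#'   `r paste(TERM_KINDS, collapse = ", ")`.
#' @param provenance One of `main`, `main_plain`, `secondary`,
#'   `enrichment`, `link`.
#' @param sentence_id Source sentence index.
#' @return A tibble with one row per triple.
#' @export
new_triples <- function(subject = character(), predicate = character(),
                        object = character(),
                        subject_kind = "literal", predicate_kind = "literal",
                        object_kind = "literal",
                        provenance = "main", sentence_id = 0L) {
  tibble::tibble(
    subject = subject, subject_kind = subject_kind,
    predicate = predicate, predicate_kind = predicate_kind,
    object = object, object_kind = object_kind,
    provenance = provenance, sentence_id = as.integer(sentence_id)
  )
}

empty_triples <- function() new_triples()

#' Strip leading stop words from a phrase
#'
#' Removes leading determiners and phrase-initial auxiliaries; interior
#' tokens are untouched. When `sentence_initial = TRUE` and the remaining
#' first word is capitalized (but not an all-caps token), its first
#' character is lower-cased.
#'
#' @param phrase Phrase text.
#' @param sentence_initial Was the phrase at the start of its sentence?
#' @return The stripped phrase (possibly empty when every token is a stop
#'   word; the caller decides what to do then).
#' @export
strip_phrase <- function(phrase, sentence_initial = FALSE) {
  toks <- simple_tokenize(phrase)
  stops <- c(STOP_DETERMINERS, STOP_AUXILIARIES)
  while (length(toks) > 0L && tolower(toks[1]) %in% stops) {
    toks <- toks[-1]
  }
  out <- detokenize(toks)
  if (sentence_initial && nzchar(out)) {
    first <- substr(out, 1L, 1L)
    second <- substr(out, 2L, 2L)
    if (first %in% LETTERS && !(second %in% LETTERS)) {
      out <- paste0(tolower(first), substr(out, 2L, nchar(out)))
    }
  }
  out
}

order_arg_labels <- function(labels) {
  core <- sort(labels[grepl("^A\\d+$", labels)])
  am <- sort(labels[grepl("^AM-", labels)])
  rest <- sort(setdiff(labels, c(core, am)))
  c(core, am, rest)
}

# Resolve one SRL argument span to its surface pieces: optionally detach a
# leading preposition (modifier arguments carry one, e.g. "in the
# development ..."), then strip leading stop words.
argument_text <- function(ann, span, label) {
  idx <- (span[1] + 1L):span[2]
  toks <- ann$tokens[idx, , drop = FALSE]
  prep <- NA_character_
  if (grepl("^AM-", label) && nrow(toks) > 1L &&
      (toks$pos[1] %in% c("IN", "TO") || tolower(toks$surface[1]) %in%
         c(DEFAULT_PREPOSITIONS, "to", "at", "by", "from"))) {
    prep <- tolower(toks$surface[1])
    toks <- toks[-1, , drop = FALSE]
  }
  txt <- strip_phrase(detokenize(toks$surface),
                      sentence_initial = span[1] == 0L && is.na(prep))
  list(text = txt, prep = prep)
}

#' Extract reified main triples from SRL frames
#'
#' Per frame, each argument yields exactly one triple with the inflected
#' verb surface as subject: arguments whose label has a roleset role name
#' get a `role:` predicate; labels without one (e.g. `AM-LOC`) get a
#' `local:` predicate. Triples are ordered A0, A1, A2, then `AM-*`
#' alphabetically.
#'
#' @param annotation A `litkg_annotation` with SRL frames.
#' @param inventory Roleset inventory from [read_rolesets()].
#' @param sentence_id Source sentence index recorded on the triples.
#' @return Triple tibble with provenance `main`.
#' @export
extract_main_triples <- function(annotation, inventory = default_rolesets(),
                                 sentence_id = 0L) {
  frames <- annotation$srl
  if (is.null(frames) || length(frames) == 0L) return(empty_triples())
  rows <- list()
  for (fr in frames) {
    labels <- order_arg_labels(names(fr$args))
    if (length(labels) == 0L) next
    roleset <- resolve_roleset(fr$lemma, names(fr$args), inventory)
    verb <- annotation$tokens$surface[fr$predicate + 1L]
    for (lab in labels) {
      at <- argument_text(annotation, fr$args[[lab]], lab)
      if (!nzchar(at$text)) next
      if (!is.null(roleset) && lab %in% names(roleset$roles)) {
        pred <- paste0("role:", roleset$roles[[lab]])
        pkind <- "role_uri"
      } else {
        pred <- paste0("local:", lab)
        pkind <- "local_uri"
      }
      rows[[length(rows) + 1L]] <- new_triples(
        subject = verb, predicate = pred, object = at$text,
        predicate_kind = pkind, provenance = "main",
        sentence_id = sentence_id)
    }
  }
  if (length(rows) == 0L) return(empty_triples())
  dplyr::bind_rows(rows)
}

#' Extract plain (non-reified) main triples
#'
#' Per frame: `(A0, verb, A1)`, plus, for each `AM-*` argument introduced by
#' a preposition `p`, a composed-predicate triple
#' `(A0, verb + A1-text + p, AM-text minus p)`. Frames lacking A0 or A1 are
#' skipped with a warning.
#'
#' @inheritParams extract_main_triples
#' @return Triple tibble with provenance `main_plain`.
#' @export
extract_main_triples_plain <- function(annotation,
                                       inventory = default_rolesets(),
                                       sentence_id = 0L) {
  frames <- annotation$srl
  if (is.null(frames) || length(frames) == 0L) return(empty_triples())
  rows <- list()
  for (fr in frames) {
    labs <- names(fr$args)
    verb <- annotation$tokens$surface[fr$predicate + 1L]
    if (!all(c("A0", "A1") %in% labs)) {
      rlang::warn(paste0("frame for '", verb,
                         "' lacks A0 or A1; skipped in plain mode"))
      next
    }
    a0 <- argument_text(annotation, fr$args[["A0"]], "A0")
    a1 <- argument_text(annotation, fr$args[["A1"]], "A1")
    rows[[length(rows) + 1L]] <- new_triples(
      subject = a0$text, predicate = verb, object = a1$text,
      provenance = "main_plain", sentence_id = sentence_id)
    for (lab in sort(labs[grepl("^AM-", labs)])) {
      at <- argument_text(annotation, fr$args[[lab]], lab)
      if (is.na(at$prep) || !nzchar(at$text)) next
      rows[[length(rows) + 1L]] <- new_triples(
        subject = a0$text,
        predicate = paste(verb, a1$text, at$prep),
        object = at$text,
        provenance = "main_plain", sentence_id = sentence_id)
    }
  }
  if (length(rows) == 0L) return(empty_triples())
  dplyr::bind_rows(rows)
}

# Pre-modifiers (amod/compound dependents to the left) of a token, indices
# restricted to a span; returns 0-based indices sorted by position.
premodifiers <- function(deps, head_idx, span_idx) {
  hits <- deps[deps$head == head_idx & deps$rel %in% PREMOD_RELS &
                 deps$dep < head_idx & deps$dep %in% span_idx, , drop = FALSE]
  sort(hits$dep)
}

noun_phrase_text <- function(ann, head_idx, span_idx) {
  idx <- sort(c(premodifiers(ann$dependencies, head_idx, span_idx), head_idx))
  strip_phrase(detokenize(ann$tokens$surface[idx + 1L]),
               sentence_initial = idx[1] == 0L)
}

#' Extract secondary triples from the dependency parse
#'
#' Two rules over each SRL argument phrase: (a) for every head noun with
#' `k` pre-modifiers (adjectival `amod` / noun `compound` edges), emit `k`
#' `rdfs:subClassOf` triples peeling the leftmost modifier one at a time
#' down to the bare head; (b) for every nominal `X prep Y` construction
#' inside an argument phrase `F`, emit `(F, local:<prep>_<slug(Y)>, X)` and
#' `(F, local:<slug(X)>_<prep>, Y)`. Subjects anchor to main-triple
#' argument texts, which keeps the assembled graph connected.
#'
#' @param annotation A `litkg_annotation` with dependency edges and SRL
#'   frames (the frames supply the argument spans the rules scan).
#' @param main_triples Main triples of the sentence (accepted for contract
#'   symmetry; anchoring uses the same argument texts).
#' @param prepositions Prepositions handled by rule (b).
#' @param sentence_id Source sentence index.
#' @return Triple tibble with provenance `secondary`; subclass rows carry
#'   `modifier` and `modifier_rel` metadata columns.
#' @export
extract_secondary_triples <- function(annotation, main_triples = NULL,
                                      prepositions = DEFAULT_PREPOSITIONS,
                                      sentence_id = 0L) {
  deps <- annotation$dependencies
  frames <- annotation$srl
  if (is.null(deps) || is.null(frames) || length(frames) == 0L) {
    return(empty_triples())
  }
  toks <- annotation$tokens
  spans <- list()
  for (fr in frames) {
    for (lab in order_arg_labels(names(fr$args))) {
      sp <- fr$args[[lab]]
      idx <- (sp[1] + 1L):sp[2]
      tt <- toks[idx, , drop = FALSE]
      # drop a leading preposition on modifier arguments, as the main
      # extraction does, so subjects match the reified objects
      if (grepl("^AM-", lab) && nrow(tt) > 1L && tt$pos[1] %in% c("IN", "TO")) {
        tt <- tt[-1, , drop = FALSE]
      }
      spans[[length(spans) + 1L]] <- list(
        idx = tt$index,
        text = strip_phrase(detokenize(tt$surface),
                            sentence_initial = sp[1] == 0L && tt$index[1] == sp[1])
      )
    }
  }

  rows <- list()
  add <- function(s, p, o, pkind, okind = "literal", modifier = NA_character_,
                  modifier_rel = NA_character_) {
    tr <- new_triples(subject = s, predicate = p, object = o,
                      predicate_kind = pkind, object_kind = okind,
                      provenance = "secondary", sentence_id = sentence_id)
    tr$modifier <- modifier
    tr$modifier_rel <- modifier_rel
    rows[[length(rows) + 1L]] <<- tr
  }

  for (sp in spans) {
    span_idx <- sp$idx
    # (a) modifier peel chains
    nouns <- toks$index[toks$index %in% span_idx & grepl("^NN", toks$pos)]
    for (h in nouns) {
      mods <- premodifiers(deps, h, span_idx)
      k <- length(mods)
      if (k == 0L) next
      for (i in seq_len(k)) {
        sub_idx <- sort(c(mods[i:k], h))
        obj_idx <- if (i < k) sort(c(mods[(i + 1L):k], h)) else h
        subj <- strip_phrase(detokenize(toks$surface[sub_idx + 1L]),
                             sentence_initial = sub_idx[1] == 0L)
        obj <- strip_phrase(detokenize(toks$surface[obj_idx + 1L]),
                            sentence_initial = FALSE)
        add(subj, "rdfs:subClassOf", obj, pkind = "builtin_uri",
            modifier = toks$surface[mods[i] + 1L],
            modifier_rel = deps$rel[deps$head == h & deps$dep == mods[i]][1])
      }
    }
    # (b) prepositional modification: X prep Y inside the argument phrase
    nmods <- deps[grepl("^nmod", deps$rel) & deps$head %in% span_idx &
                    deps$dep %in% span_idx, , drop = FALSE]
    if (nrow(nmods) > 0L) {
      for (r in seq_len(nrow(nmods))) {
        h <- nmods$head[r]
        d <- nmods$dep[r]
        case_edge <- deps[deps$rel == "case" & deps$head == d, , drop = FALSE]
        if (nrow(case_edge) == 0L) next
        p <- tolower(toks$surface[case_edge$dep[1] + 1L])
        if (!(p %in% prepositions) || !(case_edge$dep[1] %in% span_idx)) next
        x_txt <- noun_phrase_text(annotation, h, span_idx)
        y_txt <- noun_phrase_text(annotation, d, span_idx)
        if (!nzchar(x_txt) || !nzchar(y_txt)) next
        add(sp$text, paste0("local:", p, "_", slugify(y_txt)), x_txt,
            pkind = "local_uri")
        add(sp$text, paste0("local:", slugify(x_txt), "_", p), y_txt,
            pkind = "local_uri")
      }
    }
  }

  if (length(rows) == 0L) return(empty_triples())
  out <- dplyr::bind_rows(rows)
  dplyr::distinct(out, .data$subject, .data$predicate, .data$object,
                  .keep_all = TRUE)
}

#' Represent peeled modifiers as explicit triples
#'
#' For every subclass peel step that removed a modifier `m` from phrase
#' `P`, emits `(P, local:hasAdjective, m)` when the modifier was
#' adjectival and `(P, local:hasCompound, m)` when it was a noun compound.
#' Flag-gated enrichment of the secondary triples.
#'
#' @param secondary_triples Tibble from [extract_secondary_triples()].
#' @return Triple tibble (provenance `secondary`).
#' @export
emit_modifier_term_triples <- function(secondary_triples) {
  if (nrow(secondary_triples) == 0L ||
      !("modifier" %in% names(secondary_triples))) {
    return(empty_triples())
  }
  peel <- secondary_triples[secondary_triples$predicate == "rdfs:subClassOf" &
                              !is.na(secondary_triples$modifier), , drop = FALSE]
  if (nrow(peel) == 0L) return(empty_triples())
  new_triples(
    subject = peel$subject,
    predicate = ifelse(peel$modifier_rel == "amod",
                       "local:hasAdjective", "local:hasCompound"),
    object = tolower(peel$modifier),
    predicate_kind = "local_uri",
    provenance = "secondary",
    sentence_id = peel$sentence_id
  )
}

#' Extract all triples for one annotated sentence
#'
#' Convenience wrapper: reified (or plain) main triples plus secondary
#' triples, optionally with modifier-term triples.
#'
#' @inheritParams extract_main_triples
#' @param reify Use the reified form (verb as subject, role URIs as
#'   predicates); otherwise plain subject-verb-object triples.
#' @param modifier_terms Also emit `local:hasAdjective`/`local:hasCompound`
#'   triples for peeled modifiers.
#' @param prepositions Prepositions for the secondary prepositional rule.
#' @return Triple tibble.
#' @export
extract_triples <- function(annotation, inventory = default_rolesets(),
                            reify = TRUE, modifier_terms = FALSE,
                            prepositions = DEFAULT_PREPOSITIONS,
                            sentence_id = 0L) {
  main <- if (reify) {
    extract_main_triples(annotation, inventory, sentence_id)
  } else {
    extract_main_triples_plain(annotation, inventory, sentence_id)
  }
  secondary <- extract_secondary_triples(annotation, main, prepositions,
                                         sentence_id)
  out <- dplyr::bind_rows(main, secondary)
  if (modifier_terms) out <- dplyr::bind_rows(out, emit_modifier_term_triples(secondary))
  out
}
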