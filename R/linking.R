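# Ontology linking: entity mentions and verb lemmas -> UMLS CUIs -> classes
# of a target ontology annotated with those CUIs. The target ontology is a
# local RDF (Turtle) file scanned as a triple store; for live SPARQL
# endpoints the same query can be produced with sparql_cui_query() and
# executed by a caller-supplied function.

#' Collect link candidates from annotated sentences
#'
#' Deduplicated union of entity-mention surfaces and verb lemmas (tokens
#' with a `VB*` tag), preserving first-occurrence order across sentences.
#'
#' @param annotations List of `litkg_annotation` objects (with entities
#'   and PoS tags).
#' @return Character vector of candidate terms.
#' @export
extract_link_candidates <- function(annotations) {
  if (inherits(annotations, "litkg_annotation")) annotations <- list(annotations)
  seen <- character(0)
  out <- character(0)
  for (ann in annotations) {
    pos_terms <- list()
    if (!is.null(ann$entities) && nrow(ann$entities) > 0L) {
      for (i in seq_len(nrow(ann$entities))) {
        pos_terms[[length(pos_terms) + 1L]] <-
          c(ann$entities$start[i], ann$entities$surface[i])
      }
    }
    verbs <- ann$tokens[grepl("^VB", ann$tokens$pos), , drop = FALSE]
    if (nrow(verbs) > 0L) {
      for (i in seq_len(nrow(verbs))) {
        pos_terms[[length(pos_terms) + 1L]] <-
          c(verbs$index[i], verbs$lemma[i])
      }
    }
    if (length(pos_terms) == 0L) next
    ord <- order(as.integer(vapply(pos_terms, `[[`, character(1), 1L)))
    for (k in ord) {
      term <- pos_terms[[k]][[2]]
      key <- tolower(term)
      if (key %in% seen) next
      seen <- c(seen, key)
      out <- c(out, term)
    }
  }
  out
}

#' Read a CUI lexicon
#'
#' TSV with columns `term`, `cui`, `description`, `score`. The packaged
#' fixture (`synthetic_cui_lexicon.tsv`) is a synthetic stand-in for a
#' biomedical NER model's UMLS vocabulary, sized for the worked examples.
#'
#' @param path Path to the TSV file.
#' @return Tibble with those columns.
#' @export
read_cui_lexicon <- function(path) {
  if (!file.exists(path)) {
    abort_litkg(paste("CUI lexicon not found:", path), "litkg_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L && startsWith(lines[1], "term\t")) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0L) {
    abort_litkg(paste0("lexicon line ", bad[1], " does not have 4 fields"),
                "litkg_parse_error")
  }
  tibble::tibble(
    term = vapply(parts, `[[`, character(1), 1L),
    cui = vapply(parts, `[[`, character(1), 2L),
    description = vapply(parts, `[[`, character(1), 3L),
    score = as.numeric(vapply(parts, `[[`, character(1), 4L))
  )
}

#' Default packaged CUI lexicon (synthetic fixture)
#' @return Tibble as from [read_cui_lexicon()].
#' @export
default_cui_lexicon <- function() {
  read_cui_lexicon(system.file("extdata", "synthetic_cui_lexicon.tsv",
                               package = "litkg"))
}

#' Map candidate terms to UMLS concepts
#'
#' Each candidate either receives its top-scoring CUI from the lexicon
#' (score ties broken by lexicographic CUI order) or lands in the
#' unmatched list; the two outputs partition the candidates.
#'
#' @param candidates Character vector of terms.
#' @param lexicon Tibble from [read_cui_lexicon()].
#' @return List with `mappings` (tibble: surface, cui, description, score)
#'   and `unmatched` (character vector).
#' @export
map_to_umls <- function(candidates, lexicon = default_cui_lexicon()) {
  mapped <- list()
  unmatched <- character(0)
  lex_key <- tolower(lexicon$term)
  for (cand in candidates) {
    hits <- lexicon[lex_key == tolower(cand), , drop = FALSE]
    if (nrow(hits) == 0L) {
      unmatched <- c(unmatched, cand)
      next
    }
    hits <- hits[order(-hits$score, hits$cui), , drop = FALSE]
    mapped[[length(mapped) + 1L]] <- tibble::tibble(
      surface = cand, cui = hits$cui[1],
      description = hits$description[1], score = hits$score[1])
  }
  mappings <- if (length(mapped) > 0L) dplyr::bind_rows(mapped) else
    tibble::tibble(surface = character(), cui = character(),
                   description = character(), score = numeric())
  list(mappings = mappings, unmatched = unmatched)
}

#' Load a target ontology from a Turtle file
#'
#' @param path Path to a Turtle file whose classes carry UMLS CUI values
#'   on an annotation property.
#' @return A `litkg_store`: list with `triples` and `namespaces`.
#' @export
read_ontology <- function(path) {
  parsed <- parse_turtle(path, is_file = TRUE)
  structure(parsed, class = "litkg_store")
}

#' Packaged synthetic mini ontology
#' @return A `litkg_store` for the packaged synthetic fixture ontology.
#' @export
synthetic_mini_ontology <- function() {
  read_ontology(system.file("extdata", "synthetic_mini_ontology.ttl",
                            package = "litkg"))
}

expand_prefixed <- function(value, namespaces) {
  if (grepl(PREFIXED_RX, value)) {
    pfx <- sub(":.*$", "", value)
    if (pfx %in% names(namespaces)) {
      return(paste0(namespaces[[pfx]], sub("^[^:]*:", "", value)))
    }
  }
  value
}

#' SPARQL query text mapping a UMLS CUI to ontology classes
#'
#' The SELECT query a live endpoint would receive; offline, the same
#' semantics are evaluated by [map_cui_to_ontology()] over a local store.
#'
#' @param cui UMLS Concept Unique Identifier (e.g. `"C0338656"`).
#' @param cui_property Full IRI of the annotation property carrying CUIs.
#' @return Length-one character string with the query.
#' @export
sparql_cui_query <- function(cui, cui_property) {
  paste0(
    "SELECT DISTINCT ?class WHERE {\n",
    "  ?class <", cui_property, "> ?cui .\n",
    "  FILTER (str(?cui) = \"", cui, "\")\n",
    "} ORDER BY ?class"
  )
}

#' Map a UMLS CUI to target-ontology classes
#'
#' Returns all class IRIs whose `cui_property` value equals the CUI,
#' sorted lexicographically; empty when the CUI is not annotated on any
#' class. With a function as `ontology`, it is called with the SPARQL
#' query text and must return class IRIs (live-endpoint adapter).
#'
#' @param cui UMLS CUI.
#' @param ontology A `litkg_store` from [read_ontology()], or a function
#'   executing SPARQL against an endpoint.
#' @param cui_property IRI (full or prefixed in the store's namespaces) of
#'   the CUI annotation property; mandatory configuration.
#' @return Character vector of class IRIs (full IRIs, sorted).
#' @export
map_cui_to_ontology <- function(cui, ontology, cui_property) {
  if (missing(cui_property) || is.null(cui_property) || !nzchar(cui_property)) {
    abort_litkg("cui_property must be configured", "litkg_invalid_input")
  }
  if (is.function(ontology)) {
    return(sort(ontology(sparql_cui_query(cui, cui_property))))
  }
  if (!inherits(ontology, "litkg_store")) {
    abort_litkg("ontology must be a litkg_store or an endpoint function",
                "litkg_invalid_input")
  }
  ns <- ontology$namespaces
  want <- expand_prefixed(cui_property, ns)
  tr <- ontology$triples
  pred_full <- vapply(tr$predicate, expand_prefixed, character(1),
                      namespaces = ns)
  hits <- tr$subject[pred_full == want & tr$object == cui &
                       tr$object_kind == "literal"]
  sort(unique(vapply(hits, expand_prefixed, character(1), namespaces = ns)))
}

class_label <- function(class_iri, ontology) {
  ns <- ontology$namespaces
  tr <- ontology$triples
  subj_full <- vapply(tr$subject, expand_prefixed, character(1), namespaces = ns)
  lab <- tr$object[subj_full == class_iri & tr$predicate %in%
                     c("rdfs:label", "http://www.w3.org/2000/01/rdf-schema#label")]
  if (length(lab) == 0L) NA_character_ else lab[1]
}

#' Link annotated sentences to a target ontology
#'
#' Runs the whole linking chain: candidates -> UMLS CUIs -> ontology
#' classes, and builds the link table and funnel report.
#'
#' @param annotations List of `litkg_annotation` objects.
#' @param lexicon CUI lexicon tibble.
#' @param ontology A `litkg_store`.
#' @param cui_property CUI annotation property IRI.
#' @param source Label recorded in the link table's `source` column.
#' @return List with `candidates`, `mappings`, `unmatched`, `links`
#'   (tibble: surface, cui, class_iri, label, source) and `report`
#'   (a `litkg_link_report`).
#' @export
link_terms <- function(annotations, lexicon = default_cui_lexicon(),
                       ontology = synthetic_mini_ontology(),
                       cui_property, source = "umls_sparql") {
  candidates <- extract_link_candidates(annotations)
  um <- map_to_umls(candidates, lexicon)
  rows <- list()
  for (i in seq_len(nrow(um$mappings))) {
    iris <- map_cui_to_ontology(um$mappings$cui[i], ontology, cui_property)
    for (iri in iris) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        surface = um$mappings$surface[i], cui = um$mappings$cui[i],
        class_iri = iri, label = class_label(iri, ontology),
        source = source)
    }
  }
  links <- if (length(rows) > 0L) {
    dplyr::distinct(dplyr::bind_rows(rows), .data$surface, .data$class_iri,
                    .keep_all = TRUE)
  } else {
    empty_links()
  }
  list(candidates = candidates, mappings = um$mappings,
       unmatched = um$unmatched, links = links,
       report = build_link_report(candidates, um$mappings, links))
}

empty_links <- function() {
  tibble::tibble(surface = character(), cui = character(),
                 class_iri = character(), label = character(),
                 source = character())
}

#' Union of two ontology link sets
#'
#' Deduplicates on `(surface, class_iri)`; merged members get source
#' `"combined"`. The union is never smaller than either input, which is
#' what makes combining a direct-annotator link source with the UMLS
#' route worthwhile.
#'
#' @param primary,fallback Link tibbles targeting the same ontology.
#' @return Combined link tibble.
#' @export
combine_link_sets <- function(primary, fallback) {
  ont_a <- attr(primary, "ontology")
  ont_b <- attr(fallback, "ontology")
  if (!is.null(ont_a) && !is.null(ont_b) && !identical(ont_a, ont_b)) {
    abort_litkg("link sets target different ontologies",
                "litkg_invalid_combination")
  }
  out <- dplyr::bind_rows(primary, fallback)
  out <- dplyr::distinct(out, .data$surface, .data$class_iri, .keep_all = TRUE)
  out$source <- "combined"
  attr(out, "ontology") <- ont_a %||% ont_b
  out
}

#' Funnel report of the linking chain
#'
#' Terms identified, UMLS CUIs found for them, and terms that obtained at
#' least one target-ontology link. The funnel is monotone:
#' `ontology_links <= cuis_found <= terms_identified`.
#'
#' @param candidates Candidate terms.
#' @param mappings UMLS mappings tibble.
#' @param links Link tibble.
#' @return A `litkg_link_report` (one-row tibble).
#' @export
build_link_report <- function(candidates, mappings, links) {
  report <- tibble::tibble(
    terms_identified = length(candidates),
    cuis_found = nrow(mappings),
    ontology_links = length(unique(links$surface))
  )
  if (report$ontology_links > report$cuis_found ||
      report$cuis_found > report$terms_identified) {
    abort_litkg("link report violates the funnel invariant",
                "litkg_invalid_input")
  }
  class(report) <- c("litkg_link_report", class(report))
  report
}

#' Write / read the link table intermediate
#'
#' Human-editable TSV (`surface`, `cui`, `class_iri`, `label`, `source`).
#'
#' @param links Link tibble.
#' @param path File path.
#' @return `read_links_tsv()` returns the link tibble.
#' @export
write_links_tsv <- function(links, path) {
  header <- "surface\tcui\tclass_iri\tlabel\tsource"
  rows <- if (nrow(links) == 0L) character(0) else
    paste(links$surface, links$cui, links$class_iri, links$label,
          links$source, sep = "\t")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_links_tsv
#' @export
read_links_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[1], "surface\t")) {
    abort_litkg("links TSV missing header", "litkg_parse_error")
  }
  lines <- lines[-1]
  if (length(lines) == 0L) return(empty_links())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad) > 0L) {
    abort_litkg(paste0("links TSV line ", bad[1] + 1L,
                       " does not have 5 fields"), "litkg_parse_error")
  }
  tibble::tibble(
    surface = vapply(parts, `[[`, character(1), 1L),
    cui = vapply(parts, `[[`, character(1), 2L),
    class_iri = vapply(parts, `[[`, character(1), 3L),
    label = vapply(parts, `[[`, character(1), 4L),
    source = vapply(parts, `[[`, character(1), 5L)
  )
}
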