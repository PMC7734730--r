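# Graph assembly: local URI minting, rdfs:label / owl:sameAs enrichment,
# Turtle serialization and parsing (a documented Turtle subset, since the
# graphs the pipeline builds only need prefixed names, IRIs and plain
# literals), and DOT export.

#' Default namespace table
#'
#' Prefix -> IRI map used by the assembled graphs. `role:` and `vn.role:`
#' are bound to the same IRI (the two spellings are interchangeable for
#' roleset-derived predicates). The local and role IRIs are package
#' defaults and fully configurable.
#'
#' @param ... Named additional prefixes (e.g. the target-ontology prefix).
#' @return Named character vector of namespace IRIs.
#' @export
default_namespaces <- function(...) {
  base <- c(
    local = "http://example.org/kg/local#",
    role = "http://example.org/kg/role#",
    vn.role = "http://example.org/kg/role#",
    rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    owl = "http://www.w3.org/2002/07/owl#",
    umls = "http://linkedlifedata.com/resource/umls/id/"
  )
  extra <- c(...)
  if (length(extra) > 0L) base[names(extra)] <- extra
  base
}

#' Mint a deterministic local URI for a phrase
#'
#' Normalization (case-fold + whitespace-collapse) happens before minting,
#' so the same phrase always maps to the same IRI and local URIs are
#' reused across triples — which is what connects the assembled graph.
#' The IRI local name is the phrase slug (lower-case alphanumerics).
#'
#' @param phrase Literal phrase text.
#' @param registry An environment used as the phrase -> IRI registry
#'   (create with `new.env()`); the original phrase is kept as the label.
#' @return The prefixed local IRI, e.g. `"local:highprevalence"`.
#' @export
mint_local_uri <- function(phrase, registry) {
  norm <- stringr::str_squish(tolower(phrase))
  slug <- slugify(norm)
  if (!nzchar(slug)) {
    abort_litkg(paste0("phrase normalizes to an empty slug: '", phrase, "'"),
                "litkg_invalid_phrase")
  }
  iri <- paste0("local:", slug)
  if (!exists(norm, envir = registry, inherits = FALSE)) {
    assign(norm, list(iri = iri, label = phrase), envir = registry)
    order <- get0(".order", envir = registry, ifnotfound = character(0))
    assign(".order", c(order, norm), envir = registry)
  }
  iri
}

registry_table <- function(registry) {
  keys <- get0(".order", envir = registry, ifnotfound = character(0))
  tibble::tibble(
    phrase = vapply(keys, function(k) get(k, envir = registry)$label, character(1)),
    norm = keys,
    iri = vapply(keys, function(k) get(k, envir = registry)$iri, character(1))
  )
}

#' Assemble an ontology-linked knowledge graph from triples
#'
#' Every literal subject, predicate and object of the extracted triples is
#' replaced by a deterministic local URI; each minted URI gets exactly one
#' `rdfs:label` triple carrying the original phrase; and each ontology
#' link whose surface matches a registered phrase adds an `owl:sameAs`
#' triple to the target-ontology class (and to the intermediate UMLS
#' concept when a CUI is present). Linking is optional: with no links a
#' graph is still assembled.
#'
#' @param triples Triple tibble from the extraction step.
#' @param links Optional link tibble (`surface`, `cui`, `class_iri`,
#'   `label`, `source`).
#' @param namespaces Namespace table, see [default_namespaces()].
#' @param umls_links Also add `owl:sameAs` triples to `umls:` CUIs.
#' @return A `litkg_graph`: list with `triples`, `namespaces`, `registry`.
#' @export
enrich <- function(triples, links = NULL,
                   namespaces = default_namespaces(), umls_links = TRUE) {
  registry <- new.env(parent = emptyenv())
  tr <- triples[, c("subject", "subject_kind", "predicate", "predicate_kind",
                    "object", "object_kind", "provenance", "sentence_id")]
  if (nrow(tr) > 0L) {
    for (i in seq_len(nrow(tr))) {
      if (tr$subject_kind[i] == "literal") {
        tr$subject[i] <- mint_local_uri(tr$subject[i], registry)
        tr$subject_kind[i] <- "local_uri"
      }
      if (tr$predicate_kind[i] == "literal") {
        tr$predicate[i] <- mint_local_uri(tr$predicate[i], registry)
        tr$predicate_kind[i] <- "local_uri"
      }
      if (tr$object_kind[i] == "literal") {
        tr$object[i] <- mint_local_uri(tr$object[i], registry)
        tr$object_kind[i] <- "local_uri"
      }
    }
  }
  reg <- registry_table(registry)
  labels <- if (nrow(reg) > 0L) {
    new_triples(subject = reg$iri, predicate = "rdfs:label",
                object = reg$phrase,
                subject_kind = "local_uri", predicate_kind = "builtin_uri",
                object_kind = "literal", provenance = "enrichment",
                sentence_id = NA_integer_)
  } else empty_triples()

  link_rows <- empty_triples()
  if (!is.null(links) && nrow(links) > 0L && nrow(reg) > 0L) {
    pieces <- list()
    for (i in seq_len(nrow(links))) {
      norm <- stringr::str_squish(tolower(links$surface[i]))
      hit <- reg$iri[reg$norm == norm]
      if (length(hit) == 0L) next
      pieces[[length(pieces) + 1L]] <- new_triples(
        subject = hit[1], predicate = "owl:sameAs",
        object = links$class_iri[i],
        subject_kind = "local_uri", predicate_kind = "builtin_uri",
        object_kind = "external_uri", provenance = "link",
        sentence_id = NA_integer_)
      if (umls_links && !is.na(links$cui[i]) && nzchar(links$cui[i])) {
        pieces[[length(pieces) + 1L]] <- new_triples(
          subject = hit[1], predicate = "owl:sameAs",
          object = paste0("umls:", links$cui[i]),
          subject_kind = "local_uri", predicate_kind = "builtin_uri",
          object_kind = "external_uri", provenance = "link",
          sentence_id = NA_integer_)
      }
    }
    if (length(pieces) > 0L) {
      link_rows <- dplyr::distinct(
        dplyr::bind_rows(pieces),
        .data$subject, .data$predicate, .data$object, .keep_all = TRUE)
    }
  }

  structure(
    list(triples = dplyr::bind_rows(tr, labels, link_rows),
         namespaces = namespaces,
         registry = reg),
    class = "litkg_graph"
  )
}

#' @export
print.litkg_graph <- function(x, ...) {
  cat("<litkg_graph> ", nrow(x$triples), " triples, ",
      nrow(x$registry), " local URIs, ",
      length(x$namespaces), " namespaces\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Triples of a knowledge graph as a tibble
#' @param x A `litkg_graph`.
#' @param ... Unused.
#' @return The triple tibble.
#' @method tidy litkg_graph
#' @export
tidy.litkg_graph <- function(x, ...) x$triples

#' One-row summary of a knowledge graph
#' @param x A `litkg_graph`.
#' @param ... Unused.
#' @return Tibble with triple, node and provenance counts.
#' @method glance litkg_graph
#' @export
glance.litkg_graph <- function(x, ...) {
  tr <- x$triples
  tibble::tibble(
    n_triples = nrow(tr),
    n_nodes = length(unique(c(tr$subject, tr$object))),
    n_local_uris = nrow(x$registry),
    n_labels = sum(tr$predicate == "rdfs:label"),
    n_links = sum(tr$provenance == "link")
  )
}

# ---- Turtle ------------------------------------------------------------------

PREFIXED_RX <- "^[A-Za-z][A-Za-z0-9._-]*:[A-Za-z0-9][A-Za-z0-9._-]*$"

escape_turtle <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_turtle <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    res <- ""
    j <- 1L
    n <- nchar(s)
    while (j <= n) {
      ch <- substr(s, j, j)
      if (ch == "\\" && j < n) {
        nxt <- substr(s, j + 1L, j + 1L)
        res <- paste0(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                                  "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        res <- paste0(res, ch)
        j <- j + 1L
      }
    }
    out[i] <- res
  }
  out
}

render_term <- function(value, kind, namespaces) {
  if (kind == "literal") return(paste0("\"", escape_turtle(value), "\""))
  if (grepl(PREFIXED_RX, value)) {
    pfx <- sub(":.*$", "", value)
    if (pfx %in% names(namespaces)) return(value)
  }
  paste0("<", value, ">")
}

#' Serialize a knowledge graph to Turtle
#'
#' Emits one statement per triple with `@prefix` declarations for exactly
#' the namespaces used. Literal subjects or predicates are invalid RDF and
#' raise an error (enrich the triples first).
#'
#' @param kg A `litkg_graph`.
#' @return Length-one character string of Turtle text.
#' @export
serialize_turtle <- function(kg) {
  tr <- kg$triples
  if (nrow(tr) > 0L &&
      (any(tr$subject_kind == "literal") || any(tr$predicate_kind == "literal"))) {
    abort_litkg("literals in subject or predicate position cannot be serialized",
                "litkg_invalid_input")
  }
  used <- character(0)
  vals <- c(tr$subject, tr$predicate,
            tr$object[tr$object_kind != "literal"])
  for (v in vals) {
    if (grepl(PREFIXED_RX, v)) {
      pfx <- sub(":.*$", "", v)
      if (pfx %in% names(kg$namespaces)) used <- c(used, pfx)
    }
  }
  used <- sort(unique(used))
  header <- vapply(used, function(p) {
    paste0("@prefix ", p, ": <", kg$namespaces[[p]], "> .")
  }, character(1))
  body <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    body[i] <- paste(
      render_term(tr$subject[i], tr$subject_kind[i], kg$namespaces),
      render_term(tr$predicate[i], tr$predicate_kind[i], kg$namespaces),
      render_term(tr$object[i], tr$object_kind[i], kg$namespaces),
      ".")
  }
  paste(c(header, "", body, ""), collapse = "\n")
}

# Tokenizer for the Turtle subset: IRIs, quoted literals, prefixed names,
# keywords and punctuation.
turtle_tokens <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value) tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch == "#") {
      while (i <= n && substr(text, i, i) != "\n") i <- i + 1L
      next
    }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && substr(text, j, j) != ">") j <- j + 1L
      if (j > n) abort_litkg("unterminated IRI", "litkg_parse_error")
      push("iri", substr(text, i + 1L, j - 1L))
      i <- j + 1L
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      buf <- ""
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") { buf <- paste0(buf, substr(text, j, j + 1L)); j <- j + 2L; next }
        if (cj == "\"") break
        buf <- paste0(buf, cj)
        j <- j + 1L
      }
      if (j > n) abort_litkg("unterminated literal", "litkg_parse_error")
      push("literal", unescape_turtle(buf))
      i <- j + 1L
      # optional language tag or datatype
      rest <- substr(text, i, min(n, i + 1L))
      if (startsWith(rest, "@")) {
        j <- i + 1L
        while (j <= n && grepl("[A-Za-z0-9-]", substr(text, j, j))) j <- j + 1L
        i <- j
      } else if (startsWith(rest, "^^")) {
        i <- i + 2L
        if (substr(text, i, i) == "<") {
          j <- i + 1L
          while (j <= n && substr(text, j, j) != ">") j <- j + 1L
          i <- j + 1L
        } else {
          j <- i
          while (j <= n && grepl("[A-Za-z0-9._:-]", substr(text, j, j))) j <- j + 1L
          i <- j
        }
      }
      next
    }
    if (ch %in% c(".", ";", ",")) {
      push(ch, ch)
      i <- i + 1L
      next
    }
    j <- i
    while (j <= n && grepl("[A-Za-z0-9._:@-]", substr(text, j, j))) j <- j + 1L
    word <- substr(text, i, j - 1L)
    if (endsWith(word, ".")) {
      # statement-terminating dot glued to a name
      word <- substr(word, 1L, nchar(word) - 1L)
      if (nzchar(word)) push("name", word)
      push(".", ".")
    } else if (nzchar(word)) {
      push("name", word)
    } else {
      abort_litkg(paste0("unexpected character '", ch, "' in Turtle input"),
                  "litkg_parse_error")
    }
    i <- j
  }
  tokens
}

#' Parse Turtle text into a triple table
#'
#' Supports the subset the serializer emits plus common abbreviations:
#' `@prefix` declarations, prefixed names, full IRIs, plain literals (with
#' escapes; language tags and datatypes are accepted and dropped), the `a`
#' keyword, and `;` / `,` predicate and object lists. Full IRIs are
#' compressed to prefixed names when a declared namespace matches.
#'
#' @param text Turtle text (or a file path when `is_file = TRUE`).
#' @param is_file Treat `text` as a path.
#' @return List with `triples` (tibble: subject, predicate, object plus
#'   coarse kinds `uri`/`literal`) and `namespaces`.
#' @export
parse_turtle <- function(text, is_file = FALSE) {
  if (is_file) {
    if (!file.exists(text)) {
      abort_litkg(paste("Turtle file not found:", text), "litkg_io_error")
    }
    text <- paste(readLines(text, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
  }
  toks <- turtle_tokens(text)
  ns <- character(0)
  compress <- function(iri) {
    if (length(ns) == 0L) return(iri)
    ord <- order(-nchar(ns), names(ns))
    for (k in ord) {
      if (startsWith(iri, ns[[k]]) && nchar(iri) > nchar(ns[[k]])) {
        return(paste0(names(ns)[k], ":", substr(iri, nchar(ns[[k]]) + 1L, nchar(iri))))
      }
    }
    iri
  }
  term_of <- function(tok) {
    if (tok$type == "iri") return(list(value = compress(tok$value), kind = "uri"))
    if (tok$type == "literal") return(list(value = tok$value, kind = "literal"))
    if (tok$type == "name") {
      if (identical(tok$value, "a")) return(list(value = "rdf:type", kind = "uri"))
      return(list(value = tok$value, kind = "uri"))
    }
    abort_litkg(paste0("unexpected token '", tok$value, "'"), "litkg_parse_error")
  }

  subjects <- character(0); predicates <- character(0); objects <- character(0)
  okinds <- character(0)
  i <- 1L
  nt <- length(toks)
  expect <- function(i, type) {
    if (i > nt || toks[[i]]$type != type) {
      abort_litkg(paste0("expected '", type, "' in Turtle input"),
                  "litkg_parse_error")
    }
  }
  while (i <= nt) {
    tok <- toks[[i]]
    if (tok$type == "name" && tok$value %in% c("@prefix", "@PREFIX")) {
      pfx_tok <- toks[[i + 1L]]
      pfx <- sub(":$", "", pfx_tok$value)
      expect(i + 2L, "iri")
      ns[pfx] <- toks[[i + 2L]]$value
      expect(i + 3L, ".")
      i <- i + 4L
      next
    }
    subj <- term_of(tok)
    i <- i + 1L
    repeat {
      pred <- term_of(toks[[i]])
      i <- i + 1L
      repeat {
        obj <- term_of(toks[[i]])
        i <- i + 1L
        subjects <- c(subjects, subj$value)
        predicates <- c(predicates, pred$value)
        objects <- c(objects, obj$value)
        okinds <- c(okinds, obj$kind)
        if (i <= nt && toks[[i]]$type == ",") { i <- i + 1L; next }
        break
      }
      if (i <= nt && toks[[i]]$type == ";") {
        i <- i + 1L
        # tolerate trailing ';' before '.'
        if (i <= nt && toks[[i]]$type == ".") break
        next
      }
      break
    }
    expect(i, ".")
    i <- i + 1L
  }
  list(
    triples = tibble::tibble(
      subject = subjects, subject_kind = "uri",
      predicate = predicates, predicate_kind = "uri",
      object = objects, object_kind = okinds),
    namespaces = ns
  )
}

#' Export a knowledge graph to DOT
#'
#' One node per distinct subject/object term (ellipses for IRIs, boxes for
#' literals) and one labeled edge per triple; the output parses as the DOT
#' graph language.
#'
#' @param kg A `litkg_graph`.
#' @return Length-one character string of DOT text.
#' @export
export_dot <- function(kg) {
  tr <- kg$triples
  esc <- function(x) gsub("\"", "\\\"", x, fixed = TRUE)
  terms <- unique(rbind(
    data.frame(value = tr$subject, kind = tr$subject_kind),
    data.frame(value = tr$object, kind = tr$object_kind)
  ))
  if (nrow(terms) == 0L) return("digraph kg {\n}\n")
  ids <- stats::setNames(paste0("n", seq_len(nrow(terms))), terms$value)
  nodes <- vapply(seq_len(nrow(terms)), function(i) {
    shape <- if (terms$kind[i] == "literal") "box" else "ellipse"
    paste0("  ", ids[[terms$value[i]]], " [label=\"", esc(terms$value[i]),
           "\", shape=", shape, "];")
  }, character(1))
  edges <- vapply(seq_len(nrow(tr)), function(i) {
    paste0("  ", ids[[tr$subject[i]]], " -> ", ids[[tr$object[i]]],
           " [label=\"", esc(tr$predicate[i]), "\"];")
  }, character(1))
  paste(c("digraph kg {", "  rankdir=LR;", nodes, edges, "}", ""),
        collapse = "\n")
}

# Canonical (order-insensitive, coarse-kind) view used for round-trip
# comparisons between a graph and re-parsed Turtle.
canonical_triples <- function(triples) {
  out <- tibble::tibble(
    subject = unname(triples$subject),
    predicate = unname(triples$predicate),
    object = unname(triples$object),
    object_literal = unname(triples$object_kind == "literal")
  )
  out[order(out$subject, out$predicate, out$object), ]
}
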