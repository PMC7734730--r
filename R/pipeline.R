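# End-to-end pipeline: preprocessing -> triple extraction -> (optional)
# ontology linking -> graph assembly. Every stage persists a human-editable
# text intermediate; when an intermediate is newer than its upstream
# artifact the stage is skipped and the (possibly hand-edited) file is
# consumed — the semi-automatic review loop. The pipeline is free of
# randomness: identical configuration and inputs give identical bytes out.

#' Pipeline configuration
#'
#' @param input Path to the input UTF-8 text document.
#' @param out_dir Output directory for intermediates and final artifacts.
#' @param provider Annotation provider (e.g. [replay_provider()]).
#' @param linking Run the ontology-linking stage (optional: a graph is
#'   still generated without it).
#' @param reify Reified main triples (role URIs) vs plain subject-verb-object.
#' @param modifier_terms Emit `hasAdjective`/`hasCompound` triples.
#' @param combine_links Union the UMLS-route links with `annotator_links`.
#' @param annotator_links Optional link tibble from a direct annotator.
#' @param lexicon CUI lexicon tibble (required when `linking = TRUE`).
#' @param ontology A `litkg_store` (required when `linking = TRUE`).
#' @param cui_property CUI annotation property IRI (required when linking).
#' @param chains Coreference chains for preprocessing.
#' @param simplify Run sentence simplification.
#' @param prepositions Preposition list for secondary extraction.
#' @param rolesets Roleset inventory tibble.
#' @param namespaces Namespace table for the graph.
#' @return A `litkg_config` list.
#' @export
pipeline_config <- function(input, out_dir, provider,
                            linking = FALSE, reify = TRUE,
                            modifier_terms = FALSE, combine_links = FALSE,
                            annotator_links = NULL,
                            lexicon = NULL, ontology = NULL,
                            cui_property = NULL,
                            chains = list(), simplify = TRUE,
                            prepositions = DEFAULT_PREPOSITIONS,
                            rolesets = default_rolesets(),
                            namespaces = default_namespaces()) {
  if (!file.exists(input)) {
    abort_litkg(paste("input document not found:", input), "litkg_io_error")
  }
  if (linking && (is.null(lexicon) || is.null(ontology) ||
                  is.null(cui_property))) {
    abort_litkg("linking requires lexicon, ontology and cui_property",
                "litkg_invalid_input")
  }
  structure(
    list(input = input, out_dir = out_dir, provider = provider,
         linking = linking, reify = reify, modifier_terms = modifier_terms,
         combine_links = combine_links, annotator_links = annotator_links,
         lexicon = lexicon, ontology = ontology, cui_property = cui_property,
         chains = chains, simplify = simplify, prepositions = prepositions,
         rolesets = rolesets, namespaces = namespaces),
    class = "litkg_config"
  )
}

pipeline_paths <- function(out_dir) {
  list(
    sentences = file.path(out_dir, "sentences.txt"),
    provenance = file.path(out_dir, "sentences_provenance.json"),
    triples = file.path(out_dir, "triples.tsv"),
    links = file.path(out_dir, "links.tsv"),
    turtle = file.path(out_dir, "graph.ttl"),
    dot = file.path(out_dir, "graph.dot"),
    manifest = file.path(out_dir, "manifest.json")
  )
}

# A stage is skipped when every output exists and is at least as new as
# every input file (so a hand-edited intermediate is consumed, not
# overwritten).
stage_fresh <- function(inputs, outputs) {
  if (!all(file.exists(outputs))) return(FALSE)
  if (length(inputs) == 0L) return(TRUE)
  max(file.mtime(inputs)) <= min(file.mtime(outputs))
}

#' Run the full pipeline
#'
#' Executes preprocessing, triple extraction, optional ontology linking
#' and graph assembly, writing each stage's artifact under
#' `config$out_dir` (sentences + provenance sidecar, triples TSV, links
#' TSV, Turtle, DOT, manifest). Re-running consumes intermediates that
#' are newer than their upstream artifacts instead of recomputing them.
#'
#' @param config A `litkg_config` from [pipeline_config()].
#' @return The run manifest (list, class `litkg_manifest`) with per-stage
#'   status, artifact digests, warnings and a config snapshot.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- pipeline_paths(config$out_dir)
  stages <- list()
  run_stage <- function(name, inputs, outputs, fn) {
    warnings <- character(0)
    if (stage_fresh(inputs, outputs)) {
      status <- "skipped"
    } else {
      withCallingHandlers(
        tryCatch(fn(), error = function(e) {
          abort_litkg(paste0("stage '", name, "' failed: ",
                             conditionMessage(e)),
                      "litkg_stage_error", parent = e)
        }),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      status <- "run"
    }
    stages[[name]] <<- list(
      status = status,
      inputs = as.list(inputs),
      outputs = as.list(outputs),
      digests = as.list(vapply(outputs, function(f) {
        if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
      }, character(1))),
      warnings = as.list(warnings))
  }

  run_stage("preprocess", config$input, c(p$sentences, p$provenance), function() {
    doc <- paste(readLines(config$input, encoding = "UTF-8", warn = FALSE),
                 collapse = " ")
    pre <- preprocess_document(doc, config$provider, chains = config$chains,
                               simplify = config$simplify)
    writeLines(pre$sentence, p$sentences, useBytes = TRUE)
    jsonlite::write_json(
      lapply(seq_len(nrow(pre)), function(i) {
        list(sentence = pre$sentence[i], source = pre$source[i],
             transforms = as.list(pre$transforms[[i]]))
      }),
      p$provenance, auto_unbox = TRUE)
  })

  run_stage("extract", p$sentences, p$triples, function() {
    sentences <- readLines(p$sentences, encoding = "UTF-8")
    sentences <- sentences[nzchar(stringr::str_squish(sentences))]
    all_triples <- empty_triples()
    for (i in seq_along(sentences)) {
      ann <- analyze_sentence(config$provider, sentences[i],
                              c("tokens", "dependency", "srl"))
      tr <- extract_triples(ann, inventory = config$rolesets,
                            reify = config$reify,
                            modifier_terms = config$modifier_terms,
                            prepositions = config$prepositions,
                            sentence_id = i)
      all_triples <- dplyr::bind_rows(all_triples, tr)
    }
    write_triples_tsv(all_triples, p$triples)
  })

  if (config$linking) {
    run_stage("link", p$sentences, p$links, function() {
      sentences <- readLines(p$sentences, encoding = "UTF-8")
      sentences <- sentences[nzchar(stringr::str_squish(sentences))]
      anns <- lapply(sentences, function(s) {
        analyze_sentence(config$provider, s, c("tokens", "entities"))
      })
      res <- link_terms(anns, lexicon = config$lexicon,
                        ontology = config$ontology,
                        cui_property = config$cui_property)
      links <- res$links
      if (config$combine_links && !is.null(config$annotator_links)) {
        links <- combine_link_sets(links, config$annotator_links)
      }
      write_links_tsv(links, p$links)
    })
  }

  graph_inputs <- if (config$linking) c(p$triples, p$links) else p$triples
  run_stage("graph", graph_inputs, c(p$turtle, p$dot), function() {
    triples <- read_triples_tsv(p$triples)
    links <- if (config$linking) read_links_tsv(p$links) else NULL
    kg <- enrich(triples, links = links, namespaces = config$namespaces)
    writeLines(serialize_turtle(kg), p$turtle, useBytes = TRUE, sep = "")
    writeLines(export_dot(kg), p$dot, useBytes = TRUE, sep = "")
  })

  manifest <- structure(
    list(
      tool = paste0("litkg ", as.character(utils::packageVersion("litkg"))),
      stages = stages,
      config = list(
        input = config$input, out_dir = config$out_dir,
        linking = config$linking, reify = config$reify,
        modifier_terms = config$modifier_terms,
        combine_links = config$combine_links,
        simplify = config$simplify,
        prepositions = as.list(config$prepositions),
        cui_property = config$cui_property)
    ),
    class = "litkg_manifest")
  jsonlite::write_json(unclass(manifest), p$manifest, auto_unbox = TRUE)
  invisible(manifest)
}

#' @export
print.litkg_manifest <- function(x, ...) {
  cat("<litkg_manifest>\n")
  for (nm in names(x$stages)) {
    cat("  ", nm, ": ", x$stages[[nm]]$status, "\n", sep = "")
  }
  invisible(x)
}

# ---- triple TSV intermediate -------------------------------------------------

TRIPLE_TSV_COLS <- c("subject", "subject_kind", "predicate", "predicate_kind",
                     "object", "object_kind", "provenance", "sentence_id")

#' Write / read the triples intermediate
#'
#' One triple per line, tab-separated, with kind markers and provenance —
#' human-editable and re-ingestible.
#'
#' @param triples Triple tibble.
#' @param path File path.
#' @return `read_triples_tsv()` returns the triple tibble.
#' @export
write_triples_tsv <- function(triples, path) {
  header <- paste(TRIPLE_TSV_COLS, collapse = "\t")
  rows <- if (nrow(triples) == 0L) character(0) else
    vapply(seq_len(nrow(triples)), function(i) {
      paste(triples$subject[i], triples$subject_kind[i], triples$predicate[i],
            triples$predicate_kind[i], triples$object[i],
            triples$object_kind[i], triples$provenance[i],
            triples$sentence_id[i], sep = "\t")
    }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_triples_tsv
#' @export
read_triples_tsv <- function(path) {
  if (!file.exists(path)) {
    abort_litkg(paste("triples TSV not found:", path), "litkg_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[1], "subject\t")) {
    abort_litkg("triples TSV missing header", "litkg_parse_error")
  }
  lines <- lines[-1]
  if (length(lines) == 0L) return(empty_triples())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(TRIPLE_TSV_COLS))
  if (length(bad) > 0L) {
    abort_litkg(paste0("triples TSV parse error at line ", bad[1] + 1L,
                       ": expected ", length(TRIPLE_TSV_COLS), " fields"),
                "litkg_parse_error")
  }
  new_triples(
    subject = vapply(parts, `[[`, character(1), 1L),
    subject_kind = vapply(parts, `[[`, character(1), 2L),
    predicate = vapply(parts, `[[`, character(1), 3L),
    predicate_kind = vapply(parts, `[[`, character(1), 4L),
    object = vapply(parts, `[[`, character(1), 5L),
    object_kind = vapply(parts, `[[`, character(1), 6L),
    provenance = vapply(parts, `[[`, character(1), 7L),
    sentence_id = as.integer(vapply(parts, `[[`, character(1), 8L))
  )
}
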