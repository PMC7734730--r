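# Annotation provider contract.
#
# Every linguistic analysis the pipeline consumes (tokens, constituency and
# dependency parses, semantic role labeling frames, entity mentions) comes
# through one generic, analyze_sentence(). The package ships a deterministic
# replay provider that answers from a JSON fixture; a live provider is any
# object with an analyze_sentence() method returning annotations built with
# new_annotation(). Downstream stages depend only on this contract.
#
# Conventions: token indices are 0-based; spans are half-open [start, end);
# the root dependency edge uses head = -1.

ANALYSIS_KINDS <- c("tokens", "constituency", "dependency", "srl", "entities")

#' Construct a sentence annotation
#'
#' Bundles the per-sentence linguistic analyses into a validated object.
#' Token indices are 0-based and spans half-open. Any component other than
#' `tokens` may be `NULL`, meaning the analysis is not available.
#'
#' @param tokens Tibble with columns `index` (0-based integer), `surface`,
#'   `pos` (Penn-style tag) and `lemma`.
#' @param constituency Root constituency node as returned by
#'   [build_constituency()], or `NULL`.
#' @param dependencies Tibble with integer columns `head`, `dep` and character
#'   `rel`; exactly one edge must have `rel == "root"` (with `head = -1`).
#' @param srl List of frames; each frame is a list with `predicate` (0-based
#'   token index), `lemma`, and `args`, a named list of `c(start, end)` spans
#'   keyed by PropBank-style labels (`A0`, `A1`, `AM-LOC`, ...).
#' @param entities Tibble with columns `start`, `end`, `surface` and a
#'   list-column `cuis` of tibbles (`cui`, `score`, scores non-increasing).
#' @param sentence The sentence text the annotation describes.
#' @return An object of class `litkg_annotation`.
#' @export
new_annotation <- function(tokens,
                           constituency = NULL,
                           dependencies = NULL,
                           srl = NULL,
                           entities = NULL,
                           sentence = NULL) {
  ann <- structure(
    list(
      sentence = sentence,
      tokens = tokens,
      constituency = constituency,
      dependencies = dependencies,
      srl = srl,
      entities = entities
    ),
    class = "litkg_annotation"
  )
  validate_annotation(ann)
  ann
}

#' @export
print.litkg_annotation <- function(x, ...) {
  kinds <- ANALYSIS_KINDS[!vapply(x[ANALYSIS_KINDS], is.null, logical(1))]
  cat("<litkg_annotation> ", nrow(x$tokens), " tokens; analyses: ",
      paste(kinds, collapse = ", "), "\n", sep = "")
  invisible(x)
}

validate_annotation <- function(ann, key = NULL) {
  where <- if (is.null(key)) "" else paste0(" (sentence: ", key, ")")
  fail <- function(msg) abort_litkg(paste0(msg, where), "litkg_schema_error")

  tk <- ann$tokens
  if (is.null(tk) || !all(c("index", "surface", "pos", "lemma") %in% names(tk))) {
    fail("tokens must have columns index, surface, pos, lemma")
  }
  n <- nrow(tk)
  if (n == 0L) fail("annotation has no tokens")
  if (!identical(as.integer(tk$index), 0:(n - 1L))) {
    fail("token indices must be 0-based and contiguous")
  }
  if (any(!nzchar(tk$surface))) fail("token surfaces must be non-empty")

  check_span <- function(span, what) {
    if (length(span) != 2L || anyNA(span)) fail(paste(what, "span malformed"))
    if (!(span[1] >= 0 && span[1] < span[2] && span[2] <= n)) {
      fail(paste0(what, " span [", span[1], ",", span[2],
                  ") outside 0 <= start < end <= ", n))
    }
  }

  if (!is.null(ann$dependencies)) {
    dp <- ann$dependencies
    if (!all(c("head", "dep", "rel") %in% names(dp))) {
      fail("dependencies must have columns head, dep, rel")
    }
    if (any(dp$head == dp$dep)) fail("dependency edge with head == dependent")
    if (sum(dp$rel == "root") != 1L) fail("exactly one root dependency required")
    idx_ok <- dp$dep >= 0 & dp$dep < n & (dp$head == -1L | (dp$head >= 0 & dp$head < n))
    if (!all(idx_ok)) fail("dependency token index out of range")
  }

  if (!is.null(ann$srl)) {
    for (fr in ann$srl) {
      if (is.null(fr$predicate) || fr$predicate < 0 || fr$predicate >= n) {
        fail("SRL predicate index out of range")
      }
      labs <- names(fr$args)
      if (anyDuplicated(labs)) fail("duplicate SRL argument labels")
      for (lab in labs) {
        sp <- fr$args[[lab]]
        check_span(sp, paste("SRL", lab))
        if (fr$predicate >= sp[1] && fr$predicate < sp[2]) {
          fail(paste("SRL argument", lab, "contains the predicate token"))
        }
      }
    }
  }

  if (!is.null(ann$entities) && nrow(ann$entities) > 0L) {
    en <- ann$entities
    for (i in seq_len(nrow(en))) {
      check_span(c(en$start[i], en$end[i]), "entity")
      expected <- detokenize(tk$surface[(en$start[i] + 1L):en$end[i]])
      if (!identical(en$surface[i], expected)) {
        fail(paste0("entity surface '", en$surface[i],
                    "' does not match span text '", expected, "'"))
      }
      sc <- en$cuis[[i]]$score
      if (length(sc) > 1L && any(diff(sc) > 0)) {
        fail("entity candidate CUI scores must be non-increasing")
      }
    }
  }

  if (!is.null(ann$constituency)) {
    leaves <- constituency_leaves(ann$constituency)
    if (!identical(leaves, tk$surface)) {
      fail("constituency leaves do not match the token sequence")
    }
  }
  invisible(ann)
}

#' Analyze a sentence through a provider
#'
#' @param provider An annotation provider (e.g. from [replay_provider()]).
#' @param sentence Sentence text; must be non-empty after trimming.
#' @param requests Subset of `c("tokens", "constituency", "dependency",
#'   "srl", "entities")`; the returned annotation is populated for exactly
#'   these kinds.
#' @return A `litkg_annotation`.
#' @export
analyze_sentence <- function(provider, sentence, requests = ANALYSIS_KINDS) {
  if (!is.character(sentence) || length(sentence) != 1L ||
      !nzchar(stringr::str_squish(sentence))) {
    abort_litkg("sentence must be non-empty text", "litkg_invalid_input")
  }
  bad <- setdiff(requests, ANALYSIS_KINDS)
  if (length(bad) > 0L) {
    abort_litkg(paste("unknown analysis kind(s):", paste(bad, collapse = ", ")),
                "litkg_invalid_input")
  }
  UseMethod("analyze_sentence")
}

#' @export
analyze_sentence.default <- function(provider, sentence, requests = ANALYSIS_KINDS) {
  abort_litkg("object is not an annotation provider", "litkg_invalid_input")
}

#' Load a replay annotation provider from a JSON fixture
#'
#' The fixture is a JSON object keyed by whitespace-normalized sentence text;
#' each entry stores the analyses recorded for that sentence:
#' `tokens` (`surface`/`pos`/`lemma` objects), `constituency` (nested
#' `[label, children...]` lists with `[pos, surface]` preterminals),
#' `dependencies` (`head`/`dep`/`rel`, root edge `head = -1`), `srl`
#' (`pred`, `lemma`, `args` label -> `[start, end)`), and `entities`
#' (`span`, `cuis` as `[id, score]` pairs). Replayed annotations are
#' byte-identical across calls, which makes every downstream stage
#' deterministic and testable offline.
#'
#' @param path Path to the fixture JSON file.
#' @return An annotation provider of class `litkg_replay_provider`.
#' @export
replay_provider <- function(path) {
  if (!file.exists(path)) {
    abort_litkg(paste("fixture file not found:", path), "litkg_io_error")
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort_litkg(
      paste("fixture is not valid JSON:", conditionMessage(e)),
      "litkg_schema_error")
  )
  if (!is.list(raw) || is.null(names(raw))) {
    abort_litkg("fixture must be a JSON object keyed by sentence text",
                "litkg_schema_error")
  }
  store <- new.env(parent = emptyenv())
  for (key in names(raw)) {
    ann <- fixture_annotation(raw[[key]], key)
    assign(normalize_sentence_key(key), ann, envir = store)
  }
  structure(list(store = store, path = path),
            class = c("litkg_replay_provider", "litkg_provider"))
}

#' @export
print.litkg_replay_provider <- function(x, ...) {
  cat("<litkg_replay_provider> ", length(ls(x$store)), " fixture sentence(s)\n",
      sep = "")
  invisible(x)
}

#' Sentences available from a replay provider
#' @param provider A replay provider.
#' @return Character vector of normalized fixture sentence keys.
#' @export
provider_sentences <- function(provider) {
  sort(ls(provider$store))
}

#' @export
analyze_sentence.litkg_replay_provider <- function(provider, sentence,
                                                   requests = ANALYSIS_KINDS) {
  key <- normalize_sentence_key(sentence)
  if (!exists(key, envir = provider$store, inherits = FALSE)) {
    abort_litkg(paste0("no stored annotation for sentence: ", key),
                "litkg_missing_annotation")
  }
  ann <- get(key, envir = provider$store, inherits = FALSE)
  kind_field <- c(tokens = "tokens", constituency = "constituency",
                  dependency = "dependencies", srl = "srl",
                  entities = "entities")
  for (req in requests) {
    if (is.null(ann[[kind_field[[req]]]])) {
      abort_litkg(paste0("provider cannot serve analysis kind '", req,
                         "' for sentence: ", key),
                  "litkg_capability_error")
    }
  }
  keep <- unname(kind_field[requests])
  for (field in setdiff(unname(kind_field), c(keep, "tokens"))) {
    ann[[field]] <- NULL
  }
  ann
}

# ---- fixture deserialization -------------------------------------------------

fixture_annotation <- function(entry, key) {
  fail <- function(msg) abort_litkg(
    paste0("fixture entry malformed (", msg, ") at key: ", key),
    "litkg_schema_error")
  if (is.null(entry$tokens)) fail("missing tokens")

  tokens <- tibble::tibble(
    index = seq_along(entry$tokens) - 1L,
    surface = vapply(entry$tokens, function(t) as.character(t$surface %||% ""),
                     character(1)),
    pos = vapply(entry$tokens, function(t) as.character(t$pos %||% ""),
                 character(1)),
    lemma = vapply(entry$tokens, function(t) as.character(t$lemma %||% ""),
                   character(1))
  )

  constituency <- if (!is.null(entry$constituency)) {
    build_constituency(entry$constituency)
  }

  dependencies <- if (!is.null(entry$dependencies)) {
    tibble::tibble(
      head = vapply(entry$dependencies, function(d) as.integer(d$head), integer(1)),
      dep = vapply(entry$dependencies, function(d) as.integer(d$dep), integer(1)),
      rel = vapply(entry$dependencies, function(d) as.character(d$rel), character(1))
    )
  }

  srl <- if (!is.null(entry$srl)) {
    lapply(entry$srl, function(fr) {
      args <- lapply(fr$args, function(sp) as.integer(unlist(sp)))
      list(predicate = as.integer(fr$pred),
           lemma = as.character(fr$lemma),
           args = args)
    })
  }

  entities <- if (!is.null(entry$entities)) {
    if (length(entry$entities) == 0L) {
      tibble::tibble(start = integer(), end = integer(),
                     surface = character(), cuis = list())
    } else {
      tibble::tibble(
        start = vapply(entry$entities, function(e) as.integer(e$span[[1]]), integer(1)),
        end = vapply(entry$entities, function(e) as.integer(e$span[[2]]), integer(1)),
        surface = vapply(entry$entities, function(e) {
          as.character(e$surface %||% NA_character_)
        }, character(1)),
        cuis = lapply(entry$entities, function(e) {
          if (length(e$cuis) == 0L) {
            tibble::tibble(cui = character(), score = numeric())
          } else {
            tibble::tibble(
              cui = vapply(e$cuis, function(c) as.character(c[[1]]), character(1)),
              score = vapply(e$cuis, function(c) as.numeric(c[[2]]), numeric(1))
            )
          }
        })
      )
    }
  }
  if (!is.null(entities) && nrow(entities) > 0L && anyNA(entities$surface)) {
    # surface is derivable from the span when omitted in the fixture
    for (i in which(is.na(entities$surface))) {
      entities$surface[i] <- detokenize(
        tokens$surface[(entities$start[i] + 1L):entities$end[i]])
    }
  }

  ann <- structure(
    list(sentence = key, tokens = tokens, constituency = constituency,
         dependencies = dependencies, srl = srl, entities = entities),
    class = "litkg_annotation"
  )
  validate_annotation(ann, key = key)
  ann
}

# ---- constituency trees ------------------------------------------------------

#' Build a constituency tree from nested lists
#'
#' Accepts the fixture representation: `[label, child...]` where a
#' preterminal is `[pos, "surface"]`. Spans are computed from the leaf
#' order (0-based, half-open).
#'
#' @param x Nested list representation of the tree.
#' @return The root node: a list with `label`, `children`, `token`
#'   (for leaves) and `span`.
#' @export
build_constituency <- function(x) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  build_cnode(x, counter)
}

build_cnode <- function(x, counter) {
  if (!is.list(x) || length(x) < 2L) {
    abort_litkg("constituency node must be [label, children...]",
                "litkg_schema_error")
  }
  label <- as.character(x[[1]])
  rest <- x[-1]
  if (length(rest) == 1L && is.character(rest[[1]]) && !is.list(rest[[1]])) {
    start <- counter$i
    counter$i <- counter$i + 1L
    return(list(label = label, children = list(), token = rest[[1]],
                span = c(start, counter$i)))
  }
  children <- lapply(rest, build_cnode, counter = counter)
  span <- c(children[[1]]$span[1], children[[length(children)]]$span[2])
  list(label = label, children = children, token = NULL, span = span)
}

constituency_leaves <- function(node) {
  if (length(node$children) == 0L) return(node$token)
  unlist(lapply(node$children, constituency_leaves), use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
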