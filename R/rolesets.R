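# Verb roleset inventory (PropBank/VerbNet style): each verb sense maps
# argument labels (A0, A1, ...) to role names (Agent, Theme, ...).

#' Read a roleset inventory
#'
#' The inventory is a TSV with columns `lemma`, `sense_id` and `roles`,
#' the latter a comma-separated list of `label=RoleName` pairs, e.g.
#' `A0=Agent,A1=Theme`. A small inventory covering common reporting verbs
#' ships with the package (`system.file("extdata", "rolesets.tsv",
#' package = "litkg")`).
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `lemma`, `sense_id` and a list-column
#'   `roles` of named character vectors.
#' @export
read_rolesets <- function(path) {
  if (!file.exists(path)) {
    abort_litkg(paste("roleset inventory not found:", path), "litkg_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L && startsWith(lines[1], "lemma\t")) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    abort_litkg(paste0("roleset inventory line ", bad[1],
                       " does not have 3 tab-separated fields"),
                "litkg_parse_error")
  }
  tibble::tibble(
    lemma = vapply(parts, `[[`, character(1), 1L),
    sense_id = vapply(parts, `[[`, character(1), 2L),
    roles = lapply(parts, function(p) {
      kv <- strsplit(strsplit(p[[3]], ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
      stats::setNames(vapply(kv, `[[`, character(1), 2L),
                      vapply(kv, `[[`, character(1), 1L))
    })
  )
}

#' Default packaged roleset inventory
#' @return Tibble as from [read_rolesets()].
#' @export
default_rolesets <- function() {
  read_rolesets(system.file("extdata", "rolesets.tsv", package = "litkg"))
}

#' Resolve the roleset for a verb and its argument labels
#'
#' Returns the lowest-numbered sense of `verb_lemma` whose role labels
#' cover the frame's core labels (`A0`, `A1`, `A2`, ...); modifier labels
#' (`AM-*`) are not roleset roles and do not constrain the match.
#'
#' @param verb_lemma Verb lemma, e.g. `"confirm"`.
#' @param argument_labels Character vector of the frame's argument labels.
#' @param inventory Tibble from [read_rolesets()].
#' @return A list with `verb_lemma`, `sense_id` and `roles` (named
#'   character vector), or `NULL` when no sense matches.
#' @export
resolve_roleset <- function(verb_lemma, argument_labels,
                            inventory = default_rolesets()) {
  cand <- inventory[inventory$lemma == verb_lemma, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  core <- argument_labels[grepl("^A\\d+$", argument_labels)]
  covers <- vapply(cand$roles, function(r) all(core %in% names(r)), logical(1))
  cand <- cand[covers, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[order(cand$sense_id), , drop = FALSE]
  list(verb_lemma = cand$lemma[1], sense_id = cand$sense_id[1],
       roles = cand$roles[[1]])
}
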