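# Triple-set evaluation: canonical normalization, set differences and the
# Jaccard similarity coefficient J(A, B) = |A n B| / |A u B|, the statistic
# used to compare automatically extracted triples against manually curated
# sets.

#' Normalize triples to canonical form
#'
#' Case-folds, collapses whitespace and strips leading determiners from
#' each field. Idempotent; triple equality downstream is exact string
#' equality on this canonical form.
#'
#' @param triples Triple tibble (only `subject`, `predicate`, `object`
#'   are required).
#' @return The tibble with normalized fields.
#' @export
normalize_triples <- function(triples) {
  norm <- function(x) {
    x <- tolower(stringr::str_squish(x))
    stringr::str_replace(
      x, paste0("^(", paste(STOP_DETERMINERS, collapse = "|"), ")\\s+"), "")
  }
  triples$subject <- norm(triples$subject)
  triples$predicate <- stringr::str_squish(tolower(triples$predicate))
  triples$object <- norm(triples$object)
  triples
}

triple_keys <- function(triples) {
  if (nrow(triples) == 0L) return(character(0))
  unique(paste(triples$subject, triples$predicate, triples$object,
               sep = "␟"))
}

#' Jaccard similarity of two triple sets
#'
#' `|A n B| / (|A| + |B| - |A n B|)`; 1 for identical sets, 0 for disjoint
#' sets, and (by convention) 1 when both sets are empty. Inputs should be
#' normalized first (see [normalize_triples()]).
#'
#' @param a,b Triple tibbles.
#' @return A number in `[0, 1]`.
#' @export
jaccard_triples <- function(a, b) {
  ka <- triple_keys(a)
  kb <- triple_keys(b)
  if (length(ka) == 0L && length(kb) == 0L) return(1)
  inter <- length(intersect(ka, kb))
  inter / (length(ka) + length(kb) - inter)
}

#' Compare two triple sets
#'
#' Counts triples found only in `a`, only in `b`, and in both, plus the
#' Jaccard coefficient. The default matching criterion is exact equality
#' on the canonical form; `mode = "substring"` relaxes subject/object
#' matching to containment (off by default).
#'
#' @param a,b Triple tibbles (e.g. manual vs automatic extraction).
#' @param normalize Normalize both sets first.
#' @param mode `"exact"` (default) or `"substring"`.
#' @return A `litkg_comparison`: list with `only_a`, `only_b`, `both`,
#'   `jaccard` and the triple tibbles behind each count.
#' @export
diff_triple_sets <- function(a, b, normalize = TRUE,
                             mode = c("exact", "substring")) {
  mode <- match.arg(mode)
  if (normalize) {
    a <- normalize_triples(a)
    b <- normalize_triples(b)
  }
  ka <- triple_keys(a)
  kb <- triple_keys(b)
  if (mode == "exact") {
    both_keys <- intersect(ka, kb)
    only_a_keys <- setdiff(ka, kb)
    only_b_keys <- setdiff(kb, ka)
  } else {
    split_key <- function(k) strsplit(k, "␟", fixed = TRUE)[[1]]
    matches <- function(x, y) {
      xs <- split_key(x); ys <- split_key(y)
      xs[2] == ys[2] &&
        (grepl(xs[1], ys[1], fixed = TRUE) || grepl(ys[1], xs[1], fixed = TRUE)) &&
        (grepl(xs[3], ys[3], fixed = TRUE) || grepl(ys[3], xs[3], fixed = TRUE))
    }
    both_keys <- ka[vapply(ka, function(x) any(vapply(kb, matches, logical(1), x = x)),
                           logical(1))]
    only_a_keys <- setdiff(ka, both_keys)
    only_b_keys <- kb[!vapply(kb, function(y) any(vapply(ka, matches, logical(1), x = y)),
                              logical(1))]
  }
  n_both <- length(both_keys)
  n_a <- length(only_a_keys)
  n_b <- length(only_b_keys)
  jac <- if (n_a + n_b + n_both == 0L) 1 else n_both / (n_a + n_b + n_both)
  keys_to_tbl <- function(keys) {
    if (length(keys) == 0L) {
      return(tibble::tibble(subject = character(), predicate = character(),
                            object = character()))
    }
    parts <- strsplit(keys, "␟", fixed = TRUE)
    tibble::tibble(subject = vapply(parts, `[[`, character(1), 1L),
                   predicate = vapply(parts, `[[`, character(1), 2L),
                   object = vapply(parts, `[[`, character(1), 3L))
  }
  structure(
    list(only_a = n_a, only_b = n_b, both = n_both, jaccard = jac,
         triples_only_a = keys_to_tbl(only_a_keys),
         triples_only_b = keys_to_tbl(only_b_keys),
         triples_both = keys_to_tbl(both_keys)),
    class = "litkg_comparison"
  )
}

#' @export
print.litkg_comparison <- function(x, ...) {
  cat("<litkg_comparison> only A: ", x$only_a, "; only B: ", x$only_b,
      "; both: ", x$both, "; Jaccard: ",
      format_jaccard(x$jaccard), "\n", sep = "")
  invisible(x)
}

#' Round a Jaccard value for reporting
#'
#' @param j Jaccard value.
#' @param digits Decimal places (default two, as comparison tables are
#'   conventionally printed).
#' @param mode `"half_even"` (default) or `"truncate"`.
#' @return Numeric value rounded for display.
#' @export
format_jaccard <- function(j, digits = 2L, mode = c("half_even", "truncate")) {
  mode <- match.arg(mode)
  if (mode == "half_even") round(j, digits) else
    floor(j * 10^digits) / 10^digits
}

#' Tidy a triple-set comparison
#' @param x A `litkg_comparison`.
#' @param ... Unused.
#' @return Tibble with one row per category (`only_a`, `only_b`, `both`).
#' @method tidy litkg_comparison
#' @export
tidy.litkg_comparison <- function(x, ...) {
  tibble::tibble(category = c("only_a", "only_b", "both"),
                 n = c(x$only_a, x$only_b, x$both))
}

#' One-row summary of a triple-set comparison
#' @param x A `litkg_comparison`.
#' @param ... Unused.
#' @return Tibble with counts and the Jaccard coefficient.
#' @method glance litkg_comparison
#' @export
glance.litkg_comparison <- function(x, ...) {
  tibble::tibble(only_a = x$only_a, only_b = x$only_b, both = x$both,
                 jaccard = x$jaccard)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a triple-set comparison
#' @param object A `litkg_comparison`.
#' @param ... Unused.
#' @return A ggplot bar chart of the overlap counts.
#' @method autoplot litkg_comparison
#' @export
autoplot.litkg_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "triples",
      title = "Triple-set overlap",
      subtitle = paste("Jaccard =", format_jaccard(object$jaccard))) +
    ggplot2::theme_minimal()
}

#' Write / read a comparison report
#'
#' TSV and JSON serializations of the counts and coefficient.
#'
#' @param comparison A `litkg_comparison`.
#' @param path Output file; format chosen by extension (`.json` or TSV).
#' @return The path, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  g <- glance(comparison)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(g), path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(c(paste(names(g), collapse = "\t"),
                 paste(unlist(g), collapse = "\t")), path, useBytes = TRUE)
  }
  invisible(path)
}
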