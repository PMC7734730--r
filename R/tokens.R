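# Tokenisation helpers shared by preprocessing, extraction and the replay
# provider. The tokenizer mirrors Penn-Treebank conventions closely enough to
# reproduce the token streams stored in replay fixtures: punctuation and
# bracket characters are split off, possessive 's is its own token,
# hyphenated words stay whole.

#' Tokenize a sentence
#'
#' A small rule-based tokenizer: splits on whitespace, peels leading and
#' trailing punctuation into their own tokens and separates the possessive
#' `'s` clitic. Hyphenated words are kept as single tokens.
#'
#' @param text A length-one character vector.
#' @return A character vector of tokens (possibly empty).
#' @examples
#' simple_tokenize("Alzheimer's Disease causes dementia.")
#' @export
simple_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- stringr::str_squish(text)
  if (!nzchar(text)) return(character(0))
  chunks <- strsplit(text, " ", fixed = TRUE)[[1]]
  unlist(lapply(chunks, split_chunk), use.names = FALSE)
}

split_chunk <- function(ch) {
  n <- nchar(ch)
  if (n == 0L) return(character(0))
  first <- substr(ch, 1L, 1L)
  if (first %in% c("(", "[", "\"")) {
    return(c(first, split_chunk(substr(ch, 2L, n))))
  }
  last <- substr(ch, n, n)
  if (last %in% c(".", ",", ";", ":", "!", "?", ")", "]", "\"", "%")) {
    return(c(split_chunk(substr(ch, 1L, n - 1L)), last))
  }
  if (n > 2L && grepl("'s$", ch)) {
    return(c(substr(ch, 1L, n - 2L), "'s"))
  }
  ch
}

#' Reassemble tokens into running text
#'
#' Joins tokens with single spaces, then removes the space before closing
#' punctuation and before clitics starting with an apostrophe, and after
#' opening brackets.
#'
#' @param tokens Character vector of tokens.
#' @return A length-one character string.
#' @export
detokenize <- function(tokens) {
  if (length(tokens) == 0L) return("")
  glue_before <- c(".", ",", ";", ":", "!", "?", ")", "]", "%")
  out <- tokens[1L]
  for (i in seq_along(tokens)[-1L]) {
    tok <- tokens[i]
    prev <- tokens[i - 1L]
    glued <- tok %in% glue_before || startsWith(tok, "'") || prev %in% c("(", "[")
    out <- paste0(out, if (glued) "" else " ", tok)
  }
  out
}

# Normalisation used for fixture keys and URI minting: collapse whitespace,
# keep case (minting case-folds separately).
normalize_sentence_key <- function(x) stringr::str_squish(x)

slugify <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

capitalize_first <- function(x) {
  if (!nzchar(x)) return(x)
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

ensure_terminal <- function(x) {
  x <- stringr::str_squish(x)
  if (!nzchar(x)) return(x)
  last <- substr(x, nchar(x), nchar(x))
  if (last %in% c(".", "!", "?")) return(x)
  if (last == ",") x <- substr(x, 1L, nchar(x) - 1L)
  paste0(stringr::str_squish(x), ".")
}

abort_litkg <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "litkg_error"), ...)
}
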