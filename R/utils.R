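# Shared low-level helpers: surface normalization, tokenization, seeding.

# Token regex: runs of alphanumerics, hyphens kept inside tokens so forms
# like "pro-apoptotic" stay a single token.
TOKEN_REGEX <- "[[:alnum:]]+(?:-[[:alnum:]]+)*"

#' Tokenize text into character spans
#'
#' Splits text into word tokens (alphanumeric runs; internal hyphens are kept
#' so hyphenated forms such as "pro-apoptotic" are single tokens). Offsets are
#' 0-based, half-open character positions into `text`.
#'
#' @param text A single string.
#' @return A tibble with columns `start`, `end` (0-based half-open) and
#'   `token` (the matched text, original case).
#' @export
#' @examples
#' tokenize_spans("Pro-apoptotic signals.")
tokenize_spans <- function(text) {
  stopifnot(length(text) == 1L)
  m <- gregexpr(TOKEN_REGEX, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble(start = integer(), end = integer(), token = character()))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  tibble(start = start, end = end,
         token = substring(text, start + 1L, end))
}

#' Normalize a surface string for dictionary lookup
#'
#' Lowercases, tokenizes and re-joins with single spaces, so that punctuation
#' and whitespace variation do not block matches. Both dictionary entries and
#' candidate text windows go through the same normalization.
#'
#' @param x Character vector of surface strings.
#' @return Character vector of normalized surfaces ("" when no token remains).
#' @export
normalize_surface <- function(x) {
  vapply(tolower(x), function(s) {
    toks <- tokenize_spans(s)$token
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default English stopword list
#'
#' A compact list of function words removed from bag-of-words features.
#' Override by passing your own character vector wherever a `stopwords`
#' argument appears.
#'
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "if", "then", "than", "that",
    "this", "these", "those", "of", "in", "on", "at", "by", "for", "with",
    "to", "from", "as", "is", "are", "was", "were", "be", "been", "being",
    "it", "its", "we", "our", "they", "their", "he", "she", "his", "her",
    "not", "no", "nor", "so", "such", "both", "each", "which", "who",
    "whom", "what", "when", "where", "how", "all", "any", "can", "could",
    "may", "might", "will", "would", "shall", "should", "do", "does",
    "did", "has", "have", "had", "also", "into", "over", "under", "between",
    "within", "during", "after", "before", "while", "there", "here", "more",
    "most", "other", "some", "only", "very", "via", "per", "i", "you")
}
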