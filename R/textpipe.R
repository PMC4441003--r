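# Corpus reading, sentence segmentation, and dictionary-based concept
# recognition (longest-match, token-aligned, case-insensitive).

#' Read a document corpus from TSV
#'
#' Expects a header with columns `doc_id`, `unit_kind`, `text`; each record
#' is a whole abstract or one full-text paragraph. Standard TSV quoting is
#' honored (tabs/newlines inside quoted fields).
#'
#' @param path TSV path.
#' @return A tibble with columns `doc_id`, `unit_kind`, `text`.
#' @export
read_corpus <- function(path) {
  corpus <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
  required <- c("doc_id", "unit_kind", "text")
  if (!all(required %in% names(corpus))) {
    abort(paste0("corpus TSV must have columns: ",
                 paste(required, collapse = ", ")))
  }
  corpus <- as_tibble(corpus[required])
  if (anyDuplicated(corpus$doc_id)) {
    abort(paste0("duplicate doc_id: ",
                 corpus$doc_id[duplicated(corpus$doc_id)][1]))
  }
  empty <- is.na(corpus$text) | !nzchar(str_trim(corpus$text))
  if (any(empty)) {
    warn(paste0(sum(empty), " record(s) with empty text skipped"))
    corpus <- corpus[!empty, ]
  }
  corpus
}

# Abbreviations that must not end a sentence (matched against the word
# immediately before a period, case-insensitively).
SENTENCE_ABBREVS <- c("e.g", "i.e", "cf", "vs", "etc", "fig", "figs", "eq",
                      "ref", "refs", "dr", "mr", "mrs", "ms", "prof", "al",
                      "st", "no", "approx", "ca")

#' Split one text into sentence spans
#'
#' Rule-based splitter: a sentence ends at terminal punctuation (`.`, `!`,
#' `?`) followed by whitespace and an uppercase letter or digit (or end of
#' text), unless the word before the period is a known abbreviation or a
#' single initial. Spans are 0-based half-open character offsets, trimmed of
#' surrounding whitespace.
#'
#' @param text A single string.
#' @return A tibble with columns `start`, `end`, `sentence`.
#' @export
segment_sentences <- function(text) {
  stopifnot(length(text) == 1L)
  empty <- tibble(start = integer(), end = integer(), sentence = character())
  if (is.na(text) || !nzchar(str_trim(text))) return(empty)

  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  m <- gregexpr("[.!?]+", text)[[1]]
  breaks <- integer(0)  # positions (1-based) of last char of each sentence
  if (m[1] != -1L) {
    for (k in seq_along(m)) {
      pos <- as.integer(m[k]) + attr(m, "match.length")[k] - 1L  # end of run
      if (pos == n) { breaks <- c(breaks, pos); next }
      nxt <- pos + 1L
      while (nxt <= n && grepl("^\\s$", chars[nxt])) nxt <- nxt + 1L
      if (nxt == pos + 1L) next                     # no whitespace after
      if (nxt > n) { breaks <- c(breaks, pos); next }
      if (!grepl("[[:upper:][:digit:]]", chars[nxt])) next
      # abbreviation guard on the word preceding the punctuation run
      before <- substr(text, max(1L, as.integer(m[k]) - 15L),
                       as.integer(m[k]) - 1L)
      word <- str_match(before, "([A-Za-z][A-Za-z.]*)$")[, 2]
      if (!is.na(word)) {
        if (grepl("^[A-Z]$", word)) next            # initials: "A. Smith"
        if (tolower(sub("\\.$", "", word)) %in% SENTENCE_ABBREVS) next
      }
      breaks <- c(breaks, pos)
    }
  }
  if (!length(breaks) || breaks[length(breaks)] != n) breaks <- c(breaks, n)

  starts0 <- c(1L, head(breaks, -1L) + 1L)
  out <- list()
  for (i in seq_along(breaks)) {
    s <- starts0[i]; e <- breaks[i]
    while (s <= e && grepl("^\\s$", chars[s])) s <- s + 1L
    while (e >= s && grepl("^\\s$", chars[e])) e <- e - 1L
    if (s > e) next
    out[[length(out) + 1L]] <- tibble(
      start = s - 1L, end = e,
      sentence = substr(text, s, e)
    )
  }
  if (!length(out)) return(empty)
  bind_rows(out)
}

#' Segment every document of a corpus into sentences
#'
#' @param corpus Tibble from [read_corpus()] (columns `doc_id`, `unit_kind`,
#'   `text`).
#' @return A tibble with one row per sentence: `doc_id`, `unit_kind`,
#'   `sentence_index` (0-based), `start`, `end` (document-level 0-based
#'   half-open offsets), `sentence`.
#' @export
segment_corpus <- function(corpus) {
  corpus |>
    mutate(.spans = map(.data$text, segment_sentences)) |>
    select(-"text") |>
    tidyr::unnest(".spans") |>
    group_by(.data$doc_id) |>
    mutate(sentence_index = row_number() - 1L) |>
    ungroup() |>
    select("doc_id", "unit_kind", "sentence_index", "start", "end", "sentence")
}

# Build a fast lookup: normalized surface -> list of concept rows.
dictionary_index <- function(dictionary) {
  surf <- dictionary$surface
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(surf)) {
    key <- surf[i]
    idx[[key]] <- c(idx[[key]], i)
  }
  n_tokens <- lengths(gregexpr(" ", surf, fixed = TRUE)) + 1L
  n_tokens[!grepl(" ", surf)] <- 1L
  list(env = idx, max_tokens = if (length(surf)) max(n_tokens) else 0L)
}

#' Recognize dictionary concepts in segmented text
#'
#' Scans each sentence with a contiguous, token-boundary-aligned,
#' case-insensitive longest-match strategy: at each token position the
#' longest dictionary surface starting there wins, the scan resumes after
#' it (so shorter overlapping matches are suppressed), and ties are broken
#' leftmost. A surface mapping to several concepts yields one row per
#' concept id sharing the same span.
#'
#' @param sentences Segmented corpus from [segment_corpus()].
#' @param dictionary A `concept_dictionary` (with `term_id` column) or
#'   `protein_lexicon` (with `accession` column).
#' @param kind `"go_term"` or `"protein"`; defaults to the dictionary class.
#' @return A mention tibble: `doc_id`, `sentence_index`, `start`, `end`
#'   (document-level 0-based half-open character offsets), `surface` (the
#'   matched document text), `kind`, `concept_id`, `provenance`.
#' @export
match_concepts <- function(sentences, dictionary, kind = NULL) {
  if (is.null(kind)) {
    kind <- if (inherits(dictionary, "protein_lexicon")) "protein" else "go_term"
  }
  kind <- match.arg(kind, c("protein", "go_term"))
  id_col <- if ("term_id" %in% names(dictionary)) "term_id" else "accession"
  prov <- if ("provenance" %in% names(dictionary)) dictionary$provenance
          else rep("lexicon", nrow(dictionary))
  idx <- dictionary_index(dictionary)

  out <- vector("list", nrow(sentences))
  for (r in seq_len(nrow(sentences))) {
    sen <- sentences$sentence[r]
    toks <- tokenize_spans(sen)
    nt <- nrow(toks)
    if (!nt || !idx$max_tokens) next
    low <- tolower(toks$token)
    hits <- list()
    i <- 1L
    while (i <= nt) {
      matched <- FALSE
      for (j in seq(min(nt, i + idx$max_tokens - 1L), i)) {
        key <- paste(low[i:j], collapse = " ")
        rows <- idx$env[[key]]
        if (!is.null(rows)) {
          hits[[length(hits) + 1L]] <- tibble(
            start = toks$start[i], end = toks$end[j],
            concept_id = dictionary[[id_col]][rows],
            provenance = prov[rows]
          )
          i <- j + 1L
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1L
    }
    if (length(hits)) {
      h <- bind_rows(hits)
      out[[r]] <- tibble(
        doc_id = sentences$doc_id[r],
        sentence_index = sentences$sentence_index[r],
        start = sentences$start[r] + h$start,
        end = sentences$start[r] + h$end,
        surface = substring(sen, h$start + 1L, h$end),
        kind = kind,
        concept_id = h$concept_id,
        provenance = h$provenance
      )
    }
  }
  res <- bind_rows(compact(out))
  if (nrow(res)) {
    # one row per (span, concept); surfaces with several provenances collapse
    res <- res |>
      group_by(.data$doc_id, .data$sentence_index, .data$start, .data$end,
               .data$surface, .data$kind, .data$concept_id) |>
      summarise(provenance = paste(sort(unique(.data$provenance)),
                                   collapse = ";"),
                .groups = "drop") |>
      arrange(.data$doc_id, .data$start, .data$concept_id)
  }
  if (!nrow(res)) {
    res <- tibble(doc_id = character(), sentence_index = integer(),
                  start = integer(), end = integer(), surface = character(),
                  kind = character(), concept_id = character(),
                  provenance = character())
  }
  res
}

#' Write a mention table to TSV
#'
#' @param mentions Mention tibble from [match_concepts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mentions <- function(mentions, path) {
  readr::write_tsv(mentions, path, col_names = TRUE)
  invisible(path)
}
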