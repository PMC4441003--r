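# Co-mention and bag-of-words feature extraction. A co-mention is a protein
# mention and a GO concept mention co-occurring in a defined span: the same
# sentence ("sentence") or the same abstract/paragraph but different
# sentences ("non_sentence"). Counting is presence-based: one event per
# sentence (sentence span) or per unordered sentence pair (non-sentence
# span), regardless of how many times either entity is repeated there.

#' Extract sentence and non-sentence co-mentions
#'
#' For each document unit and each (protein accession, GO id) pair: one
#' `sentence` co-mention per sentence containing at least one mention of
#' each, and one `non_sentence` co-mention per unordered pair of distinct
#' sentences where one contains the protein and the other the GO concept.
#' Ambiguous protein mentions contribute once per candidate accession.
#'
#' @param mentions A mention tibble ([match_concepts()] output, protein and
#'   go_term rows together or concatenated with [dplyr::bind_rows()]).
#' @param mention_pair Count every (protein mention, GO mention) pair instead
#'   of presence-based events (off by default; inflates counts quadratically
#'   when entities repeat).
#' @return A co-mention tibble: `protein`, `go_id`, `doc_id`, `span`
#'   (`"sentence"`/`"non_sentence"`), `protein_sentence`, `go_sentence`.
#' @export
extract_comentions <- function(mentions, mention_pair = FALSE) {
  required <- c("doc_id", "sentence_index", "kind", "concept_id")
  if (!all(required %in% names(mentions))) {
    abort("mentions must have doc_id, sentence_index, kind, concept_id")
  }
  empty <- tibble(protein = character(), go_id = character(),
                  doc_id = character(), span = character(),
                  protein_sentence = integer(), go_sentence = integer())
  prot <- mentions |> filter(.data$kind == "protein")
  go <- mentions |> filter(.data$kind == "go_term")
  if (!nrow(prot) || !nrow(go)) return(empty)

  if (mention_pair) {
    pairs <- prot |>
      select("doc_id", protein = "concept_id", protein_sentence = "sentence_index") |>
      inner_join(go |> select("doc_id", go_id = "concept_id",
                              go_sentence = "sentence_index"),
                 by = "doc_id", relationship = "many-to-many")
  } else {
    pairs <- prot |>
      distinct(.data$doc_id, protein = .data$concept_id,
               protein_sentence = .data$sentence_index) |>
      inner_join(go |> distinct(.data$doc_id, go_id = .data$concept_id,
                                go_sentence = .data$sentence_index),
                 by = "doc_id", relationship = "many-to-many")
  }

  sent <- pairs |>
    filter(.data$protein_sentence == .data$go_sentence)
  nonsent <- pairs |>
    filter(.data$protein_sentence != .data$go_sentence)
  if (!mention_pair) {
    sent <- sent |>
      distinct(.data$doc_id, .data$protein, .data$go_id,
               .data$protein_sentence, .data$go_sentence)
    nonsent <- nonsent |>
      mutate(.lo = pmin(.data$protein_sentence, .data$go_sentence),
             .hi = pmax(.data$protein_sentence, .data$go_sentence)) |>
      distinct(.data$doc_id, .data$protein, .data$go_id, .data$.lo,
               .data$.hi, .keep_all = TRUE) |>
      select(-".lo", -".hi")
  }
  sent <- mutate(sent, span = "sentence")
  nonsent <- mutate(nonsent, span = "non_sentence")

  bind_rows(sent, nonsent) |>
    select("protein", "go_id", "doc_id", "span",
           "protein_sentence", "go_sentence") |>
    arrange(.data$doc_id, .data$protein, .data$go_id,
            .data$protein_sentence, .data$go_sentence)
}

#' Extract bag-of-words counts per protein
#'
#' Each sentence containing at least one mention of a protein contributes its
#' tokens (lowercased, stopwords removed, no stemming) once to that
#' protein's word counts; counts accumulate across sentences and documents.
#'
#' @param sentences Segmented corpus from [segment_corpus()].
#' @param protein_mentions Mention tibble restricted to `kind == "protein"`.
#' @param stopwords Lowercase words to drop; default [default_stopwords()].
#' @param include_protein_tokens Keep the tokens of the protein mention
#'   itself (default TRUE); set FALSE to mask the mention span.
#' @return A tibble: `protein`, `word`, `count`.
#' @export
extract_bow <- function(sentences, protein_mentions,
                        stopwords = default_stopwords(),
                        include_protein_tokens = TRUE) {
  prot <- protein_mentions |> filter(.data$kind == "protein")
  empty <- tibble(protein = character(), word = character(), count = integer())
  if (!nrow(prot)) return(empty)

  hits <- prot |>
    distinct(.data$doc_id, .data$sentence_index, protein = .data$concept_id)
  sen <- sentences |>
    inner_join(hits, by = c("doc_id", "sentence_index"),
               relationship = "many-to-many")
  if (!nrow(sen)) return(empty)

  rows <- vector("list", nrow(sen))
  for (r in seq_len(nrow(sen))) {
    toks <- tokenize_spans(sen$sentence[r])
    if (!include_protein_tokens) {
      spans <- prot |>
        filter(.data$doc_id == sen$doc_id[r],
               .data$sentence_index == sen$sentence_index[r],
               .data$concept_id == sen$protein[r])
      rel_start <- spans$start - sen$start[r]
      rel_end <- spans$end - sen$start[r]
      masked <- vapply(seq_len(nrow(toks)), function(k) {
        any(toks$start[k] < rel_end & toks$end[k] > rel_start)
      }, logical(1))
      toks <- toks[!masked, ]
    }
    w <- tolower(toks$token)
    w <- w[!w %in% stopwords]
    if (length(w)) {
      rows[[r]] <- tibble(protein = sen$protein[r], word = w)
    }
  }
  res <- bind_rows(compact(rows))
  if (!nrow(res)) return(empty)
  res |> count(.data$protein, .data$word, name = "count") |>
    arrange(.data$protein, .data$word)
}

#' Assemble a sparse per-protein feature table
#'
#' Aggregates co-mention events and bag-of-words counts over the whole
#' corpus into namespaced feature keys: `co_<GO id>` (sentence co-mention
#' counts; in `combined` mode the sentence + non-sentence sum),
#' `nco_<GO id>` (non-sentence counts) and `w_<word>`.
#'
#' @param comentions Co-mention tibble from [extract_comentions()]; may be
#'   NULL for `bow_only`.
#' @param bow Bag-of-words tibble from [extract_bow()]; required by the two
#'   BoW modes.
#' @param mode One of `"sentence_only"`, `"nonsentence_only"`, `"combined"`,
#'   `"separate"`, `"bow_only"`, `"comentions_plus_bow"`.
#' @return A `feature_table`: tibble `protein`, `feature`, `count` (positive
#'   integers; absent = 0).
#' @export
assemble_features <- function(comentions = NULL, bow = NULL,
                              mode = c("separate", "sentence_only",
                                       "nonsentence_only", "combined",
                                       "bow_only", "comentions_plus_bow")) {
  mode <- match.arg(mode)
  sent_counts <- function() {
    comentions |> filter(.data$span == "sentence") |>
      count(.data$protein, .data$go_id, name = "count") |>
      mutate(feature = paste0("co_", .data$go_id))
  }
  nonsent_counts <- function(prefix = "nco_") {
    comentions |> filter(.data$span == "non_sentence") |>
      count(.data$protein, .data$go_id, name = "count") |>
      mutate(feature = paste0(prefix, .data$go_id))
  }
  both_counts <- function() {
    comentions |> count(.data$protein, .data$go_id, name = "count") |>
      mutate(feature = paste0("co_", .data$go_id))
  }
  bow_counts <- function() {
    bow |> mutate(feature = paste0("w_", .data$word)) |>
      select("protein", "feature", "count")
  }
  need_cm <- mode != "bow_only"
  need_bow <- mode %in% c("bow_only", "comentions_plus_bow")
  if (need_cm && is.null(comentions)) abort("mode requires co-mentions")
  if (need_bow && is.null(bow)) abort("mode requires bag-of-words counts")

  parts <- switch(
    mode,
    sentence_only = list(sent_counts()),
    nonsentence_only = list(nonsent_counts()),
    combined = list(both_counts()),
    separate = list(sent_counts(), nonsent_counts()),
    bow_only = list(bow_counts()),
    comentions_plus_bow = list(sent_counts(), nonsent_counts(), bow_counts())
  )
  res <- bind_rows(parts) |>
    select("protein", "feature", "count") |>
    filter(.data$count > 0) |>
    arrange(.data$protein, .data$feature)
  structure(res, class = c("feature_table", class(tibble())))
}

#' Write / read the sparse feature file format
#'
#' One record per protein: the accession followed by comma-separated
#' `key=value` pairs, only non-zero features stated, e.g.
#' `Q9ZPY7, co_GO:0003675=6, co_GO:0005623=2`. `read_features()` of a
#' written file reproduces the table.
#'
#' @param features A `feature_table`.
#' @param path File path.
#' @return `path` invisibly (write); a `feature_table` (read).
#' @export
write_features <- function(features, path) {
  recs <- features |>
    arrange(.data$protein, .data$feature) |>
    group_by(.data$protein) |>
    summarise(line = paste(paste0(.data$feature, "=", .data$count),
                           collapse = ", "),
              .groups = "drop")
  writeLines(if (nrow(recs)) paste0(recs$protein, ", ", recs$line)
             else character(0), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(str_trim(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- str_trim(strsplit(lines[i], ",", fixed = TRUE)[[1]])
    protein <- parts[1]
    kv <- parts[-1]
    m <- str_match(kv, "^([^=]+)=([0-9]+)$")
    if (!nzchar(protein) || anyNA(m[, 1])) {
      abort(paste0("malformed feature record for '", protein,
                   "' (line ", i, ")"))
    }
    out[[i]] <- tibble(protein = protein, feature = m[, 2],
                       count = as.integer(m[, 3]))
  }
  res <- bind_rows(out)
  if (!length(out)) {
    res <- tibble(protein = character(), feature = character(),
                  count = integer())
  }
  structure(arrange(res, .data$protein, .data$feature),
            class = c("feature_table", class(tibble())))
}

#' Summarize a co-mention stream
#'
#' Counts of unique proteins, unique GO terms, unique (protein, GO) pairs
#' and total co-mention events, per span and combined. For the `combined`
#' row the unique columns can either deduplicate over the pooled events
#' (`"union"`, default) or simply add the two span rows (`"sum"`); totals
#' always add, since sentence and non-sentence events are disjoint.
#'
#' @param comentions Co-mention tibble.
#' @param combined `"union"` or `"sum"` for the combined row's unique counts.
#' @return A tibble: `span`, `n_proteins`, `n_go_terms`, `n_pairs`,
#'   `n_comentions`.
#' @export
comention_stats <- function(comentions, combined = c("union", "sum")) {
  combined <- match.arg(combined)
  one <- function(df, label) {
    tibble(span = label,
           n_proteins = n_distinct(df$protein),
           n_go_terms = n_distinct(df$go_id),
           n_pairs = nrow(distinct(df, .data$protein, .data$go_id)),
           n_comentions = nrow(df))
  }
  s <- one(filter(comentions, .data$span == "sentence"), "sentence")
  ns <- one(filter(comentions, .data$span == "non_sentence"), "non_sentence")
  comb <- if (combined == "union") {
    one(comentions, "combined")
  } else {
    tibble(span = "combined",
           n_proteins = s$n_proteins + ns$n_proteins,
           n_go_terms = s$n_go_terms + ns$n_go_terms,
           n_pairs = s$n_pairs + ns$n_pairs,
           n_comentions = s$n_comentions + ns$n_comentions)
  }
  comb$n_comentions <- s$n_comentions + ns$n_comentions
  bind_rows(s, ns, comb)
}
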