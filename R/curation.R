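# Medium-throughput human curation of sentence co-mentions via the brat
# standoff format (v1.3): one sentence per brat document, two entity lines
# (T1 protein, T2 GO concept); the annotator adds a single relation typed
# Good-Comention or Bad-Comention.

#' Build curation records from sentence co-mentions
#'
#' Joins sentence co-mentions with the sentence text and the first matching
#' protein and GO mention spans in that sentence, producing self-contained
#' records ready for brat export. Offsets are sentence-relative, 0-based,
#' half-open.
#'
#' @param comentions Co-mention tibble; only `span == "sentence"` rows are
#'   used.
#' @param mentions Mention tibble covering the same documents.
#' @param sentences Segmented corpus from [segment_corpus()].
#' @return A `curation_records` tibble: `record_id`, `protein`, `go_id`,
#'   `doc_id`, `sentence_index`, `sentence`, `protein_start`, `protein_end`,
#'   `protein_surface`, `go_start`, `go_end`, `go_surface`, `label`
#'   (`"unlabeled"` until [import_brat()]).
#' @export
build_curation_records <- function(comentions, mentions, sentences) {
  cm <- comentions |>
    filter(.data$span == "sentence") |>
    select("protein", "go_id", "doc_id", sentence_index = "protein_sentence")
  first_mention <- function(kind_val, id_col) {
    mentions |>
      filter(.data$kind == kind_val) |>
      arrange(.data$doc_id, .data$sentence_index, .data$start) |>
      distinct(.data$doc_id, .data$sentence_index, .data$concept_id,
               .keep_all = TRUE) |>
      select("doc_id", "sentence_index", concept_id = "concept_id",
             "start", "end", "surface")
  }
  prot <- first_mention("protein") |>
    rename(protein = "concept_id", protein_start = "start",
           protein_end = "end", protein_surface = "surface")
  go <- first_mention("go_term") |>
    rename(go_id = "concept_id", go_start = "start", go_end = "end",
           go_surface = "surface")

  rec <- cm |>
    inner_join(prot, by = c("doc_id", "sentence_index", "protein")) |>
    inner_join(go, by = c("doc_id", "sentence_index", "go_id")) |>
    inner_join(sentences |> select("doc_id", "sentence_index", "sentence",
                                   sentence_start = "start"),
               by = c("doc_id", "sentence_index")) |>
    mutate(
      protein_start = .data$protein_start - .data$sentence_start,
      protein_end = .data$protein_end - .data$sentence_start,
      go_start = .data$go_start - .data$sentence_start,
      go_end = .data$go_end - .data$sentence_start
    ) |>
    select(-"sentence_start") |>
    arrange(.data$doc_id, .data$sentence_index, .data$protein, .data$go_id) |>
    mutate(record_id = sprintf("cm%05d", row_number()), label = "unlabeled") |>
    select("record_id", everything())
  structure(rec, class = c("curation_records", class(tibble())))
}

#' Randomly sample co-mention curation records
#'
#' Uniform sample without replacement under a fixed seed; optionally
#' restricted to one functional class first. Asking for more records than
#' exist returns the whole population with a warning.
#'
#' @param records `curation_records` tibble.
#' @param n Sample size.
#' @param seed Integer seed (the caller's RNG state is untouched).
#' @param go_id Optional GO id filter applied before sampling.
#' @return A `curation_records` tibble of up to `n` rows.
#' @export
sample_comentions <- function(records, n, seed, go_id = NULL) {
  if (!is.null(go_id)) records <- records |> filter(.data$go_id %in% !!go_id)
  if (n > nrow(records)) {
    warn(paste0("requested ", n, " records but only ", nrow(records),
                " available; returning all"))
    return(records)
  }
  if (n == 0) return(records[0, ])
  idx <- with_seed(seed, sample(nrow(records), n))
  records[sort(idx), ]
}

#' Export curation records as brat standoff document pairs
#'
#' Writes one `.txt`/`.ann` pair per record into `dir`, named by
#' `record_id`. The `.txt` holds the single sentence; the `.ann` holds two
#' entity lines (`T1 Protein`, `T2 GO_concept`) whose offsets slice the
#' sentence to the stored surfaces, plus a relation line when the record is
#' already labeled (so export/import round-trips).
#'
#' @param records `curation_records` tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_brat <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    n <- nchar(r$sentence)
    if (r$protein_start < 0 || r$protein_end > n ||
        r$go_start < 0 || r$go_end > n) {
      abort(paste0("record ", r$record_id, ": span outside sentence"))
    }
    writeLines(r$sentence, file.path(dir, paste0(r$record_id, ".txt")))
    ann <- c(
      sprintf("T1\tProtein %d %d\t%s", r$protein_start, r$protein_end,
              r$protein_surface),
      sprintf("T2\tGO_concept %d %d\t%s", r$go_start, r$go_end, r$go_surface)
    )
    if (r$label %in% c("Good", "Bad")) {
      ann <- c(ann, sprintf("R1\t%s-Comention Arg1:T1 Arg2:T2", r$label))
    }
    writeLines(ann, file.path(dir, paste0(r$record_id, ".ann")))
  }
  invisible(dir)
}

#' Import brat relation labels back into curation records
#'
#' Reads each record's `.ann` file from `dir` and sets `label` from its
#' relation line: `Good-Comention` -> `"Good"`, `Bad-Comention` -> `"Bad"`.
#' A file with entities only leaves the record `"unlabeled"`; any other
#' relation type is an error naming it.
#'
#' @param records `curation_records` previously passed to [export_brat()].
#' @param dir Directory holding the `.ann` files.
#' @return The records with `label` filled in.
#' @export
import_brat <- function(records, dir) {
  labels <- records$label
  for (i in seq_len(nrow(records))) {
    path <- file.path(dir, paste0(records$record_id[i], ".ann"))
    if (!file.exists(path)) {
      abort(paste0("missing annotation file: ", path))
    }
    lines <- readLines(path, encoding = "UTF-8")
    rel <- lines[startsWith(lines, "R")]
    if (!length(rel)) { labels[i] <- "unlabeled"; next }
    type <- str_match(rel[1], "^R\\d+\t(\\S+)")[, 2]
    if (identical(type, "Good-Comention")) labels[i] <- "Good"
    else if (identical(type, "Bad-Comention")) labels[i] <- "Bad"
    else abort(paste0("unknown relation type '", type, "' in ", path))
  }
  records$label <- labels
  records
}

#' Per-class precision of curated co-mentions
#'
#' Among labeled records of one functional class, the fraction labeled Good:
#' `precision = n_good / n_total`.
#'
#' @param records Labeled `curation_records`.
#' @param go_id The functional class to score.
#' @param ontology Optional `go_ontology`; with
#'   `include_descendants = TRUE`, records of descendant terms count too.
#' @param include_descendants Include co-mentions of descendant terms
#'   (default FALSE).
#' @return A one-row tibble: `go_id`, `n_good`, `n_total`, `precision`.
#' @export
class_precision <- function(records, go_id, ontology = NULL,
                            include_descendants = FALSE) {
  ids <- go_id
  if (include_descendants) {
    stopifnot(inherits(ontology, "go_ontology"))
    desc <- names(ontology$ancestors)[
      vapply(ontology$ancestors, function(a) go_id %in% a, logical(1))]
    ids <- c(go_id, desc)
  }
  sel <- records |> filter(.data$go_id %in% ids)
  if (any(sel$label == "unlabeled")) {
    abort("records must all be labeled before computing class precision")
  }
  if (!nrow(sel)) abort(paste0("no labeled co-mentions for ", go_id))
  n_good <- sum(sel$label == "Good")
  tibble(go_id = go_id, n_good = n_good, n_total = nrow(sel),
         precision = n_good / nrow(sel))
}
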