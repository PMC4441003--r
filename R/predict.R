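# Gold-annotation loading (GAF), the co-mentions-as-classifier baseline,
# a flat per-term linear classifier with cross-validation, and hierarchy
# consistency for prediction scores.

#' Experimental-evidence GAF codes
#'
#' The default evidence-code allow-list: only experimentally derived
#' annotations (EXP, IDA, IPI, IMP, IGI, IEP, TAS) are kept.
#'
#' @return Character vector of evidence codes.
#' @export
gaf_experimental_codes <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS")
}

#' Load gold annotations from a GAF file
#'
#' Reads GAF 2.x, keeping only rows whose evidence code is in the
#' allow-list, dropping NOT-qualified rows, dropping the overly broad
#' protein-binding term GO:0005515 regardless of evidence, and dropping
#' terms absent from or obsolete in the ontology (with a message).
#'
#' @param path GAF path (tab-separated, `!` comment lines).
#' @param ontology A `go_ontology`.
#' @param evidence_codes Allow-list; default [gaf_experimental_codes()].
#' @param exclude_terms Term ids removed regardless of evidence; default
#'   `"GO:0005515"`.
#' @return A tibble: `protein`, `go_id`, `evidence` (distinct rows).
#' @export
read_gaf <- function(path, ontology,
                     evidence_codes = gaf_experimental_codes(),
                     exclude_terms = "GO:0005515") {
  stopifnot(inherits(ontology, "go_ontology"))
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "!") & nzchar(str_trim(lines))
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 15L)
  if (length(bad)) {
    abort(paste0("malformed GAF row at line ", lineno[bad[1]],
                 " (expected >= 15 tab-separated columns, got ",
                 lengths(parts)[bad[1]], ")"))
  }
  if (!length(parts)) {
    return(tibble(protein = character(), go_id = character(),
                  evidence = character()))
  }
  gaf <- tibble(
    protein = vapply(parts, `[`, "", 2L),
    qualifier = vapply(parts, `[`, "", 4L),
    go_id = vapply(parts, `[`, "", 5L),
    evidence = vapply(parts, `[`, "", 7L)
  )
  gaf <- gaf |>
    filter(.data$evidence %in% evidence_codes,
           !.data$go_id %in% exclude_terms,
           !grepl("(^|\\|)NOT($|\\|)", .data$qualifier))
  live <- names(ontology$ancestors)
  missing <- setdiff(unique(gaf$go_id), live)
  if (length(missing)) {
    inform(paste0("dropping ", sum(gaf$go_id %in% missing),
                  " annotation(s) to term(s) absent/obsolete in ontology: ",
                  paste(missing, collapse = ", ")))
    gaf <- gaf |> filter(!.data$go_id %in% missing)
  }
  gaf |> distinct(.data$protein, .data$go_id, .data$evidence)
}

#' Co-mentions-as-classifier baseline
#'
#' Uses the co-mention counts themselves as prediction scores, with no
#' learning: score(protein, term) is the co-mention count under the chosen
#' span mode, min-max normalized over the whole table to [0, 1] so
#' confidence-threshold sweeps are meaningful.
#'
#' @param features A `feature_table` containing `co_`/`nco_` keys.
#' @param mode `"combined"` (sentence + non-sentence sum), `"sentence"`, or
#'   `"non_sentence"`.
#' @param normalize Min-max normalize counts to [0, 1] (default TRUE; when
#'   all counts are equal every score is 1).
#' @return A `prediction_set`: tibble `protein`, `go_id`, `score`.
#' @export
baseline_predict <- function(features, mode = c("combined", "sentence",
                                                "non_sentence"),
                             normalize = TRUE) {
  mode <- match.arg(mode)
  cm <- features |>
    filter(grepl("^n?co_GO:", .data$feature)) |>
    mutate(span = ifelse(startsWith(.data$feature, "nco_"),
                         "non_sentence", "sentence"),
           go_id = sub("^n?co_", "", .data$feature))
  if (!nrow(cm)) abort("feature table contains no co_/nco_ features")
  cm <- switch(mode,
    sentence = filter(cm, .data$span == "sentence"),
    non_sentence = filter(cm, .data$span == "non_sentence"),
    combined = cm
  )
  scores <- cm |>
    group_by(.data$protein, .data$go_id) |>
    summarise(score = sum(.data$count), .groups = "drop")
  if (normalize && nrow(scores)) {
    rng <- range(scores$score)
    scores$score <- if (rng[1] == rng[2]) rep(1, nrow(scores)) else
      (scores$score - rng[1]) / (rng[2] - rng[1])
  }
  new_prediction_set(scores)
}

new_prediction_set <- function(tbl) {
  structure(arrange(tbl, .data$protein, .data$go_id),
            class = c("prediction_set", class(tibble())))
}

#' Flat per-term linear classifier with cross-validation
#'
#' A deliberately simple supervised multi-label stand-in: one-vs-rest
#' ridge-regularized logistic regression (glmnet) per GO term on the sparse
#' feature table, scored by out-of-fold predicted probabilities (already in
#' [0, 1]). Labels are the true-path-expanded gold sets; target terms are
#' restricted to those with at least `min_annotations` annotated proteins.
#' Terms with a single class overall are skipped with a warning.
#'
#' @param features A `feature_table`.
#' @param gold Gold annotation tibble (`protein`, `go_id`).
#' @param ontology A `go_ontology` (for true-path label expansion).
#' @param folds Number of cross-validation folds (default 5).
#' @param min_annotations Minimum annotated proteins per target term
#'   (default 10).
#' @param seed Integer seed controlling fold assignment; the whole procedure
#'   is deterministic given it.
#' @param lambda Ridge penalty (default 1e-3).
#' @return A `prediction_set` (`protein`, `go_id`, `score`), with skipped
#'   term ids in attribute `skipped_terms`.
#' @export
train_predict_flat <- function(features, gold, ontology, folds = 5,
                               min_annotations = 10, seed = 1,
                               lambda = 1e-3) {
  stopifnot(inherits(ontology, "go_ontology"))
  proteins <- sort(unique(c(features$protein, gold$protein)))
  n <- length(proteins)
  if (n < 2L * folds) abort("need at least 2 proteins per fold")

  feats <- sort(unique(features$feature))
  x <- Matrix::sparseMatrix(
    i = match(features$protein, proteins),
    j = match(features$feature, feats),
    x = as.numeric(features$count),
    dims = c(n, length(feats)),
    dimnames = list(proteins, feats)
  )

  expanded <- gold |>
    distinct(.data$protein, .data$go_id) |>
    group_by(.data$protein) |>
    reframe(go_id = expand_true_path(ontology, .data$go_id))
  targets <- expanded |>
    count(.data$go_id) |>
    filter(.data$n >= min_annotations) |>
    pull(.data$go_id)
  if (!length(targets)) abort("no target terms with enough annotations")

  fold_of <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  skipped <- character(0)
  preds <- list()
  for (g in targets) {
    y <- as.integer(proteins %in% expanded$protein[expanded$go_id == g])
    if (length(unique(y)) < 2L) {
      skipped <- c(skipped, g)
      next
    }
    score <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      te <- !tr
      if (min(table(y[tr])) < 2L) {
        score[te] <- mean(y[tr])           # degenerate training fold
        next
      }
      fit <- suppressWarnings(
        glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                       family = "binomial", alpha = 0,
                       lambda = c(10 * lambda, lambda),
                       standardize = FALSE))
      score[te] <- as.numeric(
        stats::predict(fit, x[te, , drop = FALSE], s = lambda,
                       type = "response"))
    }
    preds[[g]] <- tibble(protein = proteins, go_id = g, score = score)
  }
  if (length(skipped)) {
    warn(paste0("skipped single-class term(s): ",
                paste(skipped, collapse = ", ")))
  }
  res <- bind_rows(preds)
  if (!nrow(res)) abort("no terms could be trained")
  structure(new_prediction_set(res), skipped_terms = skipped)
}

#' Make prediction scores consistent with the hierarchy
#'
#' Replaces each term's score by the maximum over the term and all its
#' descendants, so scores are monotone non-increasing from root to leaf and
#' thresholding at any level yields a true-path-closed prediction set.
#' Idempotent.
#'
#' @param predictions A `prediction_set` (`protein`, `go_id`, `score`).
#' @param ontology A `go_ontology`.
#' @return A `prediction_set` covering the input terms and all their
#'   ancestors.
#' @export
enforce_hierarchy <- function(predictions, ontology) {
  stopifnot(inherits(ontology, "go_ontology"))
  if (!nrow(predictions)) return(new_prediction_set(predictions))
  expanded <- predictions |>
    mutate(.anc = map(.data$go_id, function(g)
      c(g, go_ancestors(ontology, g)))) |>
    tidyr::unnest(".anc") |>
    group_by(.data$protein, go_id = .data$.anc) |>
    summarise(score = max(.data$score), .groups = "drop")
  new_prediction_set(expanded)
}
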