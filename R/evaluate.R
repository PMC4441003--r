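# Hierarchical (true-path) evaluation: micro precision/recall, F-max over a
# confidence sweep, macro-averaged per-term ROC AUC, and depth/IC-binned
# functional-class reports. Both gold annotations and predictions are
# expanded to the root before comparison; exact-match evaluation understates
# performance because near-miss predictions share most of their ancestry
# with the gold terms.

# Expand a gold table to its true-path closure (one row per protein, term).
expand_gold <- function(gold, ontology) {
  gold |>
    distinct(.data$protein, .data$go_id) |>
    group_by(.data$protein) |>
    reframe(go_id = expand_true_path(ontology, .data$go_id))
}

# Pooled TP/FP/FN at one threshold from pre-expanded tables.
micro_counts <- function(pred, gold, threshold, recall_over) {
  at <- pred[pred$score >= threshold, c("protein", "go_id")]
  tp_tbl <- inner_join(at, gold, by = c("protein", "go_id"))
  tp <- nrow(tp_tbl)
  fp <- nrow(at) - tp
  gold_denom <- if (recall_over == "predicted") {
    gold |> semi_join(distinct(at, .data$protein), by = "protein")
  } else gold
  fn <- nrow(gold_denom) - nrow(inner_join(at, gold_denom,
                                           by = c("protein", "go_id")))
  list(tp = tp, fp = fp, fn = fn, n_predicted = nrow(at))
}

#' Micro-averaged precision and recall at a threshold
#'
#' Pools true/false positives and false negatives over all proteins after
#' true-path expansion of both predictions and gold. Precision is computed
#' over proteins with at least one prediction at the threshold (its pooled
#' denominator only contains predicted pairs); recall over all gold
#' proteins, or only gold proteins with a prediction when
#' `recall_over = "predicted"`. With no predictions at the threshold,
#' precision is reported as 0 with `no_predictions = TRUE`.
#'
#' @param predictions A `prediction_set`.
#' @param gold Gold annotation tibble (`protein`, `go_id`).
#' @param ontology A `go_ontology`.
#' @param threshold Score threshold; pairs with `score >= threshold` count
#'   as predicted.
#' @param recall_over `"all"` (default) or `"predicted"`.
#' @param expand Set FALSE if both inputs are already true-path expanded.
#' @return A one-row tibble: `precision`, `recall`, `tp`, `fp`, `fn`,
#'   `no_predictions`.
#' @export
micro_pr <- function(predictions, gold, ontology, threshold = 0,
                     recall_over = c("all", "predicted"), expand = TRUE) {
  recall_over <- match.arg(recall_over)
  if (expand) {
    predictions <- enforce_hierarchy(predictions, ontology)
    gold <- expand_gold(gold, ontology)
  }
  ct <- micro_counts(predictions, gold, threshold, recall_over)
  tibble(
    precision = if (ct$n_predicted == 0) 0 else ct$tp / (ct$tp + ct$fp),
    recall = if ((ct$tp + ct$fn) == 0) 0 else ct$tp / (ct$tp + ct$fn),
    tp = ct$tp, fp = ct$fp, fn = ct$fn,
    no_predictions = ct$n_predicted == 0
  )
}

#' F-max evaluation over a confidence sweep
#'
#' Sweeps the threshold over the distinct prediction scores (plus 0) --
#' micro precision/recall are step functions of the threshold, so this
#' sweep attains the exact maximum of the harmonic mean. Returns the
#' maximizing threshold (smallest, on ties), the precision/recall there,
#' per-term metrics at that threshold, the full sweep curve, and the
#' macro-averaged per-term AUC.
#'
#' @inheritParams micro_pr
#' @param namespace Restrict evaluation to one GO namespace (each branch of
#'   GO is normally evaluated separately); NULL evaluates everything pooled.
#' @param min_annotations Minimum expanded-gold annotations for a term to
#'   enter the macro-AUC average (default 10).
#' @param with_auc Compute the macro-AUC (default TRUE; set FALSE to skip).
#' @return A `litgo_eval` object; see [glance.litgo_eval()] and
#'   [tidy.litgo_eval()].
#' @export
fmax_eval <- function(predictions, gold, ontology, namespace = NULL,
                      recall_over = c("all", "predicted"),
                      min_annotations = 10, with_auc = TRUE) {
  recall_over <- match.arg(recall_over)
  ns_of <- setNames(ontology$terms$namespace, ontology$terms$id)
  if (!is.null(namespace)) {
    predictions <- predictions |> filter(ns_of[.data$go_id] %in% namespace)
    gold <- gold |> filter(ns_of[.data$go_id] %in% namespace)
  }
  if (!nrow(gold)) abort("no gold annotations to evaluate against")
  pred_x <- enforce_hierarchy(predictions, ontology)
  gold_x <- expand_gold(gold, ontology)

  taus <- sort(unique(c(0, pred_x$score)))
  curve <- bind_rows(lapply(taus, function(tau) {
    ct <- micro_counts(pred_x, gold_x, tau, recall_over)
    p <- if (ct$n_predicted == 0) 0 else ct$tp / (ct$tp + ct$fp)
    r <- if ((ct$tp + ct$fn) == 0) 0 else ct$tp / (ct$tp + ct$fn)
    tibble(threshold = tau, precision = p, recall = r,
           f = if (p + r == 0) 0 else 2 * p * r / (p + r))
  }))
  best <- which.max(curve$f)  # first (= smallest threshold) on ties
  tau_star <- curve$threshold[best]

  at <- pred_x[pred_x$score >= tau_star, c("protein", "go_id")]
  per_term <- full_join(
    at |> mutate(predicted = TRUE),
    gold_x |> mutate(annotated = TRUE),
    by = c("protein", "go_id")
  ) |>
    mutate(predicted = !is.na(.data$predicted),
           annotated = !is.na(.data$annotated)) |>
    group_by(.data$go_id) |>
    summarise(
      tp = sum(.data$predicted & .data$annotated),
      fp = sum(.data$predicted & !.data$annotated),
      fn = sum(!.data$predicted & .data$annotated),
      .groups = "drop"
    ) |>
    mutate(
      n_predictions = .data$tp + .data$fp,
      n_gold = .data$tp + .data$fn,
      precision = ifelse(.data$n_predictions > 0,
                         .data$tp / .data$n_predictions, 0),
      recall = ifelse(.data$n_gold > 0, .data$tp / .data$n_gold, 0),
      f = ifelse(.data$precision + .data$recall > 0,
                 2 * .data$precision * .data$recall /
                   (.data$precision + .data$recall), 0)
    )

  auc <- if (with_auc) {
    tryCatch(
      macro_auc(predictions, gold, ontology,
                min_annotations = min_annotations,
                namespace = namespace),
      error = function(e) NA_real_
    )
  } else NA_real_

  structure(
    list(fmax = curve$f[best], precision = curve$precision[best],
         recall = curve$recall[best], threshold = tau_star,
         macro_auc = auc, per_term = per_term, curve = curve,
         recall_over = recall_over, namespace = namespace,
         n_proteins = n_distinct(gold$protein)),
    class = "litgo_eval"
  )
}

#' @export
print.litgo_eval <- function(x, ...) {
  cat("<litgo_eval>",
      if (!is.null(x$namespace)) paste0(" [", paste(x$namespace, collapse = ","), "]"),
      "\n  F-max ", signif(x$fmax, 4),
      " at threshold ", signif(x$threshold, 4),
      " (P ", signif(x$precision, 4), ", R ", signif(x$recall, 4), ")",
      "\n  macro-AUC ", signif(x$macro_auc, 4),
      " over ", x$n_proteins, " proteins, ",
      nrow(x$per_term), " terms\n", sep = "")
  invisible(x)
}

#' Macro-averaged per-term ROC AUC
#'
#' For each GO term with at least `min_annotations` positive proteins in the
#' expanded gold standard (and at least one negative), computes the ROC AUC
#' of the expanded prediction scores (absent predictions score 0) over the
#' gold-standard protein set, then averages unweighted across terms. The
#' result is invariant to any strictly monotone transform of the scores.
#'
#' @inheritParams fmax_eval
#' @return A single number in [0, 1].
#' @export
macro_auc <- function(predictions, gold, ontology, min_annotations = 10,
                      namespace = NULL) {
  ns_of <- setNames(ontology$terms$namespace, ontology$terms$id)
  if (!is.null(namespace)) {
    predictions <- predictions |> filter(ns_of[.data$go_id] %in% namespace)
    gold <- gold |> filter(ns_of[.data$go_id] %in% namespace)
  }
  if (!nrow(gold)) abort("no gold annotations")
  pred_x <- enforce_hierarchy(predictions, ontology)
  gold_x <- expand_gold(gold, ontology)
  proteins <- unique(gold$protein)

  counts <- gold_x |> count(.data$go_id)
  terms <- counts$go_id[counts$n >= min_annotations &
                          counts$n < length(proteins)]
  if (!length(terms)) {
    abort("no terms qualify for macro-AUC (need both classes and enough annotations)")
  }
  aucs <- vapply(terms, function(g) {
    labels <- as.integer(proteins %in% gold_x$protein[gold_x$go_id == g])
    sc <- pred_x[pred_x$go_id == g, ]
    scores <- setNames(rep(0, length(proteins)), proteins)
    scores[sc$protein[sc$protein %in% proteins]] <-
      sc$score[sc$protein %in% proteins]
    as.numeric(pROC::auc(pROC::roc(labels, unname(scores), quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  mean(aucs)
}

#' Bin per-term F-measures by depth or information content
#'
#' Macro-averages the per-term F-measure within each depth value or each
#' unit-width, half-open IC interval `[k, k+1)`. Terms absent from the
#' depth/IC table are excluded and recorded in the `missing` attribute;
#' empty bins are omitted.
#'
#' @param eval A `litgo_eval` (or a tibble with `go_id` and `f` columns).
#' @param table [term_depths()] output (`axis = "depth"`) or [term_ic()]
#'   output (`axis = "ic"`).
#' @param axis `"depth"` or `"ic"`.
#' @return A `litgo_binned` tibble: `axis`, `bin` (lower edge), `bin_label`,
#'   `n_terms`, `mean_f`.
#' @export
binned_report <- function(eval, table, axis = c("depth", "ic")) {
  axis <- match.arg(axis)
  per_term <- if (inherits(eval, "litgo_eval")) eval$per_term else eval
  stopifnot(all(c("go_id", "f") %in% names(per_term)))
  value_col <- if (axis == "depth") "depth" else "ic"
  stopifnot(value_col %in% names(table))

  joined <- per_term |>
    left_join(table |> select(go_id = "id", value = all_of(value_col)),
              by = "go_id")
  missing <- joined$go_id[is.na(joined$value)]
  joined <- joined |> filter(!is.na(.data$value))
  joined$bin <- if (axis == "depth") joined$value else floor(joined$value)
  is_depth <- axis == "depth"
  res <- joined |>
    group_by(.data$bin) |>
    summarise(n_terms = n(), mean_f = mean(.data$f), .groups = "drop") |>
    mutate(axis = .env$axis,
           bin_label = if (is_depth) as.character(.data$bin) else
             paste0("[", .data$bin, ",", .data$bin + 1, ")")) |>
    select("axis", "bin", "bin_label", "n_terms", "mean_f") |>
    arrange(.data$bin)
  structure(res, class = c("litgo_binned", class(tibble())),
            missing = missing)
}
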