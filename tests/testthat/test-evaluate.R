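# Hierarchical evaluation: micro P/R, F-max sweep, macro-AUC, binned reports.

pset <- function(protein, go_id, score) {
  structure(tibble::tibble(protein = protein, go_id = go_id, score = score),
            class = c("prediction_set", class(tibble::tibble())))
}

test_that("micro precision/recall pool expanded counts over proteins", {
  ont <- fixture_ontology()
  gold <- tibble::tibble(protein = c("P1", "P2", "P3"),
                         go_id = c("GO:0000460", "GO:0009987", "GO:0043705"))

  perfect <- pset(gold$protein, gold$go_id, 1)
  pr <- micro_pr(perfect, gold, ont, threshold = 0.5)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)

  none <- pset(character(), character(), numeric())
  pr0 <- micro_pr(none, gold, ont, threshold = 0)
  expect_equal(pr0$recall, 0)
  expect_equal(pr0$precision, 0)
  expect_true(pr0$no_predictions)

  # hand-pooled counts: expanded gold sets are
  #   P1: {460, 6364, 9987, 8150}  P2: {9987, 8150}  P3: {43705, 8152, 8150}
  # predictions: P1 -> 6364 (expands to {6364, 9987, 8150}; 3 TP, 0 FP)
  #              P2 -> 43705 (expands to {43705, 8152, 8150}; 1 TP, 2 FP)
  pred <- pset(c("P1", "P2"), c("GO:0006364", "GO:0043705"), 1)
  prh <- micro_pr(pred, gold, ont, threshold = 1)
  expect_equal(prh$tp, 4)
  expect_equal(prh$fp, 2)
  expect_equal(prh$fn, 5)
  expect_equal(prh$precision, 4 / 6)
  expect_equal(prh$recall, 4 / 9)

  # recall restricted to proteins with predictions drops P3's gold terms
  prr <- micro_pr(pred, gold, ont, threshold = 1, recall_over = "predicted")
  expect_equal(prr$recall, 4 / 6)
})

test_that("expansion before comparison never lowers recall", {
  set.seed(4)
  for (seed in 1:5) {
    ro <- random_ontology(seed)
    prots <- paste0("P", 1:6)
    gold <- tibble::tibble(
      protein = rep(prots, each = 2),
      go_id = sample(ro$terms$id, 12, replace = TRUE))
    pred <- pset(rep(prots, each = 2),
                 sample(ro$terms$id, 12, replace = TRUE), 1)
    expanded <- micro_pr(pred, gold, ro, threshold = 0)
    exact <- {
      at <- unique(tibble::as_tibble(pred)[, c("protein", "go_id")])
      g <- unique(gold)
      tp <- nrow(dplyr::inner_join(at, g, by = c("protein", "go_id")))
      tp / nrow(g)
    }
    expect_gte(expanded$recall, exact)
  }
})

test_that("F-max equals the dense-grid oracle and behaves at the extremes", {
  ont <- fixture_ontology()
  gold <- tibble::tibble(protein = c("P1", "P2"),
                         go_id = c("GO:0000460", "GO:0043705"))
  perfect <- pset(gold$protein, gold$go_id, c(0.7, 0.9))
  ev <- fmax_eval(perfect, gold, ont, with_auc = FALSE)
  expect_equal(ev$fmax, 1)
  expect_true(ev$fmax >= max(ev$curve$f))          # fmax is the sweep max

  # two-threshold toy set against the grid oracle
  toy <- pset(c("P1", "P1", "P2"),
              c("GO:0000460", "GO:0043705", "GO:0009987"),
              c(0.9, 0.3, 0.6))
  ev2 <- fmax_eval(toy, gold, ont, with_auc = FALSE)
  expect_equal(ev2$fmax, oracle_fmax_grid(toy, gold, ont), tolerance = 1e-9)

  # random instances, scores on a coarse lattice so every plateau is sampled
  for (seed in 1:50) {
    set.seed(seed)
    ro <- random_ontology(seed %% 7 + 1)
    prots <- paste0("P", 1:5)
    gold_r <- tibble::tibble(protein = rep(prots, each = 2),
                             go_id = sample(ro$terms$id, 10, replace = TRUE))
    pred_r <- pset(sample(prots, 8, replace = TRUE),
                   sample(ro$terms$id, 8, replace = TRUE),
                   sample(seq(0.05, 1, by = 0.05), 8, replace = TRUE))
    pred_r <- structure(dplyr::distinct(pred_r, protein, go_id,
                                        .keep_all = TRUE),
                        class = class(pred_r))
    ev_r <- fmax_eval(pred_r, gold_r, ro, with_auc = FALSE)
    expect_equal(ev_r$fmax, oracle_fmax_grid(pred_r, gold_r, ro),
                 tolerance = 1e-9)
    expect_true(all(ev_r$fmax >= ev_r$curve$f - 1e-12))
  }

  # a strictly dominated prediction (low score, no gold overlap, its own
  # protein) never increases F-max
  dominated <- structure(
    dplyr::bind_rows(tibble::as_tibble(toy),
                     tibble::tibble(protein = "P9", go_id = "GO:0005488",
                                    score = 0.01)),
    class = class(toy))
  ev3 <- fmax_eval(dominated, gold, ont, with_auc = FALSE)
  expect_lte(ev3$fmax, ev2$fmax)
})

test_that("macro-AUC averages qualifying terms and ignores score scale", {
  ont <- fixture_ontology()
  set.seed(10)
  prots <- paste0("P", 1:20)
  gold <- tibble::tibble(
    protein = prots,
    go_id = sample(c("GO:0000460", "GO:0043705"), 20, replace = TRUE))
  perfect <- pset(gold$protein, gold$go_id, 1)
  expect_equal(macro_auc(perfect, gold, ont, min_annotations = 2), 1)

  # min_annotations excludes sparse terms: with the threshold above the
  # smaller class size, only the bigger branch's terms qualify
  n460 <- sum(gold$go_id == "GO:0000460")
  expect_error(macro_auc(perfect, gold, ont, min_annotations = 21),
               "qualify")

  # invariant to strictly monotone transforms
  scrambled <- pset(perfect$protein, perfect$go_id, perfect$score)
  rnd <- pset(sample(prots, 15), sample(c("GO:0000460", "GO:0043705"), 15,
                                        replace = TRUE),
              stats::runif(15))
  a1 <- macro_auc(rnd, gold, ont, min_annotations = 2)
  rnd2 <- pset(rnd$protein, rnd$go_id, plogis(5 * rnd$score - 2))
  expect_equal(macro_auc(rnd2, gold, ont, min_annotations = 2), a1,
               tolerance = 1e-12)

  # random scores vs random labels: chance level over seeds
  aucs <- vapply(1:3, function(s) {
    set.seed(s)
    prots200 <- paste0("P", 1:200)
    g <- tibble::tibble(protein = prots200,
                        go_id = sample(c("GO:0000460", "GO:0043705",
                                         "GO:0007566"), 200, replace = TRUE))
    pr <- pset(rep(prots200, 2),
               sample(c("GO:0000460", "GO:0043705", "GO:0007566"), 400,
                      replace = TRUE),
               stats::runif(400))
    pr <- structure(dplyr::distinct(pr, protein, go_id, .keep_all = TRUE),
                    class = class(pr))
    macro_auc(pr, g, ont, min_annotations = 10)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("binned reports macro-average per depth value and unit IC bin", {
  per_term <- tibble::tibble(
    go_id = c("GO:0009987", "GO:0008152", "GO:0000460"),
    f = c(0.8, 0.6, 0.4))
  depths <- tibble::tibble(id = per_term$go_id, depth = c(1L, 1L, 3L))
  rep_d <- binned_report(per_term, depths, axis = "depth")
  expect_equal(rep_d$bin, c(1, 3))
  expect_equal(rep_d$mean_f, c(0.7, 0.4))
  expect_equal(rep_d$n_terms, c(2L, 1L))

  # all terms in one depth bin: the bin mean is the plain macro-average
  d1 <- tibble::tibble(id = per_term$go_id, depth = 1L)
  rep_1 <- binned_report(per_term, d1, axis = "depth")
  expect_equal(nrow(rep_1), 1)
  expect_equal(rep_1$mean_f, mean(per_term$f))

  ics <- tibble::tibble(id = per_term$go_id, ic = c(0.2, 1.9, 1.1))
  rep_ic <- binned_report(per_term, ics, axis = "ic")
  expect_equal(rep_ic$bin_label, c("[0,1)", "[1,2)"))
  expect_equal(rep_ic$n_terms, c(1L, 2L))
  expect_equal(rep_ic$mean_f[2], mean(c(0.6, 0.4)))
  # partition: bin counts add up to the evaluated term count
  expect_equal(sum(rep_ic$n_terms), nrow(per_term))

  # terms missing from the table are excluded and reported
  rep_m <- binned_report(per_term, depths[1:2, ], axis = "depth")
  expect_equal(attr(rep_m, "missing"), "GO:0000460")
  expect_equal(sum(rep_m$n_terms), 2)
})
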