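# Fixtures built in code and independent brute-force oracles. The oracles
# deliberately use naive enumeration so they share no code with the
# implementation they check.

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# A small GO-like ontology exercising both namespaces, a curated synonym,
# an "activity" name, and an obsolete term.
fixture_obo_text <- function() {
  c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0008150", "name: biological process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0009987", "name: cellular process",
    "namespace: biological_process", "is_a: GO:0008150 ! biological process", "",
    "[Term]", "id: GO:0008152", "name: metabolic process",
    "namespace: biological_process", "is_a: GO:0008150", "",
    "[Term]", "id: GO:0043705", "name: cyanophycin metabolic process",
    "namespace: biological_process", "is_a: GO:0008152", "",
    "[Term]", "id: GO:0043065", "name: positive regulation of apoptosis",
    "namespace: biological_process", "is_a: GO:0008150", "",
    "[Term]", "id: GO:0006364", "name: rRNA processing",
    "namespace: biological_process", "is_a: GO:0009987", "",
    "[Term]", "id: GO:0000460", "name: maturation of 5.8S rRNA",
    "namespace: biological_process", "is_a: GO:0006364", "",
    "[Term]", "id: GO:0007566", "name: embryo implantation",
    "namespace: biological_process",
    "synonym: \"implantation\" EXACT []",
    "is_a: GO:0009987", "",
    "[Term]", "id: GO:0003674", "name: molecular function",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0016301", "name: kinase activity",
    "namespace: molecular_function", "is_a: GO:0003674", "",
    "[Term]", "id: GO:0005488", "name: binding",
    "namespace: molecular_function", "is_a: GO:0003674", "",
    "[Term]", "id: GO:0099999", "name: gone term",
    "namespace: biological_process", "is_obsolete: true", ""
  )
}

fixture_ontology <- function() {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(fixture_obo_text(), path)
  read_obo(path)
}

# Diamond: a -> {b, c} -> d (root).
diamond_ontology <- function() {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(c(
    "[Term]", "id: GO:0000004", "name: d", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: b", "namespace: biological_process",
    "is_a: GO:0000004", "",
    "[Term]", "id: GO:0000003", "name: c", "namespace: biological_process",
    "relationship: part_of GO:0000004", "",
    "[Term]", "id: GO:0000001", "name: a", "namespace: biological_process",
    "is_a: GO:0000002", "is_a: GO:0000003", ""
  ), path)
  read_obo(path)
}

random_ontology <- function(seed, n_terms = 15) {
  make_toy_ontology(synth_config(n_terms = n_terms, seed = seed))
}

# Brute-force transitive closure over the edge table (fixpoint iteration).
oracle_ancestors <- function(ontology, term) {
  edges <- ontology$edges
  acc <- character(0)
  frontier <- term
  repeat {
    parents <- unique(edges$parent[edges$id %in% frontier])
    new <- setdiff(parents, acc)
    if (!length(new)) break
    acc <- c(acc, new)
    frontier <- new
  }
  sort(acc)
}

# Brute-force shortest root-to-term path length: enumerate all upward paths.
oracle_depth <- function(ontology, term) {
  edges <- ontology$edges
  roots <- unname(ontology$roots)
  best <- Inf
  walk <- function(node, d) {
    if (node %in% roots) { best <<- min(best, d); return() }
    for (p in edges$parent[edges$id == node]) walk(p, d + 1L)
  }
  walk(term, 0L)
  best
}

# Brute-force dictionary matcher: enumerate every token window, keep
# dictionary hits, then apply longest/leftmost suppression.
oracle_match <- function(sentence, surfaces) {
  toks <- tokenize_spans(sentence)
  nt <- nrow(toks)
  if (!nt) return(tibble::tibble(start = integer(), end = integer()))
  cand <- list()
  for (i in seq_len(nt)) {
    for (j in i:nt) {
      key <- paste(tolower(toks$token[i:j]), collapse = " ")
      if (key %in% surfaces) {
        cand[[length(cand) + 1L]] <- c(i = i, j = j)
      }
    }
  }
  if (!length(cand)) return(tibble::tibble(start = integer(), end = integer()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, "i"], -(cand[, "j"] - cand[, "i"])), ,
               drop = FALSE]
  taken <- rep(FALSE, nt)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    span <- seq(cand[r, "i"], cand[r, "j"])
    if (!any(taken[span])) { keep[r] <- TRUE; taken[span] <- TRUE }
  }
  sel <- cand[keep, , drop = FALSE]
  tibble::tibble(start = toks$start[sel[, "i"]], end = toks$end[sel[, "j"]])
}

# Brute-force co-mention enumeration over all sentence combinations.
oracle_comentions <- function(mentions) {
  prot <- mentions[mentions$kind == "protein", ]
  go <- mentions[mentions$kind == "go_term", ]
  rows <- list()
  for (doc in unique(mentions$doc_id)) {
    dp <- prot[prot$doc_id == doc, ]
    dg <- go[go$doc_id == doc, ]
    for (p in unique(dp$concept_id)) {
      ps <- unique(dp$sentence_index[dp$concept_id == p])
      for (g in unique(dg$concept_id)) {
        gs <- unique(dg$sentence_index[dg$concept_id == g])
        for (s in intersect(ps, gs)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            doc_id = doc, protein = p, go_id = g, span = "sentence",
            lo = s, hi = s)
        }
        seen <- character(0)
        for (a in ps) for (b in gs) {
          if (a == b) next
          key <- paste(min(a, b), max(a, b))
          if (key %in% seen) next
          seen <- c(seen, key)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            doc_id = doc, protein = p, go_id = g, span = "non_sentence",
            lo = min(a, b), hi = max(a, b))
        }
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(doc_id = character(), protein = character(),
                          go_id = character(), span = character(),
                          lo = integer(), hi = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), doc_id, protein, go_id, span, lo, hi)
}

# Canonical event form of extract_comentions() output, for set comparison.
canonical_comentions <- function(cm) {
  dplyr::arrange(
    dplyr::transmute(cm, doc_id, protein, go_id, span,
                     lo = pmin(protein_sentence, go_sentence),
                     hi = pmax(protein_sentence, go_sentence)),
    doc_id, protein, go_id, span, lo, hi)
}

# Independent expansion of a protein's scored predictions: every ancestor
# gets the max score over its scored descendants (computed from
# oracle_ancestors, not from the package's closure).
oracle_expand_scores <- function(terms, scores, ontology) {
  cover <- lapply(terms, function(t) c(t, oracle_ancestors(ontology, t)))
  all_terms <- unique(unlist(cover))
  out <- vapply(all_terms, function(a) {
    max(scores[vapply(cover, function(cv) a %in% cv, logical(1))])
  }, numeric(1))
  setNames(out, all_terms)
}

# Dense-grid F-max oracle over a fixed 1000-point threshold grid, built on
# base-R set operations only.
oracle_fmax_grid <- function(predictions, gold, ontology, grid_n = 1000) {
  proteins <- unique(gold$protein)
  pred_sets <- lapply(setNames(nm = unique(predictions$protein)), function(p) {
    sub <- predictions[predictions$protein == p, ]
    oracle_expand_scores(sub$go_id, sub$score, ontology)
  })
  gold_sets <- lapply(setNames(nm = proteins), function(p) {
    g <- unique(gold$go_id[gold$protein == p])
    unique(c(g, unlist(lapply(g, oracle_ancestors, ontology = ontology))))
  })
  n_gold <- sum(lengths(gold_sets))
  best <- 0
  for (tau in seq(0, 1, length.out = grid_n)) {
    tp <- 0L; n_pred <- 0L
    for (p in names(pred_sets)) {
      P <- names(pred_sets[[p]])[pred_sets[[p]] >= tau]
      n_pred <- n_pred + length(P)
      G <- gold_sets[[p]]
      if (!is.null(G)) tp <- tp + length(intersect(P, G))
    }
    prec <- if (n_pred == 0) 0 else tp / n_pred
    rec <- if (n_gold == 0) 0 else tp / n_gold
    f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    best <- max(best, f)
  }
  best
}

# Brute-force descendant-max score propagation.
oracle_hierarchy_max <- function(predictions, ontology) {
  rows <- list()
  for (p in unique(predictions$protein)) {
    sub <- predictions[predictions$protein == p, ]
    sc <- oracle_expand_scores(sub$go_id, sub$score, ontology)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      protein = p, go_id = names(sc), score = unname(sc))
  }
  dplyr::arrange(dplyr::bind_rows(rows), protein, go_id)
}

# A 20-row GAF fixture: 9 rows carry allowed evidence codes, of which one
# annotates GO:0005515 and one is NOT-qualified, leaving 7 survivors.
fixture_gaf <- function(path) {
  allowed <- gaf_experimental_codes()
  mk <- function(prot, qual, go, ev) {
    paste(c("DB", prot, prot, qual, go, "REF:1", ev, "", "P", "", "",
            "protein", "taxon:9606", "20130101", "DB", "", ""),
          collapse = "\t")
  }
  rows <- c(
    mk("P1", "enables", "GO:0009987", "EXP"),
    mk("P2", "enables", "GO:0009987", "IDA"),
    mk("P3", "enables", "GO:0008152", "IPI"),
    mk("P4", "enables", "GO:0008152", "IMP"),
    mk("P5", "enables", "GO:0043705", "IGI"),
    mk("P6", "enables", "GO:0006364", "IEP"),
    mk("P7", "enables", "GO:0000460", "TAS"),
    mk("P8", "enables", "GO:0005515", "IDA"),        # excluded term
    mk("P9", "NOT|enables", "GO:0009987", "EXP"),    # NOT-qualified
    mk("P10", "enables", "GO:0009987", "IEA"),
    mk("P11", "enables", "GO:0009987", "ISS"),
    mk("P12", "enables", "GO:0008152", "ISO"),
    mk("P13", "enables", "GO:0008152", "ISA"),
    mk("P14", "enables", "GO:0043705", "ISM"),
    mk("P15", "enables", "GO:0043705", "IGC"),
    mk("P16", "enables", "GO:0006364", "IBA"),
    mk("P17", "enables", "GO:0006364", "RCA"),
    mk("P18", "enables", "GO:0000460", "ND"),
    mk("P19", "enables", "GO:0000460", "IC"),
    mk("P20", "enables", "GO:0007566", "IEA")
  )
  stopifnot(length(rows) == 20L)
  writeLines(c("!gaf-version: 2.2", rows), path)
  path
}

# End-to-end baseline run on a synthetic dataset: returns the litgo_eval.
run_baseline <- function(config, dictionary = c("enhanced", "original"),
                         min_annotations = 3) {
  dictionary <- match.arg(dictionary)
  d <- synth_dataset(config)
  sen <- segment_corpus(d$corpus)
  dict <- if (dictionary == "enhanced") d$dictionary_enhanced
          else d$dictionary_original
  m <- dplyr::bind_rows(match_concepts(sen, d$lexicon),
                        match_concepts(sen, dict))
  cm <- extract_comentions(m)
  feats <- assemble_features(cm, mode = "separate")
  pred <- baseline_predict(feats)
  list(data = d, mentions = m, comentions = cm, features = feats,
       predictions = pred,
       eval = fmax_eval(pred, d$gold, d$ontology,
                        min_annotations = min_annotations, with_auc = FALSE))
}
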