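# Synthetic data: toy ontologies, protein lexicons, gold annotations and
# corpora with planted protein-GO mentions, so every pipeline stage is
# testable without external downloads. Generation is a pure, seeded function
# of the configuration, and every planted mention event is recorded so tests
# can check recovery exactly.

#' Configuration for the synthetic-data generator
#'
#' @param n_terms Number of ontology terms including the root (>= 3).
#' @param rule_fraction Fraction of non-root terms named with the
#'   "X metabolic process" pattern so the synonym-generation rules apply.
#' @param synonym_fraction Fraction of non-root terms given a curated EXACT
#'   synonym.
#' @param two_parent_prob Probability a non-root term gets a second parent
#'   (making the DAG non-tree).
#' @param n_proteins Number of proteins.
#' @param annotations_per_protein Gold annotations per protein, drawn from
#'   leaf-ish terms.
#' @param planted_rate Probability a gold (protein, term) pair is planted in
#'   the corpus as a co-mention.
#' @param sentence_ratio Probability a planted co-mention is within one
#'   sentence (otherwise in adjacent sentences of the same paragraph).
#' @param noise_rate Probability, per planted document, of an extra spurious
#'   co-mention between its protein and a random non-gold term.
#' @param generated_synonym_prob Probability a planted GO mention uses a
#'   rule-generated synonym instead of the term name (only pattern-named
#'   terms have one; 1 makes planted mentions invisible to the original
#'   dictionary).
#' @param distractor_vocab Size of the distractor word vocabulary.
#' @param words_per_sentence Distractor words per sentence.
#' @param seed Mandatory integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_terms = 30, rule_fraction = 0.2,
                         synonym_fraction = 0.2, two_parent_prob = 0.3,
                         n_proteins = 50, annotations_per_protein = 2,
                         planted_rate = 1, sentence_ratio = 0.5,
                         noise_rate = 0, generated_synonym_prob = 0,
                         distractor_vocab = 100, words_per_sentence = 6,
                         seed) {
  if (missing(seed)) abort("synth_config() requires an explicit seed")
  rates <- c(rule_fraction, synonym_fraction, two_parent_prob, planted_rate,
             sentence_ratio, noise_rate, generated_synonym_prob)
  stopifnot(all(rates >= 0 & rates <= 1), n_terms >= 3)
  structure(
    list(n_terms = n_terms, rule_fraction = rule_fraction,
         synonym_fraction = synonym_fraction,
         two_parent_prob = two_parent_prob, n_proteins = n_proteins,
         annotations_per_protein = annotations_per_protein,
         planted_rate = planted_rate, sentence_ratio = sentence_ratio,
         noise_rate = noise_rate,
         generated_synonym_prob = generated_synonym_prob,
         distractor_vocab = distractor_vocab,
         words_per_sentence = words_per_sentence, seed = seed),
    class = "synth_config"
  )
}

#' Generate a toy ontology DAG
#'
#' A single-namespace (biological_process) rooted DAG: each non-root term
#' gets one parent among earlier terms (plus a second with
#' `two_parent_prob`), a configurable fraction of terms are named with the
#' "X metabolic process" rule pattern, and a fraction carry a curated EXACT
#' synonym. Term word stems (`gokwN`) are distinct from distractor and
#' protein surfaces by construction.
#'
#' @param config A [synth_config()].
#' @return A `go_ontology`.
#' @export
make_toy_ontology <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- config$n_terms
    ids <- sprintf("GO:%07d", seq_len(n))
    n_child <- n - 1L
    n_rule <- round(config$rule_fraction * n_child)
    is_rule <- c(FALSE, seq_len(n_child) %in% sample(n_child, n_rule))
    names_ <- character(n)
    names_[1] <- "biological process"
    for (i in 2:n) {
      stem <- paste0("gokw", i - 1L)
      names_[i] <- if (is_rule[i]) paste(stem, "metabolic process")
                   else paste(stem, "pathway")
    }
    parents <- list()
    for (i in 2:n) {
      p <- sample(i - 1L, 1L)
      if (i > 2L && stats::runif(1) < config$two_parent_prob) {
        p <- unique(c(p, sample(i - 1L, 1L)))
      }
      parents[[i]] <- ids[p]
    }
    edges <- bind_rows(lapply(2:n, function(i) {
      tibble(id = ids[i], parent = parents[[i]], relation = "is_a")
    }))
    n_syn <- round(config$synonym_fraction * n_child)
    syn_idx <- if (n_syn) 1L + sample(n_child, n_syn) else integer(0)
    synonyms <- if (length(syn_idx)) {
      tibble(id = ids[syn_idx],
             synonym = paste0("gosyn", syn_idx - 1L),
             scope = "EXACT")
    } else tibble(id = character(), synonym = character(), scope = character())
    term_tbl <- tibble(id = ids, name = names_,
                       namespace = "biological_process",
                       obsolete = FALSE)
    new_ontology(term_tbl, edges, synonyms)
  })
}

#' Generate a synthetic protein lexicon
#'
#' One unambiguous surface (`protN`) per accession (`SYNPnnnn`).
#'
#' @param config A [synth_config()].
#' @return A `protein_lexicon` tibble (`surface`, `accession`).
#' @export
make_protein_lexicon <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  tbl <- tibble(
    surface = paste0("prot", seq_len(config$n_proteins)),
    accession = sprintf("SYNP%04d", seq_len(config$n_proteins))
  )
  structure(tbl, class = c("protein_lexicon", class(tibble())))
}

#' Generate synthetic gold annotations
#'
#' Each protein receives `annotations_per_protein` distinct leaf-ish terms
#' (terms with no children; all non-root terms if there are too few
#' leaves), drawn uniformly under the seed.
#'
#' @param config A [synth_config()].
#' @param ontology The [make_toy_ontology()] graph.
#' @return A tibble `protein`, `go_id`, `evidence` (evidence codes cycle
#'   through the experimental allow-list).
#' @export
make_gold <- function(config, ontology) {
  stopifnot(inherits(config, "synth_config"),
            inherits(ontology, "go_ontology"))
  live <- ontology$terms$id[!ontology$terms$obsolete]
  leaves <- setdiff(live, ontology$edges$parent)
  pool <- if (length(leaves) >= config$annotations_per_protein) leaves
          else setdiff(live, ontology$roots)
  lex <- make_protein_lexicon(config)
  codes <- gaf_experimental_codes()
  with_seed(config$seed + 1L, {
    rows <- lapply(seq_len(config$n_proteins), function(i) {
      terms <- sample(pool, config$annotations_per_protein)
      tibble(protein = lex$accession[i], go_id = terms)
    })
    bind_rows(rows) |>
      mutate(evidence = codes[(row_number() - 1L) %% length(codes) + 1L])
  })
}

#' Write gold annotations as a GAF 2.2 file
#'
#' @param gold Tibble `protein`, `go_id`, `evidence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(gold, path) {
  rows <- vapply(seq_len(nrow(gold)), function(i) {
    paste(c("SYN", gold$protein[i], gold$protein[i], "enables",
            gold$go_id[i], "SYN_REF:0000001", gold$evidence[i], "",
            "P", "", "", "protein", "taxon:0000", "20260101", "SYN",
            "", ""), collapse = "\t")
  }, character(1))
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

# Surfaces a planted GO mention can use: the term name, or (with the
# configured probability) a rule-generated synonym when one exists.
planted_go_surface <- function(name, prob) {
  if (prob > 0 && stats::runif(1) < prob) {
    gen <- enhancement_variants(name)
    if (nrow(gen)) return(sample(gen$surface, 1L))
  }
  normalize_surface(name)
}

#' Generate a synthetic corpus with planted co-mentions
#'
#' For each gold (protein, term) pair kept at `planted_rate`, emits one
#' paragraph document whose sentences embed the protein surface and a GO
#' surface either in the same sentence (probability `sentence_ratio`) or in
#' adjacent sentences, surrounded by distractor words (`wN`, disjoint from
#' all dictionary surfaces). With probability `noise_rate` a document also
#' plants a spurious co-mention of its protein with a random term outside
#' that protein's expanded gold set. Every planted event is returned as
#' ground truth.
#'
#' @param config A [synth_config()].
#' @param ontology Toy ontology.
#' @param gold Gold annotations from [make_gold()].
#' @return A list: `corpus` (tibble `doc_id`, `unit_kind`, `text`), `truth`
#'   (tibble `doc_id`, `protein`, `go_id`, `go_surface`, `protein_sentence`,
#'   `go_sentence`, `span`, `planted`), where `planted` is FALSE for noise
#'   events.
#' @export
make_corpus <- function(config, ontology, gold) {
  stopifnot(inherits(config, "synth_config"))
  lex <- make_protein_lexicon(config)
  surf_of <- setNames(lex$surface, lex$accession)
  name_of <- setNames(ontology$terms$name, ontology$terms$id)
  live <- setdiff(ontology$terms$id[!ontology$terms$obsolete],
                  ontology$roots)

  with_seed(config$seed + 2L, {
    docs <- list(); truth <- list(); doc_n <- 0L

    distract <- function(k) {
      paste0("w", sample(config$distractor_vocab, k, replace = TRUE))
    }
    mk_sentence <- function(extra = character()) {
      words <- distract(config$words_per_sentence)
      for (e in extra) {
        words <- append(words, e, after = sample(0:length(words), 1L))
      }
      words[1] <- paste0(toupper(substr(words[1], 1, 1)),
                         substr(words[1], 2, nchar(words[1])))
      paste0(paste(words, collapse = " "), ".")
    }

    for (i in seq_len(nrow(gold))) {
      if (stats::runif(1) >= config$planted_rate) next
      p <- gold$protein[i]; g <- gold$go_id[i]
      doc_n <- doc_n + 1L
      doc_id <- sprintf("doc%05d", doc_n)
      gsurf <- planted_go_surface(name_of[[g]],
                                  config$generated_synonym_prob)
      same <- stats::runif(1) < config$sentence_ratio
      if (same) {
        sentences <- c(mk_sentence(), mk_sentence(c(surf_of[[p]], gsurf)),
                       mk_sentence())
        ev <- tibble(doc_id = doc_id, protein = p, go_id = g,
                     go_surface = gsurf, protein_sentence = 1L,
                     go_sentence = 1L, span = "sentence", planted = TRUE)
      } else {
        sentences <- c(mk_sentence(c(surf_of[[p]])), mk_sentence(c(gsurf)),
                       mk_sentence())
        ev <- tibble(doc_id = doc_id, protein = p, go_id = g,
                     go_surface = gsurf, protein_sentence = 0L,
                     go_sentence = 1L, span = "non_sentence", planted = TRUE)
      }
      truth[[length(truth) + 1L]] <- ev

      if (stats::runif(1) < config$noise_rate) {
        gold_terms <- expand_true_path(
          ontology, gold$go_id[gold$protein == p])
        candidates <- setdiff(live, gold_terms)
        if (length(candidates)) {
          ng <- sample(candidates, 1L)
          nsurf <- normalize_surface(name_of[[ng]])
          sentences <- c(sentences, mk_sentence(c(surf_of[[p]], nsurf)))
          truth[[length(truth) + 1L]] <- tibble(
            doc_id = doc_id, protein = p, go_id = ng, go_surface = nsurf,
            protein_sentence = length(sentences) - 1L,
            go_sentence = length(sentences) - 1L,
            span = "sentence", planted = FALSE)
        }
      }
      docs[[doc_n]] <- tibble(doc_id = doc_id, unit_kind = "paragraph",
                              text = paste(sentences, collapse = " "))
    }
    corpus <- bind_rows(docs)
    if (!length(docs)) {
      corpus <- tibble(doc_id = character(), unit_kind = character(),
                       text = character())
    }
    truth_tbl <- bind_rows(truth)
    if (!length(truth)) {
      truth_tbl <- tibble(doc_id = character(), protein = character(),
                          go_id = character(), go_surface = character(),
                          protein_sentence = integer(),
                          go_sentence = integer(), span = character(),
                          planted = logical())
    }
    list(corpus = corpus, truth = truth_tbl)
  })
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper building the ontology, protein lexicon, gold
#' annotations, both dictionaries and the corpus from one configuration.
#'
#' @param config A [synth_config()].
#' @return A list: `config`, `ontology`, `lexicon`, `gold`,
#'   `dictionary_original`, `dictionary_enhanced`, `corpus`, `truth`.
#' @export
synth_dataset <- function(config) {
  ontology <- make_toy_ontology(config)
  gold <- make_gold(config, ontology)
  cc <- make_corpus(config, ontology, gold)
  list(
    config = config,
    ontology = ontology,
    lexicon = make_protein_lexicon(config),
    gold = gold,
    dictionary_original = build_go_dictionary(ontology, "original"),
    dictionary_enhanced = build_go_dictionary(ontology, "enhanced"),
    corpus = cc$corpus,
    truth = cc$truth
  )
}
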