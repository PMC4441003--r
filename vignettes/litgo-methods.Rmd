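---
title: "Mining protein–GO co-mentions from text: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining protein–GO co-mentions from text: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litgo)
library(dplyr)
```

## The model

`litgo` treats the biomedical literature as a source of weak functional
evidence: if a protein and a Gene Ontology concept are mentioned close
together, that co-occurrence is a (noisy) vote that the protein has the
function. Two span definitions are used. A *sentence co-mention* is a
protein mention and a GO concept mention inside one sentence; a
*non-sentence co-mention* has them in different sentences of the same
abstract or paragraph. Counting is **presence-based**: one event per
sentence that contains at least one mention of each entity, and one event
per unordered pair of distinct sentences for the non-sentence span. This
avoids the quadratic inflation a repeated gene symbol would otherwise cause
in a single sentence; a `mention_pair = TRUE` flag restores per-mention-pair
multiplicity for users who want it, since either convention is defensible.
A pair co-occurring both within a sentence and across sentences of one unit
contributes to both feature namespaces.

Counts aggregate per protein into sparse features `co_<GO id>` and
`nco_<GO id>`, optionally alongside bag-of-words counts `w_<word>` from the
sentences in which the protein is mentioned (lowercased, stopword-filtered,
deliberately not stemmed). The bag-of-words counts include the protein
mention's own tokens by default (`include_protein_tokens = FALSE` masks
them); the mention surface is itself informative and masking it is the
less common convention.

## Dictionaries

The *original* concept dictionary contains every non-obsolete term's name
and synonyms; any form ending in the word "activity" also contributes its
stripped variant, because molecular-function names are conventionally
written with that suffix while running text rarely is ("kinase activity"
vs. "…is phosphorylated by this kinase"). The *enhanced* dictionary adds
rule-generated synonyms:

* **Rule M** — "X metabolic process" → "X metabolism", "metabolism of X";
  extensions for "X biosynthetic process" and "X catabolic process" exist
  but default off.
* **Rule P** — "positive regulation of X" → "stimulation of X",
  "X stimulation", "pro-X", with derivational variants of X substituted
  when the variant table knows one (apoptosis → apoptotic gives "apoptotic
  stimulation", "pro-apoptotic").
* **Rule N** — the negative analog ("inhibition of X", "anti-X"), default
  off.

Only rules M and P are enabled by default because those two families are
well attested in how process names are actually verbalized; the optional
extensions are plausible but less validated, so they ship off rather than
silently changing behavior. Every generated entry carries a `rule:<id>`
provenance, so `enhanced − original` is exactly the generated set. The
variant table is a small packaged default (apoptosis, proliferation,
inflammation) and is user-extensible, since no general morphological
engine is attempted.

## Matching and segmentation

Concept recognition is dictionary lookup: case-insensitive,
token-boundary-aligned, contiguous, longest match first, ties leftmost,
shorter overlapping matches suppressed, scanning resuming after each
accepted match. Surfaces and text windows are normalized identically
(lowercase, tokenized, single-spaced), so punctuation variation does not
block matches; hyphens stay inside tokens so "pro-apoptotic" is one token.
Matches never cross sentence boundaries and tokens are never stemmed —
both are configurable points in principle, but the defaults are the
conservative choices and are what the test oracles pin down. Protein
mentions come from the same matcher over a surface → accession lexicon;
an ambiguous surface yields one mention per candidate accession, and no
species normalization is attempted. Statistical NER is out of scope.

The sentence splitter is rule-based: terminal punctuation followed by
whitespace and an uppercase letter or digit ends a sentence, unless the
preceding word is a known abbreviation ("e.g.", "Fig.", single initials).
Offsets everywhere are 0-based, half-open character positions, the same
convention brat uses, so `substring(text, start + 1, end)` always
reproduces a stored surface.

## Prediction

Two predictors are provided. The **baseline** uses the co-mention counts
themselves as confidence scores (per span mode, min-max normalized to
[0, 1] so threshold sweeps are meaningful — raw counts are exposed with
`normalize = FALSE` since no single thresholding convention is canonical).
It learns nothing: a protein's predictions depend only on its own feature
row. The **flat classifier** is a deliberately simple supervised stand-in
for structured-output methods (which are prior work, not re-implemented
here): per-term one-vs-rest ridge-logistic regression (`glmnet`) on the
sparse feature matrix, 5-fold cross-validation with seeded fold
assignment, out-of-fold predicted probabilities as scores, targets
restricted to terms with at least `min_annotations` (default 10) annotated
proteins. Labels are true-path-expanded, which keeps training targets
consistent with the hierarchical evaluation; single-class terms (e.g. the
root, positive for everyone) are skipped with a warning. Degenerate
training folds (fewer than two proteins in a class) fall back to the
class prior for that fold.

`enforce_hierarchy()` makes any score set coherent with the ontology by
assigning each term the maximum score over itself and its descendants —
the smallest change that makes thresholding at any level produce a
true-path-closed set, and an idempotent one.

## Evaluation

Gold sets and predictions are both expanded to the namespace root before
comparison ("true-path rule"); exact matching would punish near-miss
predictions that share almost all ancestry with the gold term. Micro
precision pools TP/FP over proteins with at least one prediction at the
threshold; recall pools over all gold proteins by default
(`recall_over = "predicted"` restricts it, since either denominator is
used in practice and the choice matters when coverage is partial). F-max
sweeps the threshold over the distinct observed scores plus 0 — micro P
and R are step functions of the threshold, so this sweep attains the exact
maximum, which the test suite verifies against a dense-grid oracle to
1e-9. Macro-AUC averages per-term ROC AUC (via `pROC`) over terms with at
least `min_annotations` expanded annotations and at least one negative;
absent predictions score 0. Each GO branch is normally evaluated
separately (`namespace =`).

Functional-class reports bin per-term F either by depth — the shortest
path from the namespace root, root = 0, computed by BFS because multiple
inheritance makes depth otherwise fuzzy — or by annotation-based
information content, IC(t) = −log p(t) with p(t) the fraction of
namespace-annotated proteins whose expanded gold set contains t. Natural
log is the default and base 2 a flag, since the convention differs across
the literature. Terms never seen in the expanded gold standard have p = 0
and are omitted from the IC table rather than given infinite IC; IC bins
are unit-width, half-open intervals [k, k+1).

## Curation loop

`build_curation_records()` turns sentence co-mentions into self-contained
records (sentence text plus sentence-relative entity spans);
`sample_comentions()` draws a seeded uniform sample, optionally within one
functional class. Export writes one sentence per brat document — minimal
annotator context, trivial offsets — with two entity lines; the annotator
adds a single `Good-Comention`/`Bad-Comention` relation, and import reads
it back. Pre-labeled records export their relation line too, so
export∘import is the identity. `class_precision()` is plain
n_good/n_total, computed before any rounding; whether descendant-term
records count toward a class is a flag (`include_descendants`), defaulting
to the single-concept reading.

## The synthetic-data generator

The generator emulates exactly the structure the pipeline consumes: a
single-namespace rooted DAG (each non-root term one or, with probability
0.3, two parents among earlier terms; 20% of terms named on the
"X metabolic process" pattern; 20% given a curated synonym), one
unambiguous surface per protein, two gold leaf annotations per protein,
and one paragraph per planted (protein, term) pair — three sentences of
distractor words with the protein surface and a term surface embedded
either in one sentence or in adjacent sentences (half/half by default).
Defaults are 50 proteins, 30 terms, 100% planting, no noise: large enough
that co-mention tables, cross-validation folds and macro averages are
non-trivial, small enough that the full suite and the acceptance script
run in well under their budgets; these sizes are stated here as the
package's study conditions and used throughout the tests. The noise knob
plants spurious co-mentions of a document's protein with a term outside
its expanded gold set, which is the failure mode dictionary matchers
actually have (a correct surface in a contextually wrong pairing).

What the generator does **not** emulate: real syntax (sentences are word
salads with planted surfaces), ambiguous protein names, cross-species
homonymy, coreference ("this enzyme…"), section structure, or realistic
term-frequency distributions. Passing tests therefore demonstrate that the
machinery is correct — matching, counting, expansion, sweeping, round-trips
— not that any particular F-max carries over to Medline-scale text.
Rule-generated synonyms can be planted with configurable probability;
at probability 1 the corpus is invisible to the original dictionary by
construction, which is how the original-vs-enhanced contrast is exercised.

## Numerical and degenerate-input choices

* Threshold sweeps use `score >= tau`; `tau = 0` therefore includes every
  stored prediction.
* With no predictions at a threshold, precision is reported as 0 with a
  `no_predictions` flag rather than NA, keeping sweep curves total.
* Min-max normalization of a constant count vector maps everything to 1.
* F-max ties resolve to the smallest maximizing threshold.
* Cycles in the parent relation and namespace-less terms are hard parse
  errors; unreachable terms are an error listing the ids.
* Obsolete terms are retained by the parser but excluded from
  dictionaries, depth, IC, expansion and evaluation.
* `read_gaf()` drops NOT-qualified rows, non-experimental evidence codes
  (outside EXP, IDA, IPI, IMP, IGI, IEP, TAS), the overly broad
  protein-binding term GO:0005515, and annotations to unknown or obsolete
  terms (with a message).

## A small end-to-end run

```{r pipeline}
cfg <- synth_config(n_proteins = 20, n_terms = 15, seed = 42)
d <- synth_dataset(cfg)
sen <- segment_corpus(d$corpus)
mentions <- bind_rows(match_concepts(sen, d$lexicon),
                      match_concepts(sen, d$dictionary_enhanced))
cm <- extract_comentions(mentions)
comention_stats(cm)

pred <- assemble_features(cm, mode = "separate") |> baseline_predict()
ev <- fmax_eval(pred, d$gold, d$ontology, min_annotations = 3)
glance(ev)
```

```{r plots, fig.width = 5, fig.height = 4}
autoplot(ev)
autoplot(binned_report(ev, term_depths(d$ontology), axis = "depth"))
```

## Known limitations

* Dictionary lookup cannot disambiguate senses; the enhanced dictionary
  trades recall for new ambiguity (a curated synonym like "implantation"
  will fire inside "tumor cell implantation").
* The flat classifier is a stand-in: it ignores label structure during
  training beyond expanded labels, and its scores are per-term
  probabilities, not jointly calibrated.
* Protein mention recognition is exact-surface lexicon matching; no
  statistical NER, abbreviation expansion or species normalization.
* The rule inventory for synonym generation covers the metabolic and
  regulation families only; a general part-of-speech variant generator is
  an extension hook, not implemented.
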