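Package: litgo
Title: Literature Co-Mention Mining for Gene Ontology Function Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A text-mining toolkit for predicting protein function from the
    biomedical literature. Builds lexical dictionaries from the Gene Ontology
    (an original dictionary of names and synonyms with trailing "activity"
    stripped, and an enhanced dictionary augmented by synonym-generation rules
    such as "X metabolic process" to "X metabolism"), recognizes protein and
    GO concept mentions in text by longest-match dictionary lookup, extracts
    sentence and non-sentence co-mention features and bag-of-words features,
    provides a co-mention baseline classifier and a flat per-term linear
    classifier with cross-validation, evaluates predictions hierarchically
    under the true-path rule (micro precision/recall, F-max, macro-AUC,
    depth- and information-content-binned reports), and supports a
    medium-throughput curation loop over co-mentions via the brat standoff
    format. A synthetic-data generator produces toy ontologies, lexicons,
    gold annotations, and corpora with planted protein-GO associations so the
    entire pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    glmnet,
    Matrix,
    pROC,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
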