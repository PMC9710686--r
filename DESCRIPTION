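Package: grounder
Title: Biomedical Named-Entity Normalization with Scored String Matching
    and Context-Aware Disambiguation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps free-text biomedical entity mentions (genes, proteins,
    small molecules, processes, diseases) to ontology identifiers.  A term
    lexicon is indexed by canonicalized text; queries are expanded into
    orthographic variants (separator handling, Greek-letter spell-out and
    substitution, plural stripping), looked up exactly, and scored in [0,1]
    by string similarity and term status.  Ambiguous strings are resolved
    with per-string tf-idf logistic-regression sense classifiers applied to
    surrounding text, and cross-species gene/protein ties are broken with an
    organism priority list.  Includes synthetic lexicon and corpus
    generators, a top/any precision-recall evaluation harness, a command
    line interface and a minimal REST service.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    callr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
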