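test_that("tf-idf featurization matches a by-hand oracle", {
  corp <- labeled_corpus("X", tibble::tibble(
    doc_id = c("d1", "d2", "d3"),
    text = c("kinase pathway", "kinase signal", "membrane signal"),
    label = c("A", "A", "B")))
  x <- featurize(corp)
  # vocabulary: unigrams + bigrams, C-locale sorted
  expect_identical(colnames(x),
                   c("kinase", "kinase pathway", "kinase signal", "membrane",
                     "membrane signal", "pathway", "signal"))
  idf <- function(df) log((1 + 3) / (1 + df)) + 1
  # doc 1: kinase (df 2), pathway (df 1), bigram "kinase pathway" (df 1)
  raw <- c(idf(2), idf(1), idf(1))
  expected <- raw / sqrt(sum(raw^2))
  expect_equal(as.numeric(x[1, c("kinase", "pathway", "kinase pathway")]),
               expected[c(1, 2, 3)], tolerance = 1e-12)
  # rows are L2-normalized
  expect_equal(unname(Matrix::rowSums(x^2)), rep(1, 3), tolerance = 1e-12)
  # a repeated document yields an identical row
  corp2 <- labeled_corpus("X", corp$documents[c(1, 1, 3), ])
  x2 <- featurize(corp2)
  expect_equal(x2[1, ], x2[2, ])
  # disjoint documents share no support
  expect_equal(sum(x[1, ] * x[3, ]), 0)
})

test_that("macro-F1 follows the stated class conventions", {
  expect_equal(macro_f1(c("a", "b", "a", "b"), c("a", "b", "a", "b")), 1)
  # symmetric confusion, per-class TP=3 FP=1 FN=1 -> F1 = 0.75 each
  truth <- c(rep("a", 4), rep("b", 4))
  pred <- c(rep("a", 3), "b", rep("b", 3), "a")
  expect_equal(macro_f1(truth, pred), 0.75)
  # all predictions one class, balanced truth: F1 = (2/3 + 0) / 2
  truth <- c(rep("a", 5), rep("b", 5))
  expect_equal(macro_f1(truth, rep("a", 10)), mean(c(2 / 3, 0)))
  # classes absent from truth are excluded from the mean
  expect_equal(macro_f1(c("a", "a"), c("a", "b")), 2 / 3)
  expect_error(macro_f1(c("a"), c("a", "b")), "equal length")
  expect_error(macro_f1(character(0), character(0)), "empty")
})

test_that("training on disjoint vocabularies is perfect and deterministic", {
  corp <- generate_ambiguous_corpus("AMB1", n_senses = 2, docs_per_sense = 50,
                                    seed = 2)
  m1 <- train_disambiguator(corp, seed = 2)
  m2 <- train_disambiguator(corp, seed = 2)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$cv_macro_f1, m2$cv_macro_f1)
  # separable by construction: training accuracy 1.0
  pred <- vapply(corp$documents$text, function(tx) {
    names(which.max(disambiguate(m1, tx)))
  }, character(1))
  expect_equal(unname(pred), corp$documents$label)
})

test_that("training preconditions are enforced", {
  corp <- generate_ambiguous_corpus("AMB1", docs_per_sense = 20, seed = 1)
  one_sense <- corp$documents[corp$documents$label == "SYNT:S1", ]
  expect_error(labeled_corpus("AMB1", one_sense), "2 distinct sense")
  small <- labeled_corpus("AMB1", corp$documents[c(1:3, 21:40), ])
  expect_error(train_disambiguator(small, min_docs = 5), "SYNT:S1")
  expect_error(crossvalidate(corp, folds = 1), "at least 2")
  expect_error(crossvalidate(small, folds = 5), "at least")
})

test_that("cross-validation separates separable corpora and not shuffled ones", {
  corp <- generate_ambiguous_corpus("AMB1", n_senses = 2, docs_per_sense = 40,
                                    seed = 31)
  expect_gte(crossvalidate(corp, seed = 31), 0.95)
  shuffled <- corp
  withr::with_seed(31, {
    shuffled$documents$label <- sample(shuffled$documents$label)
  })
  f1 <- crossvalidate(shuffled, seed = 31)
  expect_lt(abs(f1 - 0.5), 0.15)
})

test_that("model selection applies the deployment cutoff exactly", {
  fake <- function(f1) structure(list(cv_macro_f1 = f1, entity_text = "x"),
                                 class = "disambiguator")
  models <- lapply(c(0.65, 0.70, 0.95), fake)
  kept <- select_models(models)
  expect_length(kept, 2L)
  expect_equal(vapply(kept, `[[`, numeric(1), "cv_macro_f1"), c(0.70, 0.95))
  expect_length(select_models(list()), 0L)
  expect_length(select_models(models, cutoff = 0), 3L)
})

test_that("disambiguation probabilities behave", {
  corp <- generate_ambiguous_corpus("AMB1", n_senses = 3, docs_per_sense = 30,
                                    seed = 12)
  m <- train_disambiguator(corp, seed = 12)
  # in-vocabulary context from sense 1
  ctx <- corp$documents$text[corp$documents$label == "SYNT:S1"][1]
  p <- disambiguate(m, ctx)
  expect_gt(p[["SYNT:S1"]], 0.5)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # out-of-vocabulary context equals the intercept-only distribution
  p0 <- disambiguate(m, "zzzz qqqq wwww")
  z <- m$coefficients[1, ]
  expect_equal(unname(p0), unname(exp(z - max(z)) / sum(exp(z - max(z)))),
               tolerance = 1e-12)
  # probabilities sum to 1 for arbitrary contexts
  set.seed(1)
  for (i in 1:20) {
    ctx <- paste(sample(c(m$vocabulary, "junk"), 10, replace = TRUE),
                 collapse = " ")
    expect_equal(sum(disambiguate(m, ctx)), 1, tolerance = 1e-9)
  }
  expect_error(disambiguate(m, ""), "non-empty")
})

test_that("score adjustment reorders without changing the match set", {
  idx <- build_index(dap4_fixture())
  m <- suppressMessages(ground(idx, "DAP4"))
  adjusted <- apply_to_matches(m, c("SYNT:S2" = 0.9, "SYNT:S1" = 0.1))
  expect_equal(adjusted$identifier[1], "S2")
  expect_setequal(paste(adjusted$namespace, adjusted$identifier),
                  paste(m$namespace, m$identifier))
  expect_true(all(adjusted$score >= 0 & adjusted$score <= 1))
  # uniform probabilities leave the order unchanged
  uniform <- apply_to_matches(m, c("SYNT:S1" = 0.5, "SYNT:S2" = 0.5))
  expect_equal(uniform$identifier, m$identifier)
  # senses absent from the matches are ignored with a note
  expect_message(apply_to_matches(m, c("SYNT:S9" = 1)), "ignored")
  empty <- m[0, ]
  expect_equal(nrow(apply_to_matches(empty, c("SYNT:S1" = 1))), 0L)
})

test_that("model bundles round-trip bit-identically", {
  corp <- generate_ambiguous_corpus("IK", n_senses = 2, docs_per_sense = 30,
                                    seed = 9)
  m <- train_disambiguator(corp, seed = 9)
  dir <- withr::local_tempdir()
  save_disambiguator(m, dir)
  m2 <- load_disambiguator(dir)
  expect_identical(m$coefficients, m2$coefficients)
  expect_identical(m$idf, m2$idf)
  expect_identical(m$vocabulary, m2$vocabulary)
  expect_identical(m$cv_macro_f1, m2$cv_macro_f1)
  for (ctx in corp$documents$text[c(1, 31)]) {
    expect_identical(disambiguate(m, ctx), disambiguate(m2, ctx))
  }
})

test_that("labeled corpora round-trip through JSONL", {
  corp <- generate_ambiguous_corpus("AMB1", docs_per_sense = 10, seed = 5)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_labeled_corpus(corp, path)
  back <- read_labeled_corpus(path, "AMB1")
  expect_equal(back$documents, corp$documents)
})

test_that("broom methods expose the fit", {
  corp <- generate_ambiguous_corpus("AMB1", docs_per_sense = 20, seed = 6)
  m <- train_disambiguator(corp, seed = 6)
  td <- tidy(m)
  expect_equal(nrow(td), (length(m$vocabulary) + 1L) * 2L)
  g <- glance(m)
  expect_equal(g$n_docs, 40L)
  expect_equal(g$folds, 5L)
  expect_s3_class(autoplot(m), "ggplot")
})
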