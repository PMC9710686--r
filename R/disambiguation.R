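# Per-ambiguous-string sense classifiers.
#
# Many lexicon entries share a text name (e.g. a synonym used by two
# distinct genes); string features cannot separate them.  Under the
# one-sense-per-discourse assumption each labeled document carries a single
# sense, and one multinomial logistic-regression classifier per ambiguous
# string -- over tf-idf weighted unigram + bigram features -- predicts the
# sense from surrounding text.

#' Construct a labeled corpus
#'
#' A labeled corpus holds the training documents for one ambiguous entity
#' string: each document has a single sense label (`"NAMESPACE:ID"`),
#' following the one-sense-per-discourse assumption.
#'
#' @param entity_text The shared ambiguous string.
#' @param documents A data frame with columns `doc_id`, `text`, `label`.
#' @return A `labeled_corpus` object.
#' @export
labeled_corpus <- function(entity_text, documents) {
  documents <- tibble::as_tibble(documents)
  stopifnot(all(c("doc_id", "text", "label") %in% names(documents)))
  documents <- documents[c("doc_id", "text", "label")]
  if (nrow(documents) == 0 || any(!nzchar(documents$text))) {
    stop("every document must be non-empty", call. = FALSE)
  }
  if (length(unique(documents$label)) < 2L) {
    stop("a labeled corpus needs at least 2 distinct sense labels",
         call. = FALSE)
  }
  structure(list(entity_text = entity_text, documents = documents),
            class = "labeled_corpus")
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat("<labeled_corpus> '", x$entity_text, "': ", nrow(x$documents),
      " documents, ", length(unique(x$documents$label)), " senses\n", sep = "")
  invisible(x)
}

#' Read / write a labeled corpus as JSONL
#'
#' One JSON object per line with fields `doc_id`, `text`, `label`.
#'
#' @param path File path.
#' @param entity_text The ambiguous string the corpus is for.
#' @return `read_labeled_corpus()` returns a `labeled_corpus`;
#'   `write_labeled_corpus()` returns `path` invisibly.
#' @export
read_labeled_corpus <- function(path, entity_text) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  docs <- purrr::map_dfr(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tibble::tibble(doc_id = as.character(rec$doc_id),
                   text = as.character(rec$text),
                   label = as.character(rec$label))
  })
  labeled_corpus(entity_text, docs)
}

#' @rdname read_labeled_corpus
#' @param corpus A `labeled_corpus`.
#' @export
write_labeled_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  lines <- vapply(seq_len(nrow(corpus$documents)), function(i) {
    jsonlite::toJSON(as.list(corpus$documents[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Tokenizer: lowercase, split on non-alphanumerics, keep tokens of length
# >= 2; bigrams are adjacent token pairs joined with a space.
tokenize_doc <- function(text) {
  toks <- stringr::str_split_1(stringr::str_to_lower(text), "[^\\p{L}\\p{N}]+")
  toks <- toks[nchar(toks) >= 2L]
  if (length(toks) >= 2L) {
    c(toks, paste(toks[-length(toks)], toks[-1L]))
  } else toks
}

#' tf-idf featurization of a labeled corpus
#'
#' Builds the document-by-feature matrix used by the sense classifiers.
#' Features are unigrams and bigrams (tokens lowercased, split on
#' non-alphanumerics, length >= 2) present in at least `min_df` documents;
#' weights are term frequency times smoothed inverse document frequency,
#' `idf = ln((1 + N) / (1 + df)) + 1`, with each row L2-normalized.  With a
#' fixed `vocab` (a prior featurization's result) the same columns and idf
#' weights are reused, as for held-out or prediction-time documents.
#'
#' @param corpus A `labeled_corpus`, or a character vector of documents.
#' @param vocab Optional fixed vocabulary: a list with `features` and `idf`.
#' @param min_df Minimum document frequency for a feature (default 1).
#' @return A sparse `dgCMatrix` (documents x features) with attributes
#'   `vocab` (list of `features`, `idf`) and `labels`.
#' @export
featurize <- function(corpus, vocab = NULL, min_df = 1L) {
  if (inherits(corpus, "labeled_corpus")) {
    texts <- corpus$documents$text
    labels <- corpus$documents$label
  } else {
    texts <- as.character(corpus)
    labels <- NULL
  }
  if (length(texts) == 0) stop("empty corpus", call. = FALSE)
  tok <- lapply(texts, tokenize_doc)
  if (is.null(vocab)) {
    df_counts <- table(unlist(lapply(tok, unique), use.names = FALSE))
    feats <- stringr::str_sort(names(df_counts)[df_counts >= min_df],
                               locale = "C")
    df <- as.numeric(df_counts[feats])
    idf <- log((1 + length(texts)) / (1 + df)) + 1
    vocab <- list(features = feats, idf = idf)
  }
  fi <- seq_along(vocab$features)
  names(fi) <- vocab$features
  triplets <- purrr::imap(tok, function(tk, d) {
    tk <- tk[tk %in% vocab$features]
    if (length(tk) == 0) return(NULL)
    tf <- table(tk)
    j <- fi[names(tf)]
    list(i = rep(d, length(j)), j = unname(j), x = as.numeric(tf))
  })
  triplets <- purrr::compact(triplets)
  if (length(triplets) == 0) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(texts), length(vocab$features)))
  } else {
    m <- Matrix::sparseMatrix(
      i = unlist(lapply(triplets, `[[`, "i")),
      j = unlist(lapply(triplets, `[[`, "j")),
      x = unlist(lapply(triplets, `[[`, "x")),
      dims = c(length(texts), length(vocab$features)))
  }
  m <- m %*% Matrix::Diagonal(x = vocab$idf)
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  m <- Matrix::Diagonal(x = 1 / norms) %*% m
  m <- methods::as(m, "CsparseMatrix")
  colnames(m) <- vocab$features
  attr(m, "vocab") <- vocab
  attr(m, "labels") <- labels
  m
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over classes of per-class F1.  Classes with zero support
#' in `truth` are excluded; a class whose precision and recall are both zero
#' contributes F1 = 0.
#'
#' @param truth,predicted Equal-length non-empty label vectors.
#' @return A number in `[0, 1]`.
#' @export
macro_f1 <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(truth) == 0) stop("empty label vectors", call. = FALSE)
  classes <- unique(truth)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

# Ridge multinomial logistic regression on a feature matrix; returns the
# dense coefficient matrix ((intercept + features) x senses).
fit_multinomial <- function(x, labels, senses, lambda) {
  y <- factor(labels, levels = senses)
  orig_p <- ncol(x)
  padded <- orig_p < 2L  # glmnet needs >= 2 predictors; pad with zero columns
  if (padded) {
    x <- cbind(x, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                       x = numeric(0),
                                       dims = c(nrow(x), 2L - orig_p)))
  }
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = FALSE, maxit = 1e5)
  coefs <- glmnet::coef.glmnet(fit, s = lambda)
  mat <- do.call(cbind, lapply(senses, function(s) as.matrix(coefs[[s]])))
  colnames(mat) <- senses
  rownames(mat)[1] <- "(Intercept)"
  if (padded) mat <- mat[seq_len(1L + orig_p), , drop = FALSE]
  mat
}

predict_probs <- function(coefficients, x) {
  z <- as.matrix(x %*% coefficients[-1L, , drop = FALSE])
  z <- sweep(z, 2L, coefficients[1L, ], "+")
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train a sense disambiguator for one ambiguous string
#'
#' Fits a multinomial (ridge-penalized) logistic regression over tf-idf
#' unigram + bigram features of the labeled documents, one classifier per
#' ambiguous entity string.  Generalization is estimated by stratified
#' k-fold cross-validation ([crossvalidate()]) and stored as `cv_macro_f1`;
#' deployment keeps only models at or above the selection cutoff
#' ([select_models()]).
#'
#' @param corpus A `labeled_corpus` with at least 2 senses.
#' @param seed Integer seed controlling fold assignment.
#' @param folds Number of cross-validation folds (default 5).
#' @param min_docs Minimum documents required per sense (default 5).
#' @param lambda Ridge penalty of the logistic regression.
#' @param min_df Minimum document frequency for features.
#' @return A `disambiguator` object.
#' @export
train_disambiguator <- function(corpus, seed = 1L, folds = 5L, min_docs = 5L,
                                lambda = 1e-3, min_df = 1L) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  counts <- table(corpus$documents$label)
  if (length(counts) < 2L) stop("need at least 2 senses", call. = FALSE)
  low <- counts[counts < min_docs]
  if (length(low)) {
    stop("sense(s) below the minimum of ", min_docs, " documents: ",
         paste(names(low), collapse = ", "), call. = FALSE)
  }
  senses <- stringr::str_sort(names(counts), locale = "C")
  cv <- crossvalidate(corpus, folds = folds, seed = seed,
                      lambda = lambda, min_df = min_df)
  x <- featurize(corpus, min_df = min_df)
  coefficients <- fit_multinomial(x, corpus$documents$label, senses, lambda)
  structure(list(
    entity_text = corpus$entity_text,
    senses = senses,
    vocabulary = attr(x, "vocab")$features,
    idf = attr(x, "vocab")$idf,
    coefficients = coefficients,
    cv_macro_f1 = cv,
    metadata = list(n_docs = as.list(counts[senses]), seed = as.integer(seed),
                    folds = as.integer(folds), lambda = lambda,
                    min_df = as.integer(min_df))
  ), class = "disambiguator")
}

#' @export
print.disambiguator <- function(x, ...) {
  cat("<disambiguator> '", x$entity_text, "': ", length(x$senses),
      " senses, ", length(x$vocabulary), " features, CV macro-F1 = ",
      format(x$cv_macro_f1, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Cross-validated macro-F1 of a sense classifier
#'
#' Stratified k-fold cross-validation: within each sense, documents are
#' shuffled (seeded) and dealt into folds; each fold is predicted by a model
#' trained on the remaining folds (featurization refit on the training split
#' only) and scored with [macro_f1()].  Returns the mean over folds.
#'
#' @inheritParams train_disambiguator
#' @return Mean macro-F1 over folds, in `[0, 1]`.
#' @export
crossvalidate <- function(corpus, folds = 5L, seed = 1L, lambda = 1e-3,
                          min_df = 1L) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  if (folds < 2L) stop("`folds` must be at least 2", call. = FALSE)
  labels <- corpus$documents$label
  counts <- table(labels)
  if (any(counts < folds)) {
    stop("every sense needs at least `folds` = ", folds, " documents",
         call. = FALSE)
  }
  senses <- stringr::str_sort(names(counts), locale = "C")
  fold_of <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in senses) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  scores <- vapply(seq_len(folds), function(k) {
    train <- fold_of != k
    xtr <- featurize(corpus$documents$text[train], min_df = min_df)
    # guard: featurize() on a character vector carries no labels
    coefs <- fit_multinomial(xtr, labels[train], senses, lambda)
    xte <- featurize(corpus$documents$text[!train], vocab = attr(xtr, "vocab"))
    probs <- predict_probs(coefs, xte)
    pred <- senses[max.col(probs, ties.method = "first")]
    macro_f1(labels[!train], pred)
  }, numeric(1))
  mean(scores)
}

#' Filter disambiguators by cross-validated macro-F1
#'
#' Keeps exactly the models whose `cv_macro_f1` meets the cutoff (default
#' 0.7), preserving order; models below the cutoff are excluded from
#' deployment.
#'
#' @param models A list of `disambiguator` objects.
#' @param cutoff Minimum mean CV macro-F1.
#' @return The retained sublist.
#' @export
select_models <- function(models, cutoff = 0.7) {
  keep <- vapply(models, function(m) m$cv_macro_f1 >= cutoff, logical(1))
  models[keep]
}

#' Predict sense probabilities from context
#'
#' Featurizes the context with the model's fixed vocabulary and idf weights
#' and applies the stored logistic-regression coefficients.  A context with
#' no in-vocabulary token yields the intercept-only distribution.
#'
#' @param model A `disambiguator`.
#' @param context Non-empty context string (a sentence or paragraph).
#' @return Named numeric vector of probabilities over senses, summing to 1.
#' @export
disambiguate <- function(model, context) {
  stopifnot(inherits(model, "disambiguator"))
  if (!is.character(context) || length(context) != 1L || !nzchar(context)) {
    stop("`context` must be a single non-empty string", call. = FALSE)
  }
  x <- featurize(context, vocab = list(features = model$vocabulary,
                                       idf = model$idf))
  probs <- predict_probs(model$coefficients, x)[1L, ]
  stats::setNames(as.numeric(probs), model$senses)
}

#' Adjust match scores with sense probabilities
#'
#' Combines each match's string score with the predicted probability of its
#' sense: `adjusted = score * (eps + (1 - eps) * p)` with `eps = 0.05`,
#' clipped to `[0, 1]` -- monotone in both inputs and bound-preserving.  The
#' match set is unchanged; matches whose entity is not among the model's
#' senses keep their score, and senses absent from the matches are ignored.
#'
#' @param matches A `grounding_matches` tibble.
#' @param probabilities Named probability vector from [disambiguate()]
#'   (names `"NAMESPACE:ID"`).
#' @param eps Floor of the probability factor.
#' @return The re-scored, re-sorted matches.
#' @export
apply_to_matches <- function(matches, probabilities, eps = 0.05) {
  if (nrow(matches) == 0) return(matches)
  key <- paste0(matches$namespace, ":", matches$identifier)
  p <- probabilities[key]
  hit <- !is.na(p)
  matches$disamb_probability <- ifelse(hit, as.numeric(p), NA_real_)
  matches$score[hit] <- pmin(1, pmax(0,
    matches$score[hit] * (eps + (1 - eps) * as.numeric(p[hit]))))
  ignored <- setdiff(names(probabilities), key)
  if (length(ignored)) {
    message("sense(s) not among matches ignored: ",
            paste(ignored, collapse = ", "))
  }
  rank_matches(matches)
}

# -- model registry -----------------------------------------------------------

#' Build a disambiguator registry
#'
#' Keys a list of disambiguators by the canonical form of their entity text,
#' the key [ground()] uses to find a model for an input string.
#'
#' @param models A list of `disambiguator` objects.
#' @return A named list.
#' @export
model_registry <- function(models) {
  if (length(models) == 0) return(stats::setNames(list(), character(0)))
  stats::setNames(models,
                  vapply(models, function(m) canonicalize(m$entity_text), ""))
}

registry_get <- function(models, key) {
  if (is.null(models) || length(models) == 0) return(NULL)
  if (inherits(models, "disambiguator")) models <- model_registry(list(models))
  if (is.null(names(models)) || !all(nzchar(names(models)))) {
    models <- model_registry(models)
  }
  models[[key]]
}

# -- serialization ------------------------------------------------------------

#' Save / load a disambiguator bundle
#'
#' A model bundle is a directory of text files: `metadata.json` (schema
#' version, entity text, senses, CV macro-F1, training metadata),
#' `vocabulary.tsv` (feature, idf) and `coefficients.tsv` (intercept +
#' per-feature rows, one column per sense).  Numbers are written with 17
#' significant digits so the round-trip is bit-identical.
#'
#' @param model A `disambiguator`.
#' @param dir Bundle directory (created if needed).
#' @return `save_disambiguator()` returns `dir` invisibly;
#'   `load_disambiguator()` returns the `disambiguator`.
#' @export
save_disambiguator <- function(model, dir) {
  stopifnot(inherits(model, "disambiguator"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema_version = 1L, entity_text = model$entity_text,
               senses = model$senses, cv_macro_f1 = num17(model$cv_macro_f1),
               metadata = model$metadata)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(paste(model$vocabulary, num17(model$idf), sep = "\t"),
             file.path(dir, "vocabulary.tsv"), useBytes = TRUE)
  co <- model$coefficients
  lines <- vapply(seq_len(nrow(co)), function(i) {
    paste(c(rownames(co)[i], num17(co[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("feature", colnames(co)), collapse = "\t"), lines),
             file.path(dir, "coefficients.tsv"), useBytes = TRUE)
  invisible(dir)
}

num17 <- function(x) sprintf("%.17g", x)

#' @rdname save_disambiguator
#' @export
load_disambiguator <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  voc <- utils::read.delim(file.path(dir, "vocabulary.tsv"), header = FALSE,
                           col.names = c("feature", "idf"),
                           colClasses = c("character", "numeric"), quote = "")
  co <- utils::read.delim(file.path(dir, "coefficients.tsv"), header = TRUE,
                          check.names = FALSE, quote = "",
                          colClasses = "character")
  mat <- as.matrix(co[, -1, drop = FALSE])
  mat <- matrix(as.numeric(mat), nrow = nrow(mat),
                dimnames = list(co$feature, colnames(co)[-1]))
  cv <- as.numeric(meta$cv_macro_f1)
  md <- meta$metadata
  md$n_docs <- as.list(md$n_docs)
  structure(list(entity_text = meta$entity_text, senses = meta$senses,
                 vocabulary = voc$feature, idf = voc$idf,
                 coefficients = mat, cv_macro_f1 = cv, metadata = md),
            class = "disambiguator")
}

# -- broom-style methods ------------------------------------------------------

#' Tidy a disambiguator
#'
#' One row per (feature, sense) coefficient, intercepts included.
#'
#' @param x A `disambiguator`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `sense`, `estimate`.
#' @export
tidy.disambiguator <- function(x, ...) {
  co <- x$coefficients
  tibble::tibble(
    feature = rep(rownames(co), times = ncol(co)),
    sense = rep(colnames(co), each = nrow(co)),
    estimate = as.numeric(co)
  )
}

#' Glance at a disambiguator
#'
#' @param x A `disambiguator`.
#' @param ... Unused.
#' @return A one-row tibble with the entity text, sense/document/feature
#'   counts, CV macro-F1 and training seed.
#' @export
glance.disambiguator <- function(x, ...) {
  tibble::tibble(
    entity_text = x$entity_text,
    n_senses = length(x$senses),
    n_docs = sum(unlist(x$metadata$n_docs)),
    n_features = length(x$vocabulary),
    cv_macro_f1 = x$cv_macro_f1,
    folds = x$metadata$folds,
    seed = x$metadata$seed
  )
}

#' Plot the strongest features of a disambiguator
#'
#' Shows the top coefficients per sense (by absolute value), a quick view of
#' which context words drive each sense.
#'
#' @param object A `disambiguator`.
#' @param n_features Features shown per sense.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disambiguator <- function(object, n_features = 10, ...) {
  df <- tidy(object)
  df <- df[df$feature != "(Intercept)", ]
  df <- dplyr::slice_max(dplyr::group_by(df, .data$sense),
                         abs(.data$estimate), n = n_features,
                         with_ties = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature, .data$estimate),
                                   y = .data$estimate)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~sense, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "coefficient")
}
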