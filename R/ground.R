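# The grounding pipeline: variants -> lookup -> compare/score -> per-entity
# dedup -> optional context disambiguation -> optional species reranking ->
# deterministic ranking.

#' Scored candidate matches before per-entity deduplication
#'
#' Runs the first half of the grounding pipeline -- variant generation, exact
#' canonical lookup, string comparison and scoring -- and returns every
#' candidate (term, variant) pair with its features and score.  [ground()]
#' deduplicates this list per entity.
#'
#' @inheritParams ground
#' @return A tibble with the term columns plus `variant_used`, `score`,
#'   `exact`, `space_dash_mismatch`, `cap_profile` (comma-separated per-token
#'   codes), `plural_dropped`.
#' @export
match_candidates <- function(index, text, constants = scoring_constants()) {
  stopifnot(inherits(index, "grounding_index"))
  variants <- generate_variants(text)
  cand <- lookup(index, variants)
  if (nrow(cand) == 0) return(empty_matches(cand))
  feats <- lapply(cand$text, function(ref) compare_strings(text, ref))
  cand$score <- vapply(seq_len(nrow(cand)), function(i) {
    score_match(feats[[i]], cand$status[i], constants)
  }, numeric(1))
  cand$exact <- vapply(feats, `[[`, logical(1), "exact")
  cand$space_dash_mismatch <- vapply(feats, `[[`, integer(1), "space_dash_mismatch")
  cand$cap_profile <- vapply(feats, function(f) {
    paste(f$cap_profile, collapse = ",")
  }, character(1))
  cand$plural_dropped <- vapply(feats, `[[`, logical(1), "plural_dropped")
  cand$n_mismatches <- vapply(feats, n_mismatches, numeric(1))
  cand
}

empty_matches <- function(cand) {
  cand$score <- numeric(0)
  cand$exact <- logical(0)
  cand$space_dash_mismatch <- integer(0)
  cand$cap_profile <- character(0)
  cand$plural_dropped <- logical(0)
  cand$n_mismatches <- numeric(0)
  cand$disamb_probability <- numeric(0)
  class(cand) <- c("grounding_matches", class(cand))
  cand
}

#' Ground an entity string
#'
#' Maps a free-text entity mention to ranked ontology identifiers.  The
#' pipeline generates canonical variants of `text`, looks each up exactly in
#' the index, scores every candidate against the original string
#' ([compare_strings()], [score_match()]), keeps the best-scoring candidate
#' per (namespace, identifier), then optionally adjusts scores with a
#' context-based sense classifier ([disambiguate()]) and reranks equal-score
#' gene/protein matches by an organism priority list
#' ([rerank_by_species()]).  The result is sorted by decreasing score with a
#' deterministic tie-break (status rank, fewer mismatch features, source,
#' namespace, identifier, text).
#'
#' @param index A `grounding_index` from [build_index()].
#' @param text The entity string to ground (non-empty).
#' @param context Optional surrounding text.  Used only when `models`
#'   contains a disambiguator for `canonicalize(text)`; otherwise ignored
#'   with a message.
#' @param organisms Optional character vector of taxonomy identifiers,
#'   highest priority first.
#' @param models Optional disambiguator registry: a list of
#'   [disambiguator][train_disambiguator()] objects, or the result of
#'   [model_registry()].
#' @param constants Scoring constants ([scoring_constants()]).
#' @return A `grounding_matches` tibble, one row per matched entity, sorted
#'   by decreasing `score`; `disamb_probability` is `NA` unless a model was
#'   applied.
#' @examples
#' idx <- build_index(pkc_fixture())
#' ground(idx, "PKC-Delta")
#' @export
ground <- function(index, text, context = NULL, organisms = NULL,
                   models = NULL, constants = scoring_constants()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("`text` must be a single non-empty string", call. = FALSE)
  }
  cand <- match_candidates(index, text, constants)
  if (nrow(cand) == 0) return(rank_matches(empty_matches(cand)))

  # per-(namespace, identifier) dedup keeping the max-scoring candidate
  cand <- cand[order(-cand$score, status_rank(cand$status), cand$n_mismatches,
                     cand$source, rank_c(cand$text)), ]
  entity <- paste(cand$namespace, cand$identifier, sep = "\r")
  matches <- cand[!duplicated(entity), ]
  matches$disamb_probability <- NA_real_

  if (!is.null(context) && nzchar(context)) {
    model <- registry_get(models, canonicalize(text))
    if (is.null(model)) {
      message("no disambiguation model for '", text, "'; context ignored")
    } else {
      probs <- disambiguate(model, context)
      matches <- apply_to_matches(matches, probs)
    }
  }
  matches <- rank_matches(matches)
  if (!is.null(organisms) && length(organisms) > 0) {
    matches <- rerank_by_species(matches, organisms)
  }
  matches
}

# Deterministic ranking: score desc, then status rank, mismatch count,
# source, namespace, identifier, text (C-locale).
rank_matches <- function(matches) {
  if (nrow(matches) > 0) {
    matches <- matches[order(-matches$score, status_rank(matches$status),
                             matches$n_mismatches, matches$source,
                             matches$namespace, matches$identifier,
                             rank_c(matches$text)), ]
  }
  if (!inherits(matches, "grounding_matches")) {
    class(matches) <- c("grounding_matches", class(matches))
  }
  matches
}

# C-locale (byte order) ranks, for locale-independent tie-breaks.
rank_c <- function(x) {
  xtfrm(factor(x, levels = stringr::str_sort(unique(x), locale = "C")))
}

#' Plot grounded matches
#'
#' Bar chart of match scores by entity, coloured by term status.
#'
#' @param object A `grounding_matches` tibble from [ground()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grounding_matches <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$entity <- stats::reorder(paste0(df$namespace, ":", df$identifier), df$score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$entity, y = .data$score,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "match score", fill = "status")
}
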