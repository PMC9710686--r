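# Synthetic fixtures: a small protein-kinase-C lexicon for the worked
# example, plus seeded generators for synthetic lexicons and labeled sense
# corpora so everything is testable without downloads.

#' The protein kinase C delta worked-example lexicon
#'
#' Four terms: three lexicalizations of the human gene HGNC:9399 (standard
#' symbol PRKCD) -- "PKCD" with status `synonym`, "PKCdelta" and "PKCδ"
#' with status `curated` -- plus a distractor standard-name term "MAP2K1".
#' Grounding "PKC-Delta" against this lexicon exercises the full variant /
#' scoring / dedup pipeline.
#'
#' @return A term tibble with 4 rows.
#' @export
pkc_fixture <- function() {
  dplyr::bind_rows(
    term_table("HGNC", "9399", "PKCD", "synonym", "PRKCD", "hgnc",
               organism = "9606"),
    term_table("HGNC", "9399", "PKCdelta", "curated", "PRKCD", "hgnc",
               organism = "9606"),
    term_table("HGNC", "9399", "PKCδ", "curated", "PRKCD", "hgnc",
               organism = "9606"),
    term_table("HGNC", "6840", "MAP2K1", "standard_name", "MAP2K1", "hgnc",
               organism = "9606")
  )
}

# Pronounceable-ish deterministic symbol for entity i, e.g. "BAQ3".
synth_symbol <- function(i) {
  cons <- c("B", "C", "D", "F", "G", "H", "K", "L", "M", "N", "P", "Q", "R",
            "S", "T", "V", "W", "X", "Z")
  vow <- c("A", "E", "I", "O", "U")
  paste0(cons[(i - 1L) %% 19L + 1L], vow[(i - 1L) %/% 19L %% 5L + 1L],
         cons[(i - 1L) %/% 95L %% 19L + 1L], (i - 1L) %/% 1805L + 1L)
}

#' Generate a synthetic lexicon
#'
#' Builds a deterministic (seeded) term table emulating the ambiguity
#' structure of a real synonym lexicon: each entity gets a standard name
#' plus extra synonyms, a fraction of synonym strings is shared between two
#' distinct entities (ambiguity), and a fraction carries a Greek element.
#'
#' @param n_entities Number of entities.
#' @param synonyms_per_entity Integer range `c(min, max)` of extra synonyms
#'   per entity (in addition to the standard name).
#' @param ambiguity_rate Shared synonym strings per entity
#'   (`round(ambiguity_rate * n_entities)` texts are each assigned to two
#'   distinct entities).
#' @param greek_rate Fraction of extra synonyms given a Greek suffix.
#' @param organism_pool Optional character vector of taxonomy ids sampled
#'   per entity.
#' @param seed Integer seed; generation is a pure function of the arguments.
#' @return A validated term tibble.
#' @export
generate_lexicon <- function(n_entities, synonyms_per_entity = c(1L, 3L),
                             ambiguity_rate = 0, greek_rate = 0,
                             organism_pool = NULL, seed = 1L) {
  stopifnot(n_entities >= 1, ambiguity_rate >= 0, ambiguity_rate <= 1,
            greek_rate >= 0, greek_rate <= 1)
  if (ambiguity_rate > 0 && n_entities < 2) {
    stop("ambiguity requires at least 2 entities", call. = FALSE)
  }
  withr::with_seed(seed, {
    rows <- vector("list", n_entities)
    greek <- the$greek_names
    for (i in seq_len(n_entities)) {
      std <- synth_symbol(i)
      n_syn <- sample(synonyms_per_entity[1]:synonyms_per_entity[2], 1L)
      texts <- std
      statuses <- "standard_name"
      if (n_syn > 0) {
        for (k in seq_len(n_syn)) {
          syn <- paste0(std, "-", k)
          if (stats::runif(1) < greek_rate) {
            syn <- paste0(std, "-", sample(greek, 1L))
          }
          texts <- c(texts, syn)
          statuses <- c(statuses, sample(c("curated", "synonym"), 1L))
        }
      }
      rows[[i]] <- term_table(
        namespace = "SYNT", identifier = sprintf("E%04d", i), text = texts,
        status = statuses, standard_name = std, source = "synth",
        organism = if (is.null(organism_pool)) NA_character_ else
          sample(organism_pool, 1L))
    }
    terms <- dplyr::bind_rows(rows)
    n_shared <- round(ambiguity_rate * n_entities)
    if (n_shared > 0) {
      shared_rows <- lapply(seq_len(n_shared), function(k) {
        pair <- sample.int(n_entities, 2L)
        text <- paste0("AMB", synth_symbol(k))
        std <- synth_symbol(pair)
        term_table(namespace = "SYNT",
                   identifier = sprintf("E%04d", pair),
                   text = text, status = "synonym", standard_name = std,
                   source = "synth",
                   organism = if (is.null(organism_pool)) NA_character_ else
                     sample(organism_pool, 2L, replace = TRUE))
      })
      terms <- dplyr::bind_rows(terms, dplyr::bind_rows(shared_rows))
    }
    terms
  })
}

#' Generate a synthetic labeled sense corpus
#'
#' Emulates the labeled documents behind a sense classifier: each sense has
#' a vocabulary (a disjoint part plus a part shared across all senses, per
#' `shared_vocab_fraction`) and documents are bags of words sampled from a
#' Zipf-weighted multinomial over that vocabulary.  `shared_vocab_fraction
#' = 0` makes senses perfectly separable; `= 1` makes labels independent of
#' the text.
#'
#' @param entity_text The shared ambiguous string.
#' @param n_senses Number of senses (>= 2).
#' @param docs_per_sense Documents per sense.
#' @param vocab_size_per_sense Words in each sense's vocabulary.
#' @param shared_vocab_fraction Fraction of each sense's vocabulary drawn
#'   from a pool common to all senses, in `[0, 1]`.
#' @param doc_length Words per document.
#' @param senses Optional sense labels; default `"SYNT:S1"`, `"SYNT:S2"`, ...
#' @param seed Integer seed; generation is a pure function of the arguments.
#' @return A `labeled_corpus`.
#' @export
generate_ambiguous_corpus <- function(entity_text = "AMB1", n_senses = 2L,
                                      docs_per_sense = 100L,
                                      vocab_size_per_sense = 50L,
                                      shared_vocab_fraction = 0,
                                      doc_length = 30L, senses = NULL,
                                      seed = 1L) {
  stopifnot(n_senses >= 2, docs_per_sense >= 1, vocab_size_per_sense >= 2,
            shared_vocab_fraction >= 0, shared_vocab_fraction <= 1,
            doc_length >= 1)
  if (is.null(senses)) senses <- sprintf("SYNT:S%d", seq_len(n_senses))
  stopifnot(length(senses) == n_senses)
  n_shared <- round(shared_vocab_fraction * vocab_size_per_sense)
  shared_pool <- sprintf("shared%04d", seq_len(max(n_shared, 1L)))
  withr::with_seed(seed, {
    docs <- vector("list", n_senses)
    for (s in seq_len(n_senses)) {
      own <- sprintf("sense%d word%04d", s,
                     seq_len(vocab_size_per_sense - n_shared))
      own <- gsub(" ", "", own)
      vocab <- c(if (n_shared > 0) shared_pool[seq_len(n_shared)], own)
      w <- 1 / seq_along(vocab)  # Zipf weights
      texts <- vapply(seq_len(docs_per_sense), function(d) {
        paste(sample(vocab, doc_length, replace = TRUE, prob = w),
              collapse = " ")
      }, character(1))
      docs[[s]] <- tibble::tibble(
        doc_id = sprintf("doc_s%d_%04d", s, seq_len(docs_per_sense)),
        text = texts, label = senses[s])
    }
  })
  labeled_corpus(entity_text, dplyr::bind_rows(docs))
}
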