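# Match-feature extraction and scoring.
#
# A candidate pair (original query string, matched term text) is compared on
# the ORIGINAL strings -- not their canonical forms -- and the resulting
# features are combined with the term's status into a score in [0, 1].

TERM_STATUSES <- c("standard_name", "curated", "synonym", "former_name")

status_rank <- function(status) match(status, TERM_STATUSES)

#' Scoring constants
#'
#' Returns the scoring-constant set: per-feature string-similarity penalties
#' and per-status multipliers, all in (0, 1].  The packaged defaults live in
#' `inst/extdata/scoring_constants.json` and are calibrated so that an exact
#' match of a standard name scores exactly 1 and the "PKC-Delta" worked
#' example surfaces its curated term at 0.9936.
#'
#' @param path Optional path to an alternative JSON constants file.
#' @return A list with elements `penalties` and `status_multipliers`.
#' @export
scoring_constants <- function(path = NULL) {
  if (is.null(path)) return(the$scoring)
  read_scoring_constants(path)
}

read_scoring_constants <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need_pen <- c("separator_mismatch", "cap_flip", "cap_mixed", "plural", "unaligned")
  if (!all(need_pen %in% names(cfg$penalties)) ||
      !all(TERM_STATUSES %in% names(cfg$status_multipliers))) {
    stop("invalid scoring constants file: ", path, call. = FALSE)
  }
  vals <- unlist(c(cfg$penalties, cfg$status_multipliers))
  if (any(vals <= 0 | vals > 1)) {
    stop("scoring constants must lie in (0, 1]", call. = FALSE)
  }
  cfg[c("penalties", "status_multipliers")]
}

#' Compare an entity string with a matched term text
#'
#' Character-level comparison of the original (not canonicalized) query
#' against a term text whose canonical form collided with one of the query's
#' variants.  The query is tokenized on separators and aligned against the
#' reference, allowing Greek-name/Greek-letter/Latin-initial substitutions
#' and query-side plural stripping.  Features recorded per §details:
#'
#' * `exact`: the strings are identical (after NFC);
#' * `space_dash_mismatch`: count of positions where one side has a
#'   space/dash separator and the other does not;
#' * `cap_profile`: per-token capitalization comparison, each one of
#'   `"same"`, `"query_upper_ref_lower"`, `"query_lower_ref_upper"`,
#'   `"mixed"`;
#' * `plural_dropped`: the query aligned only after dropping a trailing
#'   plural marker.
#'
#' @param query Original entity string.
#' @param ref The matched term's stored text.
#' @return A list of class `match_features`.
#' @export
compare_strings <- function(query, ref) {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(ref), length(ref) == 1L)
  q <- nfc(query); r <- nfc(ref)
  if (q == r) {
    return(features(q, r, exact = TRUE, sep = 0L, caps = character(0),
                    plural = FALSE, aligned = TRUE))
  }
  qtokens <- tokenize_seps(q)
  al <- align_query(qtokens, r)
  plural <- FALSE
  if (is.null(al)) {
    qp <- drop_plural_token(qtokens)
    if (!is.null(qp)) {
      al <- align_query(qp, r)
      plural <- !is.null(al)
    }
  }
  if (is.null(al)) {
    # canonical collision we cannot explain char-by-char; score conservatively
    nseps <- function(s) stringr::str_count(s, paste0("(", .sep_regex, "|\\s)+"))
    return(features(q, r, exact = FALSE, sep = abs(nseps(q) - nseps(r)),
                    caps = rep("mixed", length(qtokens)), plural = FALSE,
                    aligned = FALSE))
  }
  features(q, r, exact = FALSE, sep = al$sep_mismatch, caps = al$caps,
           plural = plural, aligned = TRUE)
}

features <- function(query, ref, exact, sep, caps, plural, aligned) {
  structure(list(query = query, ref = ref, exact = exact,
                 space_dash_mismatch = as.integer(sep), cap_profile = caps,
                 plural_dropped = plural, aligned = aligned),
            class = "match_features")
}

tokenize_seps <- function(x) {
  toks <- stringr::str_split_1(x, paste0("(", .sep_regex, "|\\s)+"))
  toks[nzchar(toks)]
}

# Drop a trailing plural marker from the last token; NULL when no rule fires.
drop_plural_token <- function(tokens) {
  last <- tokens[length(tokens)]
  low <- stringr::str_to_lower(last)
  if (stringr::str_ends(low, "ies") && nchar(last) >= 4L) {
    tokens[length(tokens)] <- paste0(stringr::str_sub(last, 1L, -4L), "y")
    return(tokens)
  }
  if (stringr::str_ends(low, "s") && !stringr::str_ends(low, "ss") &&
      nchar(last) >= 4L) {
    tokens[length(tokens)] <- stringr::str_sub(last, 1L, -2L)
    return(tokens)
  }
  NULL
}

# Align query tokens against the reference string.  Returns NULL on failure,
# else list(sep_mismatch, caps).  Separators inside the reference are
# consumed freely but counted as mismatches when the query has none at that
# point; a query token boundary with no reference separator is a mismatch.
align_query <- function(qtokens, ref) {
  rch <- strsplit(ref, "", fixed = TRUE)[[1]]
  is_sep <- stringr::str_detect(rch, paste0("(", .sep_regex, "|\\s)"))
  n <- length(rch)
  pos <- 1L
  sep_mismatch <- 0L
  caps <- character(length(qtokens))

  skip_seps <- function(pos) {
    while (pos <= n && is_sep[pos]) pos <- pos + 1L
    pos
  }

  for (t in seq_along(qtokens)) {
    if (t > 1L) {
      # query has a separator here
      if (pos <= n && is_sep[pos]) pos <- skip_seps(pos)
      else sep_mismatch <- sep_mismatch + 1L
    }
    res <- consume_token(qtokens[t], rch, is_sep, pos)
    if (is.null(res)) return(NULL)
    pos <- res$pos
    sep_mismatch <- sep_mismatch + res$sep_mismatch
    caps[t] <- res$cap
  }
  pos <- skip_seps(pos)
  if (pos <= n) return(NULL)  # unconsumed reference characters
  list(sep_mismatch = sep_mismatch, caps = caps)
}

# Consume one query token from the reference starting at pos.  Tries literal
# consumption, whole-token Greek substitution, then stem + Greek suffix.
consume_token <- function(qt, rch, is_sep, pos) {
  lit <- consume_literal(qt, rch, is_sep, pos)
  if (!is.null(lit)) {
    return(list(pos = lit$pos, sep_mismatch = lit$sep_mismatch,
                cap = cap_compare(qt, lit$segment)))
  }
  qlow <- stringr::str_to_lower(qt)
  g <- consume_greek(qt, qlow, rch, is_sep, pos)
  if (!is.null(g)) return(g)
  # stem + trailing Greek element (e.g. query token "PKCdelta" vs ref "PKCδ")
  split <- greek_suffix(qlow)
  if (!is.null(split)) {
    stem_len <- nchar(qt) - (nchar(qlow) - nchar(split$stem))
    stem <- stringr::str_sub(qt, 1L, stem_len)
    suffix <- stringr::str_sub(qt, stem_len + 1L)
    lit <- consume_literal(stem, rch, is_sep, pos)
    if (!is.null(lit)) {
      g <- consume_greek(suffix, stringr::str_to_lower(suffix), rch, is_sep, lit$pos)
      if (!is.null(g)) {
        cap1 <- cap_compare(stem, lit$segment)
        cap <- if (identical(cap1, g$cap)) cap1 else worst_cap(c(cap1, g$cap))
        return(list(pos = g$pos, sep_mismatch = lit$sep_mismatch + g$sep_mismatch,
                    cap = cap))
      }
    }
  }
  NULL
}

# Whole-token Greek equivalences: name <-> letter, name -> Latin initial,
# letter -> Latin initial.
consume_greek <- function(qt, qlow, rch, is_sep, pos) {
  n <- length(rch)
  if (pos > n) return(NULL)
  if (qlow %in% the$greek_names) {
    letter <- the$greek_lower[[qlow]]
    upper <- the$greek[the$greek$name == qlow, "upper"]
    if (rch[pos] %in% c(letter, upper)) {
      return(list(pos = pos + 1L, sep_mismatch = 0L,
                  cap = cap_case_compare(qt, rch[pos])))
    }
    init <- the$name_to_initial[[qlow]]
    if (stringr::str_to_lower(rch[pos]) == init) {
      return(list(pos = pos + 1L, sep_mismatch = 0L,
                  cap = cap_case_compare(qt, rch[pos])))
    }
    return(NULL)
  }
  if (is_greek_letter(qlow) || is_greek_letter(qt)) {
    nm <- the$letter_to_name[[qt]]
    if (is.null(nm)) nm <- the$letter_to_name[[qlow]]
    lit <- consume_literal(nm, rch, is_sep, pos)
    if (!is.null(lit)) {
      return(list(pos = lit$pos, sep_mismatch = lit$sep_mismatch,
                  cap = cap_case_compare(qt, lit$segment)))
    }
    if (stringr::str_to_lower(rch[pos]) == the$name_to_initial[[nm]]) {
      return(list(pos = pos + 1L, sep_mismatch = 0L,
                  cap = cap_case_compare(qt, rch[pos])))
    }
  }
  NULL
}

# Literal, case-insensitive consumption of `qt`; reference separators are
# skipped, each run counting one separator mismatch.
consume_literal <- function(qt, rch, is_sep, pos) {
  qch <- strsplit(qt, "", fixed = TRUE)[[1]]
  n <- length(rch)
  sep_mismatch <- 0L
  seg <- character(0)
  for (qc in qch) {
    if (pos <= n && is_sep[pos]) {
      sep_mismatch <- sep_mismatch + 1L
      while (pos <= n && is_sep[pos]) pos <- pos + 1L
    }
    if (pos > n) return(NULL)
    if (stringr::str_to_lower(rch[pos]) != stringr::str_to_lower(qc)) return(NULL)
    seg <- c(seg, rch[pos])
    pos <- pos + 1L
  }
  list(pos = pos, sep_mismatch = sep_mismatch,
       segment = paste0(seg, collapse = ""))
}

cap_pattern <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  letters_only <- ch[stringr::str_detect(ch, "\\p{L}")]
  if (length(letters_only) == 0) return("none")
  up <- stringr::str_detect(letters_only, "\\p{Lu}")
  if (all(up)) return("upper")
  if (!any(up)) return("lower")
  if (up[1] && !any(up[-1])) return("initial")
  "mixed"
}

cap_compare <- function(qt, seg) {
  qp <- cap_pattern(qt); rp <- cap_pattern(seg)
  if (qp == rp || qp == "none" || rp == "none") return("same")
  if ((qp == "initial" && rp == "upper" && nchar(seg) == 1L) ||
      (rp == "initial" && qp == "upper" && nchar(qt) == 1L)) {
    return("same")  # single capital letter vs initial-capitalized token
  }
  if (qp %in% c("upper", "initial") && rp == "lower") return("query_upper_ref_lower")
  if (qp == "lower" && rp %in% c("upper", "initial")) return("query_lower_ref_upper")
  "mixed"
}

# First-character case comparison, used across Greek substitutions where
# whole-pattern comparison is meaningless.
cap_case_compare <- function(qt, seg) {
  qu <- stringr::str_detect(stringr::str_sub(qt, 1L, 1L), "\\p{Lu}")
  ru <- stringr::str_detect(stringr::str_sub(seg, 1L, 1L), "\\p{Lu}")
  if (qu == ru) "same" else if (qu) "query_upper_ref_lower" else "query_lower_ref_upper"
}

worst_cap <- function(caps) {
  order <- c("same", "query_upper_ref_lower", "query_lower_ref_upper", "mixed")
  order[max(match(caps, order))]
}

#' Score a candidate match
#'
#' Combines string-similarity features with the matched term's status:
#' `score = string_similarity * status_multiplier`.  The similarity is 1 for
#' an exact match and otherwise the product of per-feature penalties
#' (separator mismatches, per-token capitalization differences, plural
#' stripping), so an exact match of a standard name scores exactly 1 and the
#' score is strictly decreasing in every mismatch feature.  Status
#' multipliers order standard name > curated > synonym > former name and are
#' spaced so that status dominates among near-equal similarities.
#'
#' @param features A `match_features` object from [compare_strings()].
#' @param status Term status, one of
#'   `"standard_name"`, `"curated"`, `"synonym"`, `"former_name"`.
#' @param constants Scoring constants, see [scoring_constants()].
#' @return A single number in `[0, 1]`.
#' @export
score_match <- function(features, status, constants = scoring_constants()) {
  stopifnot(inherits(features, "match_features"))
  status <- match.arg(status, TERM_STATUSES)
  p <- constants$penalties
  sim <- if (features$exact) 1 else {
    s <- p$separator_mismatch^features$space_dash_mismatch
    for (cp in features$cap_profile) {
      s <- s * switch(cp, same = 1,
                      query_upper_ref_lower = p$cap_flip,
                      query_lower_ref_upper = p$cap_flip,
                      mixed = p$cap_mixed)
    }
    if (features$plural_dropped) s <- s * p$plural
    if (!features$aligned) s <- s * p$unaligned
    s
  }
  unname(sim * constants$status_multipliers[[status]])
}

# number of non-clean features, used in tie-breaks
n_mismatches <- function(features) {
  features$space_dash_mismatch + sum(features$cap_profile != "same") +
    features$plural_dropped + !features$aligned
}
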