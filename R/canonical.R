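# String canonicalization and orthographic variant generation.
#
# Every index key and every lookup goes through canonicalize(); variant
# generation produces the alternative spellings (separator handling, Greek
# letter substitution / spell-out, plural stripping) that are each looked up
# exactly in the index.

the <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  path <- system.file("extdata", "greek_letters.tsv", package = pkgname)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", quote = "")
  the$greek <- tab
  the$greek_names <- tab$name
  the$greek_lower <- stats::setNames(tab$lower, tab$name)
  the$greek_letters <- c(tab$lower, tab$upper)
  # letter (either case) -> spelled-out name
  the$letter_to_name <- stats::setNames(rep(tab$name, 2L), c(tab$lower, tab$upper))
  the$name_to_initial <- stats::setNames(tab$initial, tab$name)
  the$scoring <- read_scoring_constants(
    system.file("extdata", "scoring_constants.json", package = pkgname))
  the$mesh_taxonomy <- utils::read.delim(
    system.file("extdata", "mesh_taxonomy.tsv", package = pkgname),
    header = FALSE, col.names = c("mesh", "taxonomy"),
    colClasses = "character", quote = "")
  invisible()
}

# Unicode dash class plus the minus sign; all are treated as separators.
.sep_regex <- "[\\p{Pd}−]"

#' Canonicalize an entity string
#'
#' Produces the normal form used as the lookup key of a [grounding index]
#' [build_index()]: Unicode NFC, the micro sign folded to Greek mu, every
#' dash/hyphen replaced by a space, runs of whitespace collapsed, leading and
#' trailing whitespace stripped, and the result lowercased (locale
#' independent, so Greek capitals fold too).  The function is idempotent.
#'
#' @param text Character vector of non-empty strings.
#' @return Character vector of canonical forms, same length as `text`.
#' @examples
#' canonicalize("PKC-Delta")  # "pkc delta"
#' @export
canonicalize <- function(text) {
  if (!is.character(text) || length(text) == 0) {
    stop("`text` must be a non-empty character vector", call. = FALSE)
  }
  if (anyNA(text)) stop("`text` must not contain NA", call. = FALSE)
  x <- nfc(text)
  x <- stringr::str_replace_all(x, .sep_regex, " ")
  x <- stringr::str_squish(x)
  if (any(x == "")) {
    stop("cannot canonicalize an empty or whitespace-only string", call. = FALSE)
  }
  stringr::str_to_lower(x)
}

# NFC normalization + micro sign -> Greek mu. Applied before any comparison.
nfc <- function(x) {
  chartr("µ", "μ", stringi::stri_trans_nfc(x))
}

is_greek_letter <- function(ch) ch %in% the$greek_letters

#' Generate lookup variants for an entity string
#'
#' Expands an input string into the set of canonicalized orthographic
#' variants that are each looked up exactly in the grounding index:
#'
#' * the canonical form itself (separators as spaces);
#' * the separator-removed form;
#' * Greek-name tokens substituted by the Greek letter and contracted to the
#'   single Latin initial (on the separator-removed form);
#' * Greek letters spelled out as their names (spaced and separator-removed
#'   forms), and contracted to the Latin initial;
#' * a trailing Greek element inside a token is also recognised and split;
#' * a plural-stripped form of each variant (trailing "s" with a stem of at
#'   least 3 characters; "-ies" to "y").
#'
#' Greek substitution is applied to one token per variant so the expansion
#' stays linear in the number of tokens.  The result is unique, canonical and
#' in deterministic order (first occurrence wins).
#'
#' @param text A single non-empty string.
#' @return Character vector of canonical variants; the canonical form of
#'   `text` is always the first element.
#' @examples
#' generate_variants("PKC-Delta")
#' @export
generate_variants <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    stop("`text` must be a single string", call. = FALSE)
  }
  base <- canonicalize(text)
  tokens <- strsplit(base, " ", fixed = TRUE)[[1]]
  out <- base
  joined <- paste0(tokens, collapse = "")
  out <- c(out, joined)

  # Greek handling, one token substituted per variant.
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    sub_join <- function(repl) {
      t2 <- tokens; t2[i] <- repl
      paste0(t2, collapse = "")
    }
    sub_space <- function(repl) {
      t2 <- tokens; t2[i] <- repl
      paste(t2, collapse = " ")
    }
    if (tok %in% the$greek_names) {
      out <- c(out, sub_join(the$name_to_initial[[tok]]),
               sub_join(the$greek_lower[[tok]]))
    } else if (tok %in% the$greek$lower) {
      nm <- the$letter_to_name[[tok]]
      out <- c(out, sub_space(nm), sub_join(nm),
               sub_join(the$name_to_initial[[nm]]))
    } else {
      # trailing Greek element inside a token, e.g. "pkcdelta" or "tnfα"
      hit <- greek_suffix(tok)
      if (!is.null(hit)) {
        stem <- hit$stem; nm <- hit$name
        out <- c(out, sub_space(paste(stem, nm)),
                 sub_join(paste0(stem, the$greek_lower[[nm]])),
                 sub_join(paste0(stem, the$name_to_initial[[nm]])),
                 sub_join(paste0(stem, nm)))
      }
    }
  }

  out <- c(out, unlist(lapply(out, strip_plural), use.names = FALSE))
  unique(out[nzchar(out)])
}

# Detect a trailing Greek name or letter in a canonical token; stem >= 2.
greek_suffix <- function(tok) {
  for (nm in the$greek_names) {
    if (stringr::str_ends(tok, nm) && nchar(tok) >= nchar(nm) + 2L) {
      return(list(stem = stringr::str_sub(tok, 1L, nchar(tok) - nchar(nm)),
                  name = nm))
    }
  }
  last <- stringr::str_sub(tok, -1L)
  if (last %in% the$greek$lower && nchar(tok) >= 3L) {
    return(list(stem = stringr::str_sub(tok, 1L, nchar(tok) - 1L),
                name = the$letter_to_name[[last]]))
  }
  NULL
}

# Plural stripping on the last word of a canonical string; returns
# character(0) when no rule applies.
strip_plural <- function(x) {
  if (stringr::str_ends(x, "ies") && nchar(x) >= 4L) {
    return(paste0(stringr::str_sub(x, 1L, nchar(x) - 3L), "y"))
  }
  if (stringr::str_ends(x, "s") && !stringr::str_ends(x, "ss")) {
    words <- strsplit(x, " ", fixed = TRUE)[[1]]
    stem <- stringr::str_sub(words[length(words)], 1L, -2L)
    if (nchar(stem) >= 3L) {
      return(stringr::str_sub(x, 1L, nchar(x) - 1L))
    }
  }
  character(0)
}
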