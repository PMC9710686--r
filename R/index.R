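# The grounding index: a term table keyed by canonical text in a hash map
# (an R environment), giving constant-time average candidate lookup
# independent of the total number of terms.

#' Build a grounding index
#'
#' Indexes a term table by canonicalized text.  Duplicate
#' (namespace, identifier, text, status, organism) tuples under one key are
#' collapsed at build time (loaders keep source files verbatim); the number
#' dropped is recorded in the build report.
#'
#' @param terms A term tibble (see [term_table()]).
#' @param merge_genes_proteins Flag recorded in the index config noting
#'   whether gene/protein synonym sets were merged upstream
#'   (see [merge_gene_protein()]).
#' @return A `grounding_index` object.
#' @seealso [lookup()], [index_report()]
#' @export
build_index <- function(terms, merge_genes_proteins = TRUE) {
  terms <- validate_terms(terms)
  n_input <- nrow(terms)
  dup <- duplicated(paste(terms$canonical, terms$namespace, terms$identifier,
                          terms$text, terms$status, terms$organism,
                          sep = "\r"))
  terms <- terms[!dup, ]
  map <- new.env(parent = emptyenv(), hash = TRUE,
                 size = max(29L, nrow(terms)))
  if (nrow(terms) > 0) {
    idx_by_key <- split(seq_len(nrow(terms)), terms$canonical)
    for (key in names(idx_by_key)) assign(key, idx_by_key[[key]], envir = map)
  }
  report <- list(
    n_input = n_input,
    n_indexed = nrow(terms),
    n_duplicates_dropped = n_input - nrow(terms),
    n_keys = length(ls(map, all.names = TRUE)),
    by_source = as.list(table(terms$source)),
    by_status = as.list(table(terms$status))
  )
  structure(list(terms = terms, map = map,
                 config = list(merge_genes_proteins = merge_genes_proteins),
                 report = report),
            class = "grounding_index")
}

#' @export
print.grounding_index <- function(x, ...) {
  cat("<grounding_index> ", x$report$n_indexed, " terms under ",
      x$report$n_keys, " canonical keys\n", sep = "")
  invisible(x)
}

#' Index build report
#'
#' Term counts of an index build: input rows, indexed rows, duplicates
#' collapsed, distinct keys, and per-source / per-status tallies.  Written as
#' JSON when `path` is given.
#'
#' @param index A `grounding_index`.
#' @param path Optional path to write the report as JSON.
#' @return The report list, invisibly when `path` is given.
#' @export
index_report <- function(index, path = NULL) {
  stopifnot(inherits(index, "grounding_index"))
  if (is.null(path)) return(index$report)
  jsonlite::write_json(index$report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(index$report)
}

#' Look up canonical variants in a grounding index
#'
#' Returns the union over `variants` of exact canonical-key hits: one row
#' per (term, variant that hit it) -- the pre-deduplication candidate list of
#' the grounding pipeline.
#'
#' @param index A `grounding_index`.
#' @param variants Character vector of canonical strings, typically from
#'   [generate_variants()].
#' @return A tibble of term rows plus a `variant_used` column; zero rows
#'   when no key matches.
#' @export
lookup <- function(index, variants) {
  stopifnot(inherits(index, "grounding_index"), is.character(variants))
  hits <- lapply(variants, function(v) {
    rows <- get0(v, envir = index$map, inherits = FALSE)
    if (is.null(rows)) return(NULL)
    out <- index$terms[rows, ]
    out$variant_used <- v
    out
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0) {
    out <- term_table0()
    out$variant_used <- character(0)
    return(out)
  }
  dplyr::bind_rows(hits)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Glance at a grounding index
#'
#' One-row summary of the index: term and key counts and the duplicate count
#' collapsed at build time.
#'
#' @param x A `grounding_index`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.grounding_index <- function(x, ...) {
  tibble::tibble(
    n_terms = x$report$n_indexed,
    n_keys = x$report$n_keys,
    n_duplicates_dropped = x$report$n_duplicates_dropped,
    merge_genes_proteins = x$config$merge_genes_proteins
  )
}

#' Tidy a grounding index
#'
#' Returns the indexed term table (after duplicate collapse), one row per
#' term.
#'
#' @param x A `grounding_index`.
#' @param ... Unused.
#' @return A term tibble.
#' @export
tidy.grounding_index <- function(x, ...) x$terms
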