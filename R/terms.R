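# The term data model and its loaders.
#
# A term is one lexicalization of one entity.  Term tables are tibbles with
# one row per term and a fixed column set; the on-disk form is a 9-column
# UTF-8 TSV (namespace, identifier, text, status, canonical, standard_name,
# source, source_ns:source_id, organism), no header, gzip-transparent.

TERM_COLUMNS <- c("namespace", "identifier", "text", "status", "canonical",
                  "standard_name", "source", "source_namespace",
                  "source_identifier", "organism")

#' Construct a term table
#'
#' Builds a validated tibble of terms (one row per lexicalization).  The
#' `canonical` column is recomputed from `text` via [canonicalize()] when not
#' supplied, and is checked when it is.
#'
#' @param namespace,identifier Ontology namespace code (e.g. `"HGNC"`) and
#'   identifier within it.
#' @param text The name or synonym as it appears in the source.
#' @param status One of `"standard_name"`, `"curated"`, `"synonym"`,
#'   `"former_name"`.
#' @param standard_name The entity's preferred label.
#' @param source Provenance resource code.
#' @param canonical Optional canonical form; recomputed when `NA`.
#' @param source_namespace,source_identifier Set together iff the term was
#'   created by mapping from another namespace.
#' @param organism Optional taxonomy identifier for gene/protein terms.
#' @return A tibble with columns
#'   `r paste0('\x60', TERM_COLUMNS, '\x60', collapse = ", ")`.
#' @export
term_table <- function(namespace, identifier, text, status, standard_name,
                       source, canonical = NA_character_,
                       source_namespace = NA_character_,
                       source_identifier = NA_character_,
                       organism = NA_character_) {
  out <- tibble::tibble(
    namespace = as.character(namespace),
    identifier = as.character(identifier),
    text = as.character(text),
    status = as.character(status),
    canonical = as.character(canonical),
    standard_name = as.character(standard_name),
    source = as.character(source),
    source_namespace = as.character(source_namespace),
    source_identifier = as.character(source_identifier),
    organism = as.character(organism)
  )
  out$text <- nfc(out$text)
  missing_canon <- is.na(out$canonical) | out$canonical == ""
  if (any(missing_canon)) {
    out$canonical[missing_canon] <- canonicalize(out$text[missing_canon])
  }
  validate_terms(out)
}

#' Validate a term table
#'
#' Checks the term-table invariants: all required fields non-empty, a known
#' status, `canonical == canonicalize(text)`, and `source_namespace` /
#' `source_identifier` both present or both absent.
#'
#' @param terms A term tibble.
#' @return The input, invisibly unchanged, as a tibble.
#' @export
validate_terms <- function(terms) {
  terms <- tibble::as_tibble(terms)
  missing_cols <- setdiff(TERM_COLUMNS, names(terms))
  if (length(missing_cols)) {
    stop("term table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  terms <- terms[TERM_COLUMNS]
  if (nrow(terms) == 0) return(terms)
  required <- c("namespace", "identifier", "text", "standard_name", "source")
  for (col in required) {
    bad <- is.na(terms[[col]]) | terms[[col]] == ""
    if (any(bad)) {
      stop("term rows ", paste(which(bad), collapse = ", "),
           " have empty `", col, "`", call. = FALSE)
    }
  }
  bad_status <- !terms$status %in% TERM_STATUSES
  if (any(bad_status)) {
    stop("unknown term status: ",
         paste(unique(terms$status[bad_status]), collapse = ", "), call. = FALSE)
  }
  recomputed <- canonicalize(terms$text)
  off <- terms$canonical != recomputed
  if (any(off)) {
    stop("`canonical` disagrees with canonicalize(text) at rows ",
         paste(utils::head(which(off), 5), collapse = ", "), call. = FALSE)
  }
  half_mapped <- xor(is.na(terms$source_namespace), is.na(terms$source_identifier))
  if (any(half_mapped)) {
    stop("source_namespace and source_identifier must be set together (rows ",
         paste(which(half_mapped), collapse = ", "), ")", call. = FALSE)
  }
  terms
}

#' Read a term table from TSV
#'
#' Reads the 9-column tab-separated term-table dialect (no header, UTF-8,
#' gzip-transparent): namespace, identifier, text, status, canonical,
#' standard_name, source, `source_ns:source_id` (or empty), organism (or
#' empty).  The canonical form is recomputed when the column is empty and row
#' order is preserved.
#'
#' @param path Path to a `.tsv` or `.tsv.gz` file.
#' @return A validated term tibble.
#' @export
read_terms <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(term_table0())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 7L | nf > 9L)
  if (length(bad)) {
    stop("malformed term row at line ", bad[1], ": expected 9 tab-separated ",
         "fields, found ", nf[bad[1]], call. = FALSE)
  }
  # right-pad optional trailing fields
  mat <- t(vapply(fields, function(f) c(f, rep("", 9L - length(f)))[1:9],
                  character(9)))
  mapped <- strsplit(mat[, 8], ":", fixed = TRUE)
  src_ns <- vapply(mapped, function(m) if (length(m) >= 1 && nzchar(m[1])) m[1] else NA_character_, "")
  src_id <- vapply(mapped, function(m) if (length(m) >= 2) m[2] else NA_character_, "")
  blank_na <- function(x) ifelse(x == "", NA_character_, x)
  term_table(
    namespace = mat[, 1], identifier = mat[, 2], text = mat[, 3],
    status = mat[, 4], canonical = blank_na(mat[, 5]),
    standard_name = mat[, 6], source = mat[, 7],
    source_namespace = src_ns, source_identifier = src_id,
    organism = blank_na(mat[, 9])
  )
}

term_table0 <- function() {
  term_table(character(0), character(0), character(0), character(0),
             character(0), character(0))
}

#' Write a term table to TSV
#'
#' Inverse of [read_terms()]: `read_terms(write_terms(terms, path))`
#' reproduces `terms` exactly.
#'
#' @param terms A validated term tibble.
#' @param path Output path; a `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_terms <- function(terms, path) {
  terms <- validate_terms(terms)
  blank <- function(x) ifelse(is.na(x), "", x)
  mapped <- ifelse(is.na(terms$source_namespace), "",
                   paste0(blank(terms$source_namespace), ":",
                          blank(terms$source_identifier)))
  lines <- paste(terms$namespace, terms$identifier, terms$text, terms$status,
                 terms$canonical, terms$standard_name, terms$source, mapped,
                 blank(terms$organism), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

#' Load terms from an OBO ontology
#'
#' Parses an OBO 1.4 flat file into a term table: each `[Term]` stanza
#' contributes its name (status `standard_name`) plus its synonyms, with the
#' synonym scope mapped to a term status via `synonym_scopes` (default: only
#' `EXACT` synonyms are kept, as `synonym`; other scopes are skipped).
#' Obsolete stanzas are skipped unless `keep_obsolete = TRUE`, in which case
#' their lexicalizations get status `former_name`.  Stanzas without a name
#' are skipped with a warning.
#'
#' @param path Path to an OBO file.
#' @param namespace Namespace code for the resulting terms; defaults to the
#'   prefix of the stanza ids (e.g. `"GO"` from `GO:0006915`).
#' @param source Provenance code; defaults to lowercased `namespace`.
#' @param synonym_scopes Named character vector mapping OBO synonym scopes to
#'   term statuses.
#' @param keep_obsolete Keep obsolete stanzas as `former_name` terms?
#' @return A validated term tibble.
#' @export
load_obo <- function(path, namespace = NULL, source = NULL,
                     synonym_scopes = c(EXACT = "synonym"),
                     keep_obsolete = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) return(term_table0())
  bounds <- c(starts, length(lines) + 1L)
  stanza_of <- function(i) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block[nzchar(block) & !startsWith(block, "[")]
  }
  rows <- list()
  for (i in seq_along(starts)) {
    block <- stanza_of(i)
    get <- function(key) {
      hit <- block[startsWith(block, paste0(key, ":"))]
      stringr::str_trim(stringr::str_sub(hit, nchar(key) + 2L))
    }
    id <- get("id")
    if (length(id) != 1L || !nzchar(id)) {
      stop("unparseable OBO stanza (missing id) starting at line ",
           starts[i], call. = FALSE)
    }
    name <- get("name")
    if (length(name) == 0L || !nzchar(name[1])) {
      warning("OBO stanza ", id, " has no name; skipped", call. = FALSE)
      next
    }
    obsolete <- any(grepl("^true", get("is_obsolete")))
    if (obsolete && !keep_obsolete) next
    idp <- strsplit(id, ":", fixed = TRUE)[[1]]
    ns <- namespace %||% idp[1]
    ident <- if (is.null(namespace) && length(idp) > 1L) {
      paste(idp[-1], collapse = ":")
    } else id
    src <- source %||% stringr::str_to_lower(ns)
    texts <- name[1]
    statuses <- if (obsolete) "former_name" else "standard_name"
    for (syn in get("synonym")) {
      m <- stringr::str_match(syn, '^"((?:[^"\\\\]|\\\\.)*)"\\s+([A-Z_]+)')
      if (is.na(m[1, 1])) {
        stop("unparseable synonym line in OBO stanza ", id, call. = FALSE)
      }
      scope <- m[1, 3]
      st <- synonym_scopes[scope]
      if (is.na(st)) next
      texts <- c(texts, gsub('\\\\(.)', "\\1", m[1, 2]))
      statuses <- c(statuses, if (obsolete) "former_name" else unname(st))
    }
    rows[[length(rows) + 1L]] <- term_table(
      namespace = ns, identifier = ident, text = texts, status = statuses,
      standard_name = name[1], source = src)
  }
  if (length(rows) == 0) return(term_table0())
  dplyr::bind_rows(rows)
}

#' Merge gene and protein synonym sets
#'
#' In the default configuration genes are not distinguished from their
#' protein products: protein-namespace terms whose identifier maps to a gene
#' are re-emitted under the gene namespace, with `source_namespace` /
#' `source_identifier` recording where they came from.  Unmapped terms pass
#' through unchanged, and with `enabled = FALSE` the input is returned as is.
#'
#' @param terms A term tibble.
#' @param mapping A data frame with columns `protein_namespace`,
#'   `protein_identifier`, `gene_namespace`, `gene_identifier`.
#' @param enabled Merge switch (default on).
#' @return A term tibble of the same length.
#' @export
merge_gene_protein <- function(terms, mapping, enabled = TRUE) {
  terms <- validate_terms(terms)
  if (!enabled || nrow(terms) == 0 || is.null(mapping) || nrow(mapping) == 0) {
    return(terms)
  }
  mapping <- tibble::as_tibble(mapping)
  need <- c("protein_namespace", "protein_identifier", "gene_namespace",
            "gene_identifier")
  if (!all(need %in% names(mapping))) {
    stop("mapping must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(mapping$protein_namespace, mapping$protein_identifier, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    conflicts <- unique(paste0(mapping$protein_namespace[dup], ":",
                               mapping$protein_identifier[dup]))
    stop("protein(s) mapped to multiple genes: ",
         paste(conflicts, collapse = ", "), call. = FALSE)
  }
  idx <- match(paste(terms$namespace, terms$identifier, sep = "\r"), key)
  hit <- !is.na(idx)
  terms$source_namespace[hit] <- terms$namespace[hit]
  terms$source_identifier[hit] <- terms$identifier[hit]
  terms$namespace[hit] <- mapping$gene_namespace[idx[hit]]
  terms$identifier[hit] <- mapping$gene_identifier[idx[hit]]
  terms
}
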