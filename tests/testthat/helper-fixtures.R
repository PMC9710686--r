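# Shared test fixtures and the brute-force lookup oracle.

# Two entities sharing the synonym "DAP4" (a gene synonym held by two
# distinct genes), with sense labels matching generate_ambiguous_corpus().
dap4_fixture <- function() {
  dplyr::bind_rows(
    term_table("SYNT", "S1", "DLGAP4", "standard_name", "DLGAP4", "synth",
               organism = "9606"),
    term_table("SYNT", "S1", "DAP4", "synonym", "DLGAP4", "synth",
               organism = "9606"),
    term_table("SYNT", "S2", "THAP12", "standard_name", "THAP12", "synth",
               organism = "9606"),
    term_table("SYNT", "S2", "DAP4", "synonym", "THAP12", "synth",
               organism = "9606")
  )
}

# Independent oracle: candidate set by scanning EVERY term for a
# variant-canonical collision, no index involved.
brute_force_candidates <- function(terms, query) {
  variants <- generate_variants(query)
  out <- list()
  for (v in variants) {
    hit <- terms[terms$canonical == v, ]
    if (nrow(hit) > 0) {
      hit$variant_used <- v
      out[[length(out) + 1L]] <- hit
    }
  }
  if (length(out) == 0) return(character(0))
  all <- dplyr::bind_rows(out)
  sort(paste(all$namespace, all$identifier, all$text, all$variant_used,
             sep = "\r"))
}

candidate_keys <- function(cand) {
  sort(paste(cand$namespace, cand$identifier, cand$text, cand$variant_used,
             sep = "\r"))
}

# Random query generator: mixes lexicon texts, case/separator mutations of
# them, and unrelated strings.
random_queries <- function(terms, n) {
  texts <- terms$text
  vapply(seq_len(n), function(i) {
    mode <- sample(4L, 1L)
    if (mode == 1L) {
      sample(texts, 1L)
    } else if (mode == 2L) {
      toupper(sample(texts, 1L))
    } else if (mode == 3L) {
      gsub("-", "", sample(texts, 1L), fixed = TRUE)
    } else {
      paste0(paste(sample(letters, 6L, replace = TRUE), collapse = ""),
             sample(0:9, 1L))
    }
  }, character(1))
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

# Run the packaged CLI in a subprocess that sees the same library paths.
run_cli <- function(args) {
  cli <- system.file("exec", "grounder", package = "grounder")
  out <- withr::with_envvar(
    c(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep)),
    system2(rscript_bin(), c(shQuote(cli), shQuote(args)), stdout = TRUE,
            stderr = FALSE)
  )
  paste(out, collapse = "\n")
}
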