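test_that("term tables round-trip through the TSV dialect", {
  terms <- dplyr::bind_rows(
    pkc_fixture(),
    term_table("GO", "0006915", "apoptotic process", "standard_name",
               "apoptotic process", "go"),
    term_table("HGNC", "9399", "PRKCD", "standard_name", "PRKCD", "hgnc",
               source_namespace = "UP", source_identifier = "Q05655",
               organism = "9606")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_terms(terms, path)
  expect_equal(read_terms(path), terms)
  # gzip-transparent
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_terms(terms, gz)
  expect_equal(read_terms(gz), terms)
})

test_that("the worked-example synonym row loads with its status and organism", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("HGNC\t9399\tPKCD\tsynonym\tpkcd\tPRKCD\thgnc\t\t9606", path)
  t <- read_terms(path)
  expect_equal(t$namespace, "HGNC")
  expect_equal(t$identifier, "9399")
  expect_equal(t$status, "synonym")
  expect_equal(t$organism, "9606")
  # canonical recomputed when the column is empty
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("HGNC\t9399\tPKC-delta\tsynonym\t\tPRKCD\thgnc\t\t9606", path2)
  expect_equal(read_terms(path2)$canonical, "pkc delta")
})

test_that("term loading errors are precise", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("HGNC\t1\tA\tsynonym\ta\tA\thgnc\t\t",
               "too\tfew\tfields"), path)
  expect_error(read_terms(path), "line 2")
  writeLines("HGNC\t1\tA\tbogus_status\ta\tA\thgnc\t\t", path)
  expect_error(read_terms(path), "bogus_status")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_equal(nrow(read_terms(empty)), 0L)
  expect_error(read_terms("/nonexistent/terms.tsv"), "no such file")
})

test_that("duplicated rows are preserved at load and removed at index build", {
  path <- withr::local_tempfile(fileext = ".tsv")
  row <- "HGNC\t1\tABC\tsynonym\tabc\tABC1\thgnc\t\t"
  writeLines(c(row, row), path)
  terms <- read_terms(path)
  expect_equal(nrow(terms), 2L)
  idx <- build_index(terms)
  expect_equal(nrow(tidy(idx)), 1L)
  expect_equal(index_report(idx)$n_duplicates_dropped, 1L)
})

test_that("validation enforces the term invariants", {
  t <- pkc_fixture()
  t$canonical[1] <- "wrong"
  expect_error(validate_terms(t), "canonicalize")
  t <- pkc_fixture()
  t$source_namespace[1] <- "UP"  # identifier left NA
  expect_error(validate_terms(t), "together")
  t <- pkc_fixture()
  t$standard_name[2] <- ""
  expect_error(validate_terms(t), "standard_name")
})

obo_fixture <- function(extra = character(0)) {
  c("format-version: 1.4",
    "",
    "[Term]",
    "id: GO:0006915",
    "name: apoptotic process",
    'synonym: "apoptosis" EXACT []',
    'synonym: "programmed cell death" EXACT []',
    'synonym: "cell death-ish" RELATED []',
    "",
    extra)
}

test_that("OBO loading maps names and synonym scopes to statuses", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo_fixture(), path)
  terms <- load_obo(path)
  expect_equal(nrow(terms), 3L)  # name + 2 EXACT synonyms; RELATED skipped
  expect_setequal(terms$status, c("standard_name", "synonym"))
  expect_true(all(terms$namespace == "GO"))
  expect_true(all(terms$identifier == "0006915"))
  expect_true(all(terms$standard_name == "apoptotic process"))
  # scope mapping is configurable
  terms2 <- load_obo(path, synonym_scopes = c(EXACT = "synonym",
                                              RELATED = "curated"))
  expect_equal(sum(terms2$status == "curated"), 1L)
})

test_that("OBO obsolete stanzas follow keep_obsolete", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo_fixture(c("[Term]",
                           "id: GO:0000001",
                           "name: old process",
                           "is_obsolete: true")), path)
  expect_equal(nrow(load_obo(path)), 3L)
  kept <- load_obo(path, keep_obsolete = TRUE)
  expect_equal(nrow(kept), 4L)
  expect_equal(kept$status[kept$identifier == "0000001"], "former_name")
})

test_that("OBO edge cases: empty document, nameless stanza", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.4", "ontology: test"), path)
  expect_equal(nrow(load_obo(path)), 0L)
  writeLines(c("[Term]", "id: GO:0000002"), path)
  expect_warning(terms <- load_obo(path), "no name")
  expect_equal(nrow(terms), 0L)
})

test_that("gene/protein synonym merging follows the mapping", {
  terms <- dplyr::bind_rows(
    term_table("UP", "P05771", "PKC-B", "synonym", "KPCB", "uniprot",
               organism = "9606"),
    term_table("HGNC", "9395", "PRKCB", "standard_name", "PRKCB", "hgnc",
               organism = "9606")
  )
  mapping <- tibble::tibble(protein_namespace = "UP",
                            protein_identifier = "P05771",
                            gene_namespace = "HGNC", gene_identifier = "9395")
  merged <- merge_gene_protein(terms, mapping)
  moved <- merged[merged$text == "PKC-B", ]
  expect_equal(moved$namespace, "HGNC")
  expect_equal(moved$identifier, "9395")
  expect_equal(moved$source_namespace, "UP")
  expect_equal(moved$source_identifier, "P05771")
  # empty mapping and disabled merging are identity
  expect_equal(merge_gene_protein(terms, mapping[0, ]), terms)
  expect_equal(merge_gene_protein(terms, mapping, enabled = FALSE), terms)
})

test_that("a protein mapped to two genes is a configuration error", {
  mapping <- tibble::tibble(
    protein_namespace = c("UP", "UP"), protein_identifier = c("P1", "P1"),
    gene_namespace = "HGNC", gene_identifier = c("1", "2"))
  expect_error(merge_gene_protein(pkc_fixture(), mapping), "UP:P1")
})
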