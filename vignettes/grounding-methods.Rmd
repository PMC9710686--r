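---
title: "How grounder normalizes entity strings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How grounder normalizes entity strings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grounder)
```

## The problem

Named-entity normalization maps a mention in text — `PKC-Delta`, `IFN-γ`,
`kinases` — to an identifier in a curated resource. Exact thesaurus search
fails for two independent reasons: orthographic variability (spacing,
dashes, capitalization, Greek letters, plurals) and genuine ambiguity (one
string naming several entities). `grounder` treats these with two separate
mechanisms — deterministic scored string matching, and per-string machine
learned sense classification — plus an organism tie-break for cross-species
gene/protein ambiguity.

## The term model and the index

A *term* is one lexicalization of one entity: namespace, identifier, text,
status (`standard_name`, `curated`, `synonym`, `former_name`), the
canonicalized text, the entity's standard name, a source code, optional
mapped-from namespace/identifier, and an optional organism (taxonomy id).
Loaders (`read_terms()` for the 9-column TSV dialect, `load_obo()` for OBO
1.4 flat files) keep source files verbatim, duplicates included; duplicate
collapse happens once, at `build_index()`, so the index is the single place
where the retrieval invariants hold. The index is a hash map from canonical
text to term rows, making candidate lookup average O(1) in lexicon size.
In the default configuration a gene and its protein product are not
distinguished: `merge_gene_protein()` re-namespaces protein terms onto
their mapped gene, recording the original in the mapped-from fields, and
can be disabled when a use case needs them separate.

## Canonicalization and variants

`canonicalize()` is the single normal form used for index keys and lookups:
Unicode NFC, micro sign folded to Greek mu, every dash treated as a space,
whitespace collapsed and trimmed, lowercased locale-independently. It is
idempotent, and validation rejects strings that are empty once separators
are removed.

`generate_variants()` expands an input into the finite set of spellings
that are each looked up exactly — there is no edit-distance search. For
`PKC-Delta` it produces exactly `pkc delta`, `pkcdelta`, `pkcd`, `pkcδ`.
The rules: the canonical (spaced) form; the separator-removed form; for a
token that is a Greek name, the letter-substituted and Latin-initial
contracted joins; for a token that is a Greek letter, the spelled-out forms
(spaced and joined) and the initial contraction; a trailing Greek element
inside an unseparated token is split out the same way; and a
plural-stripped form of each variant (trailing `s` with stem length at
least 3, `-ies` to `y`). Greek substitution touches one token per variant,
keeping the expansion linear; the 24-letter table, both cases plus Latin
initials, ships as a package data file.

## Scoring

Candidates are compared on the *original* strings, not the canonical forms:
the query is tokenized on separators and aligned character-by-character
against the term text, permitting the same Greek equivalences used in
variant generation and query-side plural stripping. The alignment yields
the feature set: `exact`, the count of separator mismatches, a per-token
capitalization comparison (`same`, query-upper/ref-lower, the reverse, or
`mixed`), and whether a plural was dropped. An exact match has, by
construction, a clean profile.

`score_match()` multiplies a string-similarity component by a status
component, both in (0, 1]. Similarity is 1 for exact matches, otherwise a
product of per-feature penalties; the constants live in
`inst/extdata/scoring_constants.json`:

| constant | value | applies per |
|---|---|---|
| separator mismatch | 0.999 | occurrence |
| capitalization flip | 0.998 | token |
| mixed capitalization | 0.995 | token |
| plural dropped | 0.98 | match |
| unalignable collision | 0.9 | match |
| status: standard name / curated / synonym / former name | 1 / 0.9966 / 0.99 / 0.85 | match |

The set was chosen once to satisfy the ordering constraints the method
requires — exact standard name scores exactly 1; similarity strictly
decreases with each mismatch feature; status dominates among near-equal
similarities (the status gap, ≥ 0.0034 between adjacent ranks, exceeds the
largest single-feature similarity gap, ≤ 0.005 per feature at one or two
features) — and calibrated so the `PKC-Delta` example surfaces its curated
term at 0.999 × 0.998 × 0.9966 ≈ 0.9936, which makes the worked example an
executable regression test. For `PKC-Delta`, `PKCD` aligns with a clean
capitalization profile (suffix `D` matches the capitalized `Delta`) and one
separator mismatch, so its *string* similarity (0.999) beats `PKCdelta`'s
(0.999 × 0.998, a capitalization flip on `delta`); but its `synonym` status
(0.99) loses to `curated` (0.9966): 0.98901 < 0.99361. `PKCδ` ties
`PKCdelta` exactly, and the deterministic tie-break (status rank, fewer
mismatch features, source, then namespace/identifier/text in C-locale
order) surfaces `PKCdelta`.

`ground()` deduplicates candidates per (namespace, identifier), keeping the
max-scoring one, so one entity appears once however many of its
lexicalizations were hit.

## Context disambiguation

Textually identical terms with identical status tie exactly; only context
can separate them. Following one-sense-per-discourse, each training
document carries a single sense label for its ambiguous string, and one
classifier is trained per string: tf-idf weighted unigrams + bigrams
(lowercase, split on non-alphanumerics, tokens of length ≥ 2; `idf =
ln((1+N)/(1+df)) + 1`, rows L2-normalized — a hand-checkable convention
the tests verify against a worked 3-document oracle) feeding a multinomial
logistic regression with an L2 (ridge) penalty, fixed regularization
λ = 10⁻³, fit by glmnet. The fit is deterministic; the only randomness is
the seeded, sense-stratified assignment of documents to the 5
cross-validation folds, whose mean macro-averaged F1 estimates
generalization. Models below the deployment cutoff of 0.7 macro-F1 are
excluded by `select_models()`. Stratification and the regularization /
tokenizer defaults are this package's documented choices; class weighting
is uniform.

At grounding time a context's predicted sense probability rescales the
string score as `score · (ε + (1−ε)·p)` with ε = 0.05 — monotone in both
inputs, bound-preserving, and never able to introduce or remove a match.
Without context, or without a model for the canonicalized input string, no
adjustment happens (no corpus-frequency prior is applied); a missing model
with context supplied is a logged no-op. Model bundles serialize to plain
text (metadata JSON, vocabulary + idf TSV, coefficient TSV at 17
significant digits) and round-trip bit-identically.

## Species priority

`rerank_by_species()` applies an ordered organism list as a pure
tie-break: only matches whose scores are equal within 10⁻⁹ are reordered,
by priority rank, stably; scores never change and strictly different
scores are never overridden (an explicit design choice — the alternative,
a score modifier, would let a weak cross-species match beat a strong one).
`priority_from_mesh()` derives the list from a publication's MeSH
descriptors via a small packaged mapping for common model organisms.

## Synthetic data: what it emulates and what it does not

The generators define the test conditions. `generate_lexicon()` emulates
the *structure* of a synonym lexicon — entities with a standard name and
1–3 synonyms, a configurable fraction of synonym strings shared between two
entities (ambiguity), a configurable fraction carrying Greek elements —
deterministically from a seed. `generate_ambiguous_corpus()` emulates
labeled documents as bags of words over per-sense vocabularies with a
controllable shared fraction, sampled from a Zipf-weighted multinomial
(100 documents per sense and ~50-word vocabularies in the standard
configuration; documents of 30 words). Disjoint vocabularies make senses
separable by construction, so recovering them (CV macro-F1 ≥ 0.95) checks
the pipeline, not real-world performance; fully shared vocabularies make
labels uninformative and CV macro-F1 must sit at chance. Real abstracts
have correlated topics, overlapping vocabularies, negation and section
structure that these bags of words do not model, so passing tests
demonstrate correctness of the machinery, not benchmark-level accuracy on
literature corpora. Corpus harvesting from gene/document annotation
databases is deliberately out of scope; the JSONL loader
(`read_labeled_corpus()`) is the interface through which real labeled
corpora would enter.

## Evaluation harness

`evaluate_grounding()` scores labeled records under two conditions in one
pass: *top* (first-ranked match must be the expected grounding or one of
its declared cross-namespace equivalents) and *any* (any returned match
counts). Precision divides hits by records that returned at least one
match; recall divides by all records — so an ungrounded record hurts recall
only. This denominator convention is a documented package choice, applied
consistently. Matches in namespaces absent from a record's equivalence set
count as misses.

## Numerical and degenerate-input choices

* Ranking and dedup tie-breaks are fully deterministic (C-locale string
  order, never the session locale).
* A canonical-key collision the character aligner cannot explain (possible
  for exotic inputs) is not dropped: it is scored with a conservative
  `unaligned` penalty and a `mixed` capitalization profile.
* Empty or whitespace-only inputs are validation errors everywhere;
  grounding a string with no key hit returns an empty, typed tibble.
* Probabilities from the classifier sum to 1 within 10⁻⁹; an
  out-of-vocabulary context yields the intercept-only distribution.
* glmnet requires two predictor columns, so degenerate one-feature corpora
  are padded with an explicit zero column whose coefficient is discarded.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which each property is meaningful: lexicons of up to 200
terms (100 random lexicons × 50 queries for the lookup-oracle check),
10⁴ fuzzed queries for the score-bounds property, 100 documents per sense
for classifier recovery and 200 fresh contexts per sense for the
context-flip check. Production-scale ingestion (millions of strings, a
thousand-model registry) is out of scope here, though nothing in the
design is quadratic in lexicon size.

## Known limitations

* No fuzzy (edit-distance) matching: a misspelling that no variant rule
  reaches will not ground. This is the method: exact lookup over generated
  variants.
* Greek substitution applies to one token per variant, so strings with two
  Greek elements only vary one at a time.
* Acronym-definition models (spelled-out-definition mining) are not
  implemented; the model registry keys on canonical entity text, so such
  model packs could be slotted in.
* The REST service is a single-threaded, one-request-per-connection loop
  intended for local use and testing, not a production server.
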