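# Species-priority reranking of gene/protein matches.
#
# An organism priority list expresses prior knowledge (e.g. "prefer human,
# then mouse").  It acts purely as a tie-break: only matches whose scores
# are equal within a small tolerance are reordered, scores never change.

#' Rerank equal-score matches by organism priority
#'
#' Within each run of matches whose scores are equal (tolerance `tol`),
#' matches carrying an organism annotation are ordered by their rank in
#' `priority`; matches without an annotation, or with an organism not in the
#' list, keep their relative order after the prioritized ones.  Matches with
#' strictly different scores are never reordered and no score changes.  The
#' operation is idempotent.
#'
#' @param matches A `grounding_matches` tibble sorted by decreasing score.
#' @param priority Character vector of taxonomy identifiers, highest
#'   priority first, without duplicates; empty means no preference.
#' @param tol Score-equality tolerance.
#' @return The reranked matches (a permutation; scores untouched).
#' @export
rerank_by_species <- function(matches, priority, tol = 1e-9) {
  priority <- as.character(priority)
  if (anyDuplicated(priority)) {
    stop("`priority` must not contain duplicates", call. = FALSE)
  }
  if (nrow(matches) == 0 || length(priority) == 0) return(matches)
  s <- matches$score
  if (is.unsorted(-s)) {
    stop("`matches` must be sorted by decreasing score", call. = FALSE)
  }
  group <- cumsum(c(TRUE, (s[-length(s)] - s[-1]) > tol))
  rank <- match(matches$organism, priority)
  rank[is.na(rank)] <- length(priority) + 1L
  ord <- order(group, rank)  # stable within groups
  matches[ord, ]
}

#' Derive a species priority from MeSH annotations
#'
#' Maps the MeSH descriptor annotations of a publication to taxonomy
#' identifiers using a two-column mapping (MeSH id, taxonomy id) and returns
#' them in first-occurrence order; unmapped descriptors are skipped.  A
#' table covering common model organisms is packaged
#' (`extdata/mesh_taxonomy.tsv`) and used by default.
#'
#' @param mesh_terms Character vector of MeSH descriptor ids (e.g.
#'   `"D006801"` for Humans).
#' @param mapping Optional data frame with columns `mesh`, `taxonomy`, or a
#'   path to a two-column TSV.
#' @return Character vector of taxonomy identifiers, highest priority first.
#' @export
priority_from_mesh <- function(mesh_terms, mapping = NULL) {
  if (is.null(mapping)) {
    mapping <- the$mesh_taxonomy
  } else if (is.character(mapping)) {
    mapping <- utils::read.delim(mapping, header = FALSE,
                                 col.names = c("mesh", "taxonomy"),
                                 colClasses = "character", quote = "")
  }
  taxa <- mapping$taxonomy[match(as.character(mesh_terms), mapping$mesh)]
  unique(taxa[!is.na(taxa)])
}
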