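# Top/any precision-recall evaluation harness.
#
# Each record carries an entity text, an expected grounding and optionally
# equivalent identifiers in other namespaces (cross-ontology equivalence
# mapping).  Two conditions are scored in one pass: "top" (the first-ranked
# match must be acceptable) and "any" (any returned match may be).

#' Read evaluation records
#'
#' TSV dialect, no header, columns: entity_text, expected (`NS:ID`),
#' equivalents (`NS:ID|NS:ID|...` or empty), context (or empty), category
#' (or empty).
#'
#' @param path File path.
#' @return A tibble of evaluation records with an `equivalents` list-column.
#' @export
read_eval_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  mat <- t(vapply(fields, function(f) c(f, rep("", 5L - length(f)))[1:5],
                  character(5)))
  tibble::tibble(
    entity_text = mat[, 1],
    expected = mat[, 2],
    equivalents = lapply(strsplit(mat[, 3], "|", fixed = TRUE),
                         function(e) e[nzchar(e)]),
    context = ifelse(mat[, 4] == "", NA_character_, mat[, 4]),
    category = ifelse(mat[, 5] == "", "uncategorized", mat[, 5])
  )
}

#' Evaluate grounding on labeled records
#'
#' Grounds every record and scores it under two conditions: *top* -- the
#' first-ranked match is the expected grounding or one of its equivalents --
#' and *any* -- any returned match is acceptable.  Precision counts hits
#' over records that returned at least one match; recall counts hits over
#' all records (so an ungrounded record hurts recall only).  F1 is the
#' harmonic mean.  Results are reported per category and overall.
#'
#' @param index A `grounding_index`.
#' @param records A tibble with columns `entity_text`, `expected`
#'   (`"NS:ID"`), and optionally `equivalents` (list of `"NS:ID"`),
#'   `context`, `category`, `organisms` (list-column).
#' @param models Optional disambiguator registry used when records carry
#'   context.
#' @return A `grounding_eval` tibble: one row per (category, condition) plus
#'   the overall rows, columns `precision`, `recall`, `f1`, `n_records`,
#'   `n_grounded`, `n_hits`; the number of context-disambiguated records is
#'   in `attr(, "n_disambiguated")`.
#' @export
evaluate_grounding <- function(index, records, models = NULL) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) stop("no evaluation records", call. = FALSE)
  stopifnot(all(c("entity_text", "expected") %in% names(records)))
  if (any(!nzchar(records$expected))) {
    stop("every record needs a non-empty expected grounding", call. = FALSE)
  }
  if (!"equivalents" %in% names(records)) {
    records$equivalents <- list(character(0))
  }
  if (!"context" %in% names(records)) records$context <- NA_character_
  if (!"category" %in% names(records)) records$category <- "uncategorized"

  n <- nrow(records)
  grounded <- logical(n); top_hit <- logical(n); any_hit <- logical(n)
  disamb <- logical(n)
  for (i in seq_len(n)) {
    ctx <- records$context[i]
    has_ctx <- !is.na(ctx) && nzchar(ctx)
    if (has_ctx && !is.null(registry_get(models, canonicalize(records$entity_text[i])))) {
      disamb[i] <- TRUE
    }
    m <- suppressMessages(ground(index, records$entity_text[i],
                                 context = if (has_ctx) ctx,
                                 models = models))
    acceptable <- c(records$expected[i], records$equivalents[[i]])
    if (nrow(m) > 0) {
      grounded[i] <- TRUE
      keys <- paste0(m$namespace, ":", m$identifier)
      top_hit[i] <- keys[1] %in% acceptable
      any_hit[i] <- any(keys %in% acceptable)
    }
  }

  summarize_cat <- function(idx, category) {
    purrr::map_dfr(c(top = "top", any = "any"), function(cond) {
      hits <- sum(if (cond == "top") top_hit[idx] else any_hit[idx])
      n_g <- sum(grounded[idx])
      prec <- if (n_g > 0) hits / n_g else NA_real_
      rec <- hits / length(idx)
      f1 <- if (!is.na(prec) && prec + rec > 0) {
        2 * prec * rec / (prec + rec)
      } else 0
      tibble::tibble(category = category, condition = cond,
                     precision = prec, recall = rec, f1 = f1,
                     n_records = length(idx), n_grounded = n_g,
                     n_hits = hits)
    })
  }
  cats <- unique(records$category)
  out <- dplyr::bind_rows(
    purrr::map_dfr(cats, function(cat) {
      summarize_cat(which(records$category == cat), cat)
    }),
    summarize_cat(seq_len(n), "overall")
  )
  attr(out, "n_disambiguated") <- sum(disamb)
  class(out) <- c("grounding_eval", class(out))
  out
}

#' Plot an evaluation result
#'
#' Precision / recall / F1 bars per category, faceted by the top/any
#' condition.
#'
#' @param object A `grounding_eval` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grounding_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
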