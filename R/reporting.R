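#' Per-topic keyword table
#'
#' One row per topic with its top terms, an optional translation column and
#' an expert label column (empty when labels are pending), the layout used
#' to hand topics to a medical expert.
#'
#' @param model An `lda_model`.
#' @param n Words per topic (default 10; all terms if `V < n`).
#' @param labels Optional character vector of expert labels, length K.
#' @param translations Optional named character vector term -> translation.
#' @return Tibble with `topic`, `top_words`, optionally `translation`, and
#'   `label`.
#' @export
topic_table <- function(model, n = 10, labels = NULL, translations = NULL) {
  K <- nrow(model$phi)
  n <- min(n, ncol(model$phi))
  words <- vapply(seq_len(K), function(t) {
    paste(top_words(model, t, n = n)$term, collapse = ", ")
  }, character(1))
  out <- tibble::tibble(topic = seq_len(K), top_words = words)
  if (!is.null(translations)) {
    out$translation <- vapply(seq_len(K), function(t) {
      terms <- top_words(model, t, n = n)$term
      tr <- translations[terms]
      tr[is.na(tr)] <- terms[is.na(tr)]
      paste(tr, collapse = ", ")
    }, character(1))
  }
  out$label <- if (is.null(labels)) rep("", K) else labels
  out
}

#' Format "n (percent)" distribution cells
#'
#' @param count Integer vector of per-topic document counts.
#' @param total Corpus size.
#' @return Character vector like `"523 (3.10)"` (percent to 2 decimals).
#' @export
format_count_percent <- function(count, total) {
  sprintf("%d (%.2f)", as.integer(count), 100 * count / total)
}

#' Document-distribution table
#'
#' Renders per-topic document counts as `"n (percent)"` rows with a column
#' total, the conventional per-topic distribution layout.
#'
#' @param counts Tibble from [dominant_topic_counts()] (columns `topic`,
#'   `count`) or a named vector of counts.
#' @return Tibble with `topic` and `documents`; the last row is the total.
#' @export
distribution_table <- function(counts) {
  if (!is.data.frame(counts)) {
    counts <- tibble::tibble(topic = seq_along(counts), count = as.integer(counts))
  }
  total <- sum(counts$count)
  tibble::tibble(
    topic = c(as.character(counts$topic), "total"),
    documents = c(format_count_percent(counts$count, total),
                  sprintf("%d (100.00)", total))
  )
}

#' Grouped item-topic alignment report
#'
#' Groups validated alignments by questionnaire scale and appends the
#' trailing section of topics without any validated relationship (the
#' emerging-topic candidates).
#'
#' @param alignment An `alignment_result`.
#' @param annotations Annotation tibble.
#' @param q The `questionnaire`.
#' @param model The fitted `lda_model`.
#' @return Tibble with `section` (`"scale"` rows then
#'   `"topics without a relationship"`), `scale`, `items`, `topics`.
#' @export
alignment_map_table <- function(alignment, annotations, q, model) {
  key_ann <- paste(annotations$item_number, annotations$topic_id)
  key_al <- paste(alignment$item_number, alignment$best_topic)
  ok <- annotations$validated[match(key_al, key_ann)]
  ok[is.na(ok)] <- FALSE

  scales <- unique(q$items$scale)
  rows <- lapply(scales, function(sc) {
    idx <- alignment$scale == sc & ok
    items <- alignment$item_number[alignment$scale == sc]
    topics <- sort(unique(alignment$best_topic[idx]))
    tibble::tibble(section = "scale", scale = sc,
                   items = paste(sort(items), collapse = ", "),
                   topics = if (length(topics)) paste(topics, collapse = ", ") else "")
  })
  validated_topics <- unique(alignment$best_topic[ok])
  orphan <- setdiff(seq_len(nrow(model$phi)), validated_topics)
  tail_row <- tibble::tibble(section = "topics without a relationship",
                             scale = "", items = "",
                             topics = if (length(orphan)) paste(orphan, collapse = ", ") else "")
  do.call(rbind, c(rows, list(tail_row)))
}

#' Cross-corpus topic comparison table
#'
#' Combines a topic pairing between two corpora with per-topic document
#' distributions. Every topic of each model appears exactly once, either in
#' the `"both"` section (paired) or in the `"only one"` section; unmatched
#' cells render `"N/A"`.
#'
#' @param pairing Tibble from [match_topics_across_corpora()].
#' @param counts_a,counts_b Tibbles from [dominant_topic_counts()].
#' @param matched_a,matched_b Optional logical vectors: is the topic matched
#'   to a questionnaire item (rendered as Yes/No).
#' @return Tibble with `section`, `topic_a`, `docs_a`, `topic_b`, `docs_b`,
#'   `questionnaire_match`.
#' @export
cross_corpus_table <- function(pairing, counts_a, counts_b,
                               matched_a = NULL, matched_b = NULL) {
  total_a <- sum(counts_a$count)
  total_b <- sum(counts_b$count)
  cell_a <- format_count_percent(counts_a$count, total_a)
  cell_b <- format_count_percent(counts_b$count, total_b)
  flag <- function(m, t) {
    if (is.null(m)) "" else if (m[t]) "Yes" else "No"
  }

  both <- lapply(seq_len(nrow(pairing)), function(i) {
    ta <- pairing$topic_a[i]; tb <- pairing$topic_b[i]
    tibble::tibble(section = "both", topic_a = as.character(ta),
                   docs_a = cell_a[ta], topic_b = as.character(tb),
                   docs_b = cell_b[tb],
                   questionnaire_match = flag(matched_a, ta))
  })
  only_a <- setdiff(counts_a$topic, pairing$topic_a)
  only_b <- setdiff(counts_b$topic, pairing$topic_b)
  one <- c(
    lapply(only_a, function(t) {
      tibble::tibble(section = "only one", topic_a = as.character(t),
                     docs_a = cell_a[t], topic_b = "N/A", docs_b = "N/A",
                     questionnaire_match = flag(matched_a, t))
    }),
    lapply(only_b, function(t) {
      tibble::tibble(section = "only one", topic_a = "N/A", docs_a = "N/A",
                     topic_b = as.character(t), docs_b = cell_b[t],
                     questionnaire_match = flag(matched_b, t))
    })
  )
  do.call(rbind, c(both, one))
}

#' Questionnaire-dimension coverage of corpus topics
#'
#' Given the per-dimension mapping between questionnaire scales and corpus
#' topic labels, counts how many of the instrument dimensions found at least
#' one corpus topic, as an integer percentage (truncated, the convention of
#' the published coverage figures).
#'
#' @param matched Logical vector: did the dimension match a corpus topic.
#' @return List with `n_matched`, `n_total`, `percent`
#'   (`floor(100 * n_matched / n_total)`).
#' @export
dimension_coverage <- function(matched) {
  n <- sum(matched)
  total <- length(matched)
  list(n_matched = n, n_total = total, percent = floor(100 * n / total))
}

#' Render a table as TSV text
#'
#' Pure function of its input: identical tables render to identical bytes.
#'
#' @param tbl A data frame.
#' @return A single string (header line + one line per row, tab-separated).
#' @export
render_tsv <- function(tbl) {
  header <- paste(names(tbl), collapse = "\t")
  body <- apply(tbl, 1, function(r) paste(as.character(r), collapse = "\t"))
  paste(c(header, body), collapse = "\n")
}

#' Render a table as GitHub-flavored Markdown
#'
#' @param tbl A data frame.
#' @return A single string.
#' @export
render_markdown <- function(tbl) {
  header <- paste0("| ", paste(names(tbl), collapse = " | "), " |")
  rule <- paste0("|", paste(rep(" --- ", ncol(tbl)), collapse = "|"), "|")
  body <- apply(tbl, 1, function(r) paste0("| ", paste(as.character(r), collapse = " | "), " |"))
  paste(c(header, rule, body), collapse = "\n")
}
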