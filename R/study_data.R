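#' Bundled reference tables from a breast-cancer social-media topic study
#'
#' Summary tables from a published topic analysis of two French
#' breast-cancer communities (the cancerdusein.org forum, 16,868 messages,
#' and public Facebook groups, 70,092 messages; K = 20 topics per corpus,
#' labeled and validated by a medical expert against the EORTC QLQ-C30 and
#' QLQ-BR23 instruments). The raw message corpora are not redistributable;
#' these aggregate tables are the published inputs from which the headline
#' evaluation figures (precision, dimension coverage, emerging-topic shares)
#' can be recomputed.
#'
#' @return A list of tibbles:
#' \describe{
#'   \item{topic_counts}{per-topic document counts in each corpus
#'     (`topic`, `forum_n`, `facebook_n`).}
#'   \item{topic_catalog}{expert topic labels with their topic number in
#'     each corpus (`NA` when the topic appears in only one) and whether the
#'     topic matched a questionnaire item.}
#'   \item{dimension_map}{the 23 questionnaire dimensions (scales) with
#'     their item numbers and whether each matched at least one corpus
#'     topic.}
#'   \item{validation_counts}{expert validation tallies of the 53 proposed
#'     item-topic relationships per corpus.}
#' }
#' @export
qlq_study_tables <- function() {
  dir <- system.file("extdata", "qlq_study", package = "qoltopics")
  if (!nzchar(dir)) stop("bundled study tables not found", call. = FALSE)
  tsv <- function(name) {
    tibble::as_tibble(utils::read.delim(file.path(dir, name), sep = "\t",
                                        stringsAsFactors = FALSE))
  }
  list(
    topic_counts = tsv("topic_counts.tsv"),
    topic_catalog = tsv("topic_catalog.tsv"),
    dimension_map = tsv("dimension_map.tsv"),
    validation_counts = tibble::as_tibble(
      utils::read.csv(file.path(dir, "validation_counts.csv")))
  )
}
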