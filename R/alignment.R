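#' Probability-weighted Jaccard similarity
#'
#' Generalizes the Jaccard coefficient to nonnegative weight vectors, so
#' topic-term probabilities enter the comparison rather than bare term sets:
#' \deqn{s(x, y) = \frac{\sum_w \min(x_w, y_w)}{\sum_w \max(x_w, y_w)}.}
#' Symmetric, bounded in \[0, 1\], equal to 1 iff `x == y` and 0 iff the
#' supports are disjoint; when both vectors are uniform over their supports
#' it reduces to the plain Jaccard index of the supports.
#'
#' An `"overlap"` variant is available:
#' \eqn{\sum_{w \in T \cap Q} x_w / |T \cup Q|}, the topic mass on shared
#' terms scaled by the union size (asymmetric).
#'
#' @param x,y Named nonnegative numeric vectors (term -> weight); for the
#'   default variant each is expected to sum to 1.
#' @param variant `"minmax"` (default) or `"overlap"`.
#' @return Similarity in \[0, 1\].
#' @export
weighted_jaccard <- function(x, y, variant = c("minmax", "overlap")) {
  variant <- match.arg(variant)
  x <- x[x > 0]
  y <- y[y > 0]
  if (length(x) == 0 || length(y) == 0) {
    stop("weighted_jaccard requires nonempty supports", call. = FALSE)
  }
  if (is.null(names(x)) || is.null(names(y))) {
    stop("weight vectors must be named by term", call. = FALSE)
  }
  terms <- union(names(x), names(y))
  xv <- stats::setNames(rep(0, length(terms)), terms)
  yv <- xv
  xv[names(x)] <- x
  yv[names(y)] <- y
  if (variant == "minmax") {
    sum(pmin(xv, yv)) / sum(pmax(xv, yv))
  } else {
    shared <- intersect(names(x), names(y))
    sum(x[shared]) / length(terms)
  }
}

#' Topic profiles: renormalized top-n term weights
#'
#' @param model An `lda_model`.
#' @param top_n Number of highest-probability terms kept per topic
#'   (default 20, the keyword-presentation convention).
#' @return List of K named weight vectors, each summing to 1.
#' @export
topic_profiles <- function(model, top_n = 20) {
  K <- nrow(model$phi)
  n <- min(top_n, ncol(model$phi))
  lapply(seq_len(K), function(t) {
    tw <- top_words(model, t, n = n)
    stats::setNames(tw$probability / sum(tw$probability), tw$term)
  })
}

#' Item profiles: uniform weights over preprocessed item tokens
#'
#' Items are normalized with the identical pipeline as the messages
#' (including lay-term substitution) so that both profiles live in the same
#' vocabulary. Items whose text reduces to no tokens are flagged with a
#' warning and dropped.
#'
#' @param q A `questionnaire`.
#' @param config,lexicons,... Passed to [preprocess_document()].
#' @return Named list (by item number) of uniform weight vectors.
#' @export
item_profiles <- function(q, config = preprocess_config(),
                          lexicons = lexicon_set(), ...) {
  stopifnot(inherits(q, "questionnaire"))
  profiles <- lapply(q$items$text, function(txt) {
    tok <- preprocess_document(txt, config = config, lexicons = lexicons, ...)
    terms <- unique(tok$lemma)
    if (length(terms) == 0) return(NULL)
    stats::setNames(rep(1 / length(terms), length(terms)), terms)
  })
  names(profiles) <- q$items$item_number
  empty <- vapply(profiles, is.null, logical(1))
  if (any(empty)) {
    warning("item(s) reduced to no tokens and were skipped: ",
            paste(q$items$item_number[empty], collapse = ", "), call. = FALSE)
  }
  profiles[!empty]
}

#' Align questionnaire items to topics
#'
#' Scores every item against every topic with the probability-weighted
#' Jaccard similarity and keeps the best topic per item (ties broken toward
#' the lowest topic id). The full item-by-topic score matrix is retained as
#' the `"score_matrix"` attribute for audit.
#'
#' @param model An `lda_model`.
#' @param q A `questionnaire`.
#' @param config,lexicons Preprocessing settings shared with the corpus.
#' @param top_n Terms per topic profile (default 20).
#' @param variant Similarity variant, see [weighted_jaccard()].
#' @param ... Passed to [preprocess_document()] (e.g. a lemmatizer).
#' @return Tibble of class `alignment_result` with columns `item_number`,
#'   `scale`, `best_topic`, `score`.
#' @export
align_items <- function(model, q, config = preprocess_config(),
                        lexicons = lexicon_set(), top_n = 20,
                        variant = c("minmax", "overlap"), ...) {
  variant <- match.arg(variant)
  stopifnot(inherits(q, "questionnaire"))
  if (nrow(q$items) == 0) stop("questionnaire has no items", call. = FALSE)
  tprof <- topic_profiles(model, top_n = top_n)
  iprof <- item_profiles(q, config = config, lexicons = lexicons, ...)
  if (length(iprof) == 0) stop("no questionnaire item survived preprocessing", call. = FALSE)
  K <- length(tprof)
  scores <- matrix(0, nrow = length(iprof), ncol = K,
                   dimnames = list(names(iprof), NULL))
  for (i in seq_along(iprof)) {
    for (t in seq_len(K)) {
      scores[i, t] <- weighted_jaccard(tprof[[t]], iprof[[i]], variant = variant)
    }
  }
  item_numbers <- as.integer(names(iprof))
  best <- apply(scores, 1, which.max)     # first max = lowest topic id on ties
  out <- tibble::tibble(
    item_number = item_numbers,
    scale = q$items$scale[match(item_numbers, q$items$item_number)],
    best_topic = as.integer(best),
    score = scores[cbind(seq_along(best), best)]
  )
  attr(out, "score_matrix") <- scores
  class(out) <- c("alignment_result", class(out))
  out
}

#' Precision of item-topic alignments against expert annotations
#'
#' Each proposed (item, best topic) relationship must carry an expert
#' verdict; precision is the percentage of validated relationships, rounded
#' to the nearest whole percent.
#'
#' @param alignment An `alignment_result` (or tibble with `item_number`,
#'   `best_topic`).
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @return List with `n_validated`, `n_invalidated`, `precision`.
#' @export
evaluate_precision <- function(alignment, annotations) {
  key_align <- paste(alignment$item_number, alignment$best_topic)
  key_ann <- paste(annotations$item_number, annotations$topic_id)
  hit <- match(key_align, key_ann)
  if (anyNA(hit)) {
    stop("no annotation for item(s): ",
         paste(alignment$item_number[is.na(hit)], collapse = ", "),
         call. = FALSE)
  }
  verdict <- annotations$validated[hit]
  n_val <- sum(verdict)
  n_inv <- sum(!verdict)
  list(n_validated = n_val, n_invalidated = n_inv,
       precision = round(100 * n_val / (n_val + n_inv)))
}

#' Emerging topics: topics validated for no questionnaire item
#'
#' Topics that are the validated best topic of no item are candidate
#' emerging concerns the instruments do not cover; they are reported with
#' the number and share of corpus documents they dominate.
#'
#' @param alignment An `alignment_result`.
#' @param annotations Annotation tibble.
#' @param model The fitted `lda_model` (for dominant-document counts).
#' @return Tibble with `topic`, `count`, `percent` for each emerging topic.
#' @export
emerging_topics <- function(alignment, annotations, model) {
  key_align <- paste(alignment$item_number, alignment$best_topic)
  key_ann <- paste(annotations$item_number, annotations$topic_id)
  hit <- match(key_align, key_ann)
  validated_topics <- unique(alignment$best_topic[!is.na(hit) & annotations$validated[hit]])
  dist <- dominant_topic_counts(model)
  out <- dist[!(dist$topic %in% validated_topics), , drop = FALSE]
  class(out) <- c("emerging_topic_report", class(out))
  out
}

#' Match topics across two fitted models
#'
#' Greedy one-to-one pairing of topics from two corpora: similarities are
#' computed between top-`top_n` profiles over the union vocabulary (terms
#' absent from a model have weight 0), the highest-similarity pair is taken
#' first, and pairing stops when the best remaining similarity falls below
#' `threshold`.
#'
#' @param model_a,model_b Fitted `lda_model`s.
#' @param top_n Terms per topic profile.
#' @param threshold Minimum similarity to accept a pair (default 0.3).
#' @param variant Similarity variant, see [weighted_jaccard()].
#' @return Tibble with `topic_a`, `topic_b`, `score`, sorted by decreasing
#'   score; zero rows if nothing clears the threshold.
#' @export
match_topics_across_corpora <- function(model_a, model_b, top_n = 20,
                                        threshold = 0.3,
                                        variant = c("minmax", "overlap")) {
  variant <- match.arg(variant)
  pa <- topic_profiles(model_a, top_n = top_n)
  pb <- topic_profiles(model_b, top_n = top_n)
  S <- matrix(0, length(pa), length(pb))
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      S[i, j] <- weighted_jaccard(pa[[i]], pb[[j]], variant = variant)
    }
  }
  pairs <- tibble::tibble(topic_a = integer(), topic_b = integer(),
                          score = numeric())
  while (TRUE) {
    best <- which.max(S)
    if (length(best) == 0 || S[best] < threshold) break
    ij <- arrayInd(best, dim(S))
    pairs <- rbind(pairs, tibble::tibble(topic_a = ij[1], topic_b = ij[2],
                                         score = S[best]))
    S[ij[1], ] <- -Inf
    S[, ij[2]] <- -Inf
    if (all(!is.finite(S))) break
  }
  pairs
}
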