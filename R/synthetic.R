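rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), ncol = k, byrow = TRUE)
  sweep(x, 1, rowSums(x), "/")
}

#' Generate a corpus from the LDA generative model
#'
#' Draws topic-term distributions `phi_t ~ Dirichlet(beta_gen)`, then for
#' each document `theta_d ~ Dirichlet(alpha)` with `alpha = alpha0 / K`, a
#' topic per position from `theta_d`, and a term from the chosen topic. The
#' generating `phi`, `theta` and per-position assignments are returned as
#' ground truth for recovery experiments. Documents are also wrapped as raw
#' messages (space-joined terms, users and threads assigned round-robin) so
#' the reading and summary utilities can be exercised on synthetic data.
#'
#' Defaults emulate short patient messages around well-separated themes:
#' `beta_gen = 0.01` yields peaked topics (fitting typically uses the larger
#' smoothing `beta = 0.1`), `alpha0 = 10` matches the fitting scheme, and
#' document lengths are Poisson with mean 30 truncated at 1.
#'
#' @param K,V,D Number of topics, vocabulary size, number of documents.
#' @param doc_length Either a fixed integer length or `"poisson"`.
#' @param mean_length Mean of the (truncated) Poisson document length.
#' @param alpha0 Document-topic prior mass; `alpha = alpha0 / K`.
#' @param beta_gen Topic-term concentration used for generation.
#' @param n_users,n_threads Round-robin sizes for the message metadata.
#' @param seed Integer seed (mandatory; generation is reproducible).
#' @return List with `corpus` (a `doc_term_corpus` over the synthetic
#'   vocabulary `term001`, `term002`, ...), `messages` (a `qol_corpus`
#'   tibble), and `truth` (list: `phi`, `theta`, `assignments`,
#'   `alpha`, `beta_gen`).
#' @export
generate_corpus <- function(K = 5, V = 200, D = 500,
                            doc_length = "poisson", mean_length = 30,
                            alpha0 = 10, beta_gen = 0.01,
                            n_users = 40, n_threads = 120, seed) {
  if (missing(seed)) stop("seed is mandatory for corpus generation", call. = FALSE)
  stopifnot(K >= 1, V >= 2, D >= 0)
  set.seed(seed)
  alpha <- alpha0 / K
  vocab <- sprintf("term%03d", seq_len(V))
  phi <- rdirichlet(K, rep(beta_gen, V))

  if (D == 0) {
    truth <- list(phi = phi, theta = matrix(0, 0, K), assignments = list(),
                  alpha = alpha, beta_gen = beta_gen)
    msgs <- tibble::tibble(message_id = character(), thread_id = character(),
                           user_id = character(), date = character(),
                           text = character())
    class(msgs) <- c("qol_corpus", class(msgs))
    return(list(corpus = new_doc_term_corpus(vocab, list(), "synthetic"),
                messages = msgs, truth = truth))
  }

  lens <- if (identical(doc_length, "poisson")) {
    pmax(1L, stats::rpois(D, mean_length))
  } else {
    rep(as.integer(doc_length), D)
  }
  theta <- rdirichlet(D, rep(alpha, K))
  docs <- vector("list", D)
  assignments <- vector("list", D)
  for (d in seq_len(D)) {
    z <- sample.int(K, lens[d], replace = TRUE, prob = theta[d, ])
    w <- integer(lens[d])
    for (t in unique(z)) {
      idx <- which(z == t)
      w[idx] <- sample.int(V, length(idx), replace = TRUE, prob = phi[t, ])
    }
    docs[[d]] <- w
    assignments[[d]] <- z
  }

  msgs <- tibble::tibble(
    message_id = sprintf("m%05d", seq_len(D)),
    thread_id = sprintf("t%04d", (seq_len(D) - 1L) %% n_threads + 1L),
    user_id = sprintf("u%04d", (seq_len(D) - 1L) %% n_users + 1L),
    date = "",
    text = vapply(docs, function(w) paste(vocab[w], collapse = " "), character(1))
  )
  class(msgs) <- c("qol_corpus", class(msgs))

  list(corpus = new_doc_term_corpus(vocab, docs, "synthetic"),
       messages = msgs,
       truth = list(phi = phi, theta = theta, assignments = assignments,
                    alpha = alpha, beta_gen = beta_gen))
}

#' Generate a questionnaire from synthetic topic truth
#'
#' Emulates quality-of-life items: very short sentences (fewer than five
#' words) drawn from a topic's highest-probability terms, with the
#' generating topic recorded as ground truth. Optionally one uniform noise
#' term per item.
#'
#' @param truth Truth list from [generate_corpus()].
#' @param vocabulary Vocabulary of the generating corpus.
#' @param topics Topic ids to write items for (default: all).
#' @param items_per_topic Items generated per topic.
#' @param words_per_item Distinct terms per item (2-4).
#' @param noise_word_prob Probability that an item receives one extra term
#'   drawn uniformly from the whole vocabulary.
#' @param top_pool Size of the per-topic top-term pool sampled from.
#' @param seed Integer seed.
#' @return List with `questionnaire` (a `questionnaire` object; scale names
#'   `"synthetic scale <t>"`) and `labels` (tibble `item_number`, `topic`).
#' @export
generate_questionnaire <- function(truth, vocabulary, topics = NULL,
                                   items_per_topic = 1, words_per_item = 4,
                                   noise_word_prob = 0, top_pool = 20, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (!(words_per_item %in% 2:4)) stop("words_per_item must be 2, 3 or 4", call. = FALSE)
  K <- nrow(truth$phi)
  V <- ncol(truth$phi)
  if (is.null(topics)) topics <- seq_len(K)
  if (any(topics < 1 | topics > K)) stop("requested topic does not exist", call. = FALSE)
  pool_n <- min(top_pool, V)
  if (words_per_item > pool_n) stop("words_per_item exceeds the top-word pool", call. = FALSE)
  set.seed(seed)
  rows <- list()
  labels <- list()
  item_no <- 0L
  for (t in topics) {
    ord <- order(-truth$phi[t, ], seq_len(V))[seq_len(pool_n)]
    pool_p <- truth$phi[t, ord]
    for (i in seq_len(items_per_topic)) {
      item_no <- item_no + 1L
      w <- ord[sample.int(pool_n, words_per_item, prob = pool_p)]
      terms <- vocabulary[w]
      if (noise_word_prob > 0 && stats::runif(1) < noise_word_prob) {
        terms <- c(terms, vocabulary[sample.int(V, 1)])
      }
      rows[[item_no]] <- tibble::tibble(item_number = item_no,
                                        scale = sprintf("synthetic scale %d", t),
                                        text = paste(terms, collapse = " "))
      labels[[item_no]] <- tibble::tibble(item_number = item_no, topic = t)
    }
  }
  list(questionnaire = questionnaire("synthetic QoL instrument",
                                     do.call(rbind, rows)),
       labels = do.call(rbind, labels))
}

#' Wrap clean tokens in social-media noise
#'
#' Builds a raw message around a clean token sequence by injecting the kinds
#' of noise the normalization pipeline removes: user tags, URLs and email
#' addresses, slang, pseudonyms, lay variants of medical terms (the inverse
#' of the lay-to-medical table), misspellings (the inverse of the spelling
#' dictionary), and random uppercasing. By construction,
#' `preprocess_document()` on the result recovers the clean tokens exactly
#' when run with the same lexicons and `link_mode = "delete"` (with
#' `link_mode = "replace"` each injected URL/email additionally yields a
#' `"link"`/`"mail"` token).
#'
#' @param clean_tokens Character vector of normalized tokens (lowercase,
#'   not in any removal lexicon).
#' @param lexicons A `lexicon_set` supplying slang/pseudonyms and the
#'   substitution tables to invert.
#' @param noise Character vector choosing injections, any of `"user_tag"`,
#'   `"url"`, `"email"`, `"slang"`, `"pseudonym"`, `"lay_swap"`,
#'   `"misspell"`, `"case"`.
#' @param seed Integer seed.
#' @return The noisy text string; the clean tokens are recoverable by
#'   [preprocess_document()].
#' @export
generate_noisy_text <- function(clean_tokens, lexicons = lexicon_set(),
                                noise = c("user_tag", "url", "slang",
                                          "pseudonym", "lay_swap", "case"),
                                seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  words <- clean_tokens

  if ("lay_swap" %in% noise && length(lexicons$lay_to_medical) > 0) {
    inv <- stats::setNames(names(lexicons$lay_to_medical),
                           unname(lexicons$lay_to_medical))
    hit <- which(words %in% names(inv))
    swap <- hit[stats::runif(length(hit)) < 0.5]
    words[swap] <- unname(inv[words[swap]])
  }
  if ("misspell" %in% noise && length(lexicons$spelling_dictionary) > 0) {
    inv <- stats::setNames(names(lexicons$spelling_dictionary),
                           unname(lexicons$spelling_dictionary))
    hit <- which(words %in% names(inv))
    swap <- hit[stats::runif(length(hit)) < 0.5]
    words[swap] <- unname(inv[words[swap]])
  }
  if ("case" %in% noise && length(words) > 0) {
    flip <- stats::runif(length(words)) < 0.3
    words[flip] <- toupper(words[flip])
  }

  inject <- character(0)
  if ("user_tag" %in% noise) inject <- c(inject, paste0("@user", sample.int(999, 1)))
  if ("url" %in% noise) inject <- c(inject, sprintf("http://example.org/p%d", sample.int(999, 1)))
  if ("email" %in% noise) inject <- c(inject, sprintf("user%d@example.org", sample.int(999, 1)))
  if ("slang" %in% noise && length(lexicons$slang) > 0) {
    inject <- c(inject, sample(lexicons$slang, 1))
  }
  if ("pseudonym" %in% noise && length(lexicons$pseudonyms) > 0) {
    inject <- c(inject, sample(lexicons$pseudonyms, 1))
  }

  # scatter injections between the clean words
  out <- words
  for (nz in inject) {
    pos <- sample.int(length(out) + 1L, 1) - 1L
    out <- append(out, nz, after = pos)
  }
  paste(out, collapse = " ")
}
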