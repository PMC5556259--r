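#' LDA hyperparameters with the alpha = alpha0/K scheme
#'
#' The document-topic concentration is parameterized as `alpha = alpha0 / K`,
#' which keeps the effective prior mass `alpha0` on each document constant as
#' the number of topics changes. Defaults follow the scheme used for
#' patient-forum corpora: `alpha0 = 10` (the classical 50 yields overly flat
#' document-topic posteriors on short messages), `beta = 0.1`, `K = 20`.
#'
#' @param K Number of topics; must exceed 1.
#' @param alpha0 Total document-topic prior mass; `alpha = alpha0 / K`.
#' @param beta Topic-word concentration.
#' @param n_iterations Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before averaging count tables.
#' @param seed Integer RNG seed.
#' @return A `lda_hyperparameters` list with the derived `alpha` filled in.
#' @export
lda_hyperparameters <- function(K = 20, alpha0 = 10, beta = 0.1,
                                n_iterations = 1000, burn_in = 200,
                                seed = 1L) {
  K <- as.integer(K)
  if (is.na(K) || K <= 1L) stop("K must be an integer > 1", call. = FALSE)
  if (alpha0 <= 0 || beta <= 0) stop("alpha0 and beta must be positive", call. = FALSE)
  if (burn_in < 0 || n_iterations <= burn_in) {
    stop("need n_iterations > burn_in >= 0", call. = FALSE)
  }
  structure(list(K = K, alpha0 = alpha0, alpha = alpha0 / K, beta = beta,
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "lda_hyperparameters")
}

new_lda_model <- function(phi, theta, hyperparameters, vocabulary,
                          assignments = NULL) {
  structure(list(phi = phi, theta = theta, hyperparameters = hyperparameters,
                 vocabulary = vocabulary, assignments = assignments),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> K =", nrow(x$phi), " V =", ncol(x$phi),
      " D =", nrow(x$theta), "\n")
  cat("  alpha0 =", x$hyperparameters$alpha0,
      " alpha =", x$hyperparameters$alpha,
      " beta =", x$hyperparameters$beta, "\n")
  invisible(x)
}

#' Fit LDA by collapsed Gibbs sampling
#'
#' Topic assignments are initialized uniformly at random and resampled
#' position by position from the collapsed conditional
#' \deqn{P(z = t \mid \cdot) \propto (n_{d,t}^{-i} + \alpha)\,
#'   \frac{n_{t,w}^{-i} + \beta}{n_t^{-i} + V\beta}.}
#' After `burn_in` sweeps the count tables are averaged over the retained
#' sweeps, and the point estimates are the smoothed ratios
#' \eqn{\hat\phi_{t,w} = (\bar n_{t,w} + \beta) / (\bar n_t + V\beta)} and
#' \eqn{\hat\theta_{d,t} = (\bar n_{d,t} + \alpha) / (l_d + K\alpha)}.
#' Runs are bitwise reproducible for a fixed seed: the sampler uses R's RNG
#' and a fixed scan order.
#'
#' @param corpus A `doc_term_corpus` (see [build_vocabulary()] or
#'   [generate_corpus()]).
#' @param hp An `lda_hyperparameters` object.
#' @param check_counts Verify count-table conservation after every sweep
#'   (cheap on small corpora; used by the test suite).
#' @param allow_single_topic Permit `K = 1`, in which case the closed form is
#'   returned without sampling: `theta[d, 1] = 1` and
#'   `phi[w] = (n_w + beta) / (N + V beta)`. Off by default; ordinary fits
#'   require `K > 1`.
#' @return An `lda_model` with `phi` (K x V), `theta` (D x K),
#'   `hyperparameters`, `vocabulary`, and the final sweep's `assignments`
#'   (list of 1-based topic ids per position).
#' @export
fit_lda_gibbs <- function(corpus, hp = lda_hyperparameters(),
                          check_counts = FALSE, allow_single_topic = FALSE) {
  stopifnot(inherits(corpus, "doc_term_corpus"))
  V <- length(corpus$vocabulary)
  if (V == 0) stop("vocabulary is empty", call. = FALSE)
  l_d <- doc_lengths(corpus)
  if (sum(l_d) == 0) stop("all documents are empty", call. = FALSE)

  if (allow_single_topic && !is.null(hp$K) && hp$K == 1) {
    counts <- tabulate(unlist(corpus$docs), nbins = V)
    phi <- matrix((counts + hp$beta) / (sum(counts) + V * hp$beta), nrow = 1)
    colnames(phi) <- corpus$vocabulary
    theta <- matrix(1, nrow = length(corpus$docs), ncol = 1)
    hp$alpha <- hp$alpha0
    return(new_lda_model(phi, theta, unclass(hp), corpus$vocabulary,
                         assignments = lapply(l_d, function(n) rep(1L, n))))
  }
  if (!inherits(hp, "lda_hyperparameters")) stop("hp must be lda_hyperparameters", call. = FALSE)
  if (hp$K <= 1L) stop("K must be > 1 (single-topic closed form requires allow_single_topic)", call. = FALSE)

  docs0 <- lapply(corpus$docs, function(d) as.integer(d) - 1L)
  set.seed(hp$seed)
  fit <- gibbs_lda_cpp(docs0, V, hp$K, hp$alpha, hp$beta,
                       hp$n_iterations, hp$burn_in, check_counts)

  nt_bar <- rowSums(fit$avg_nw)
  phi <- (fit$avg_nw + hp$beta) / (nt_bar + V * hp$beta)
  theta <- (fit$avg_nd + hp$alpha) / (l_d + hp$K * hp$alpha)
  colnames(phi) <- corpus$vocabulary
  new_lda_model(phi, theta, unclass(hp), corpus$vocabulary,
                assignments = lapply(fit$z, function(z) z + 1L))
}

#' Top terms of a topic
#'
#' @param model An `lda_model`.
#' @param topic_id Topic index in `1:K`.
#' @param n Number of terms (default 20, the customary keyword cut).
#' @return Tibble with `term` and `probability`, sorted by probability
#'   descending; ties broken by vocabulary index ascending.
#' @export
top_words <- function(model, topic_id, n = 20) {
  K <- nrow(model$phi)
  if (length(topic_id) != 1 || is.na(topic_id) || topic_id < 1 || topic_id > K) {
    stop("topic_id must be in 1..", K, call. = FALSE)
  }
  V <- ncol(model$phi)
  if (n < 1 || n > V) stop("n must be in 1..", V, call. = FALSE)
  p <- model$phi[topic_id, ]
  ord <- order(-p, seq_len(V))[seq_len(n)]
  tibble::tibble(term = model$vocabulary[ord], probability = unname(p[ord]))
}

#' Dominant-topic distribution of documents
#'
#' Each document is assigned its highest-probability topic (ties broken
#' toward the lowest topic index); the per-topic document counts and shares
#' are the figures reported in per-topic distribution tables.
#'
#' @param model An `lda_model`.
#' @return Tibble with `topic`, `count` and `percent`
#'   (`100 * count / D`, rounded to 2 decimals).
#' @export
dominant_topic_counts <- function(model) {
  K <- nrow(model$phi)
  D <- nrow(model$theta)
  dom <- apply(model$theta, 1, which.max)   # which.max takes the first max
  counts <- tabulate(dom, nbins = K)
  tibble::tibble(topic = seq_len(K), count = counts,
                 percent = round(100 * counts / D, 2))
}

#' Held-out perplexity of a corpus under a fitted model
#'
#' \deqn{\mathrm{PPX} = \exp\!\left(-\frac{\sum_d \sum_j \log \sum_t
#'   \hat\theta_{d,t}\hat\phi_{t,w_{dj}}}{\sum_d l_d}\right)}
#' Lower is better. The corpus must use the model's vocabulary (term ids are
#' remapped by name when the vocabularies differ).
#'
#' @param model An `lda_model`; `theta` must have one row per corpus
#'   document.
#' @param corpus A `doc_term_corpus`.
#' @return A positive scalar (always >= 1 for a proper model).
#' @export
perplexity <- function(model, corpus) {
  stopifnot(inherits(corpus, "doc_term_corpus"))
  D <- length(corpus$docs)
  if (nrow(model$theta) != D) {
    stop("model theta has ", nrow(model$theta), " rows but corpus has ", D,
         " documents", call. = FALSE)
  }
  same_vocab <- identical(corpus$vocabulary, model$vocabulary)
  if (!same_vocab) {
    idx_map <- match(corpus$vocabulary, model$vocabulary)
    oov <- corpus$vocabulary[is.na(idx_map)]
    if (length(oov) > 0) {
      stop("term(s) not in model vocabulary: ", paste(oov, collapse = ", "),
           call. = FALSE)
    }
  }
  loglik <- 0
  for (d in seq_len(D)) {
    ids <- corpus$docs[[d]]
    if (length(ids) == 0) next
    if (!same_vocab) ids <- idx_map[ids]
    # P(w | d) = theta_d %*% phi[, w]
    pw <- as.numeric(model$theta[d, , drop = FALSE] %*% model$phi[, ids, drop = FALSE])
    loglik <- loglik + sum(log(pw))
  }
  exp(-loglik / sum(doc_lengths(corpus)))
}

#' Exact LDA posterior by exhaustive enumeration
#'
#' Enumerates all `K^N` topic-assignment vectors of a tiny corpus
#' (`N = sum l_d` total positions), weights each by the collapsed joint
#' \deqn{P(w, z) = \prod_d \frac{\Gamma(K\alpha)}{\Gamma(l_d + K\alpha)}
#'   \prod_t \frac{\Gamma(n_{d,t} + \alpha)}{\Gamma(\alpha)} \times
#'   \prod_t \frac{\Gamma(V\beta)}{\Gamma(n_t + V\beta)}
#'   \prod_w \frac{\Gamma(n_{t,w} + \beta)}{\Gamma(\beta)},}
#' and returns the exact posterior mean of
#' \eqn{\theta_{d,t} = (n_{d,t} + \alpha)/(l_d + K\alpha)}. This is a
#' brute-force reference for validating the Gibbs sampler and shares no code
#' with it. Refuses corpora with more than `max_positions` positions.
#'
#' @param corpus A `doc_term_corpus`.
#' @param K Number of topics.
#' @param alpha,beta Concentration parameters (`alpha` is the per-topic
#'   value, i.e. `alpha0 / K`).
#' @param max_positions Safety cap on `N` (default 12).
#' @return A `D x K` matrix of exact posterior means of theta.
#' @export
enumerate_lda_posterior <- function(corpus, K, alpha, beta, max_positions = 12) {
  stopifnot(inherits(corpus, "doc_term_corpus"))
  V <- length(corpus$vocabulary)
  l_d <- doc_lengths(corpus)
  N <- sum(l_d)
  if (N == 0) stop("all documents are empty", call. = FALSE)
  if (N > max_positions) {
    stop("corpus has ", N, " positions; enumeration is limited to ",
         max_positions, call. = FALSE)
  }
  D <- length(corpus$docs)
  doc_of <- rep(seq_len(D), l_d)
  word_of <- unlist(corpus$docs, use.names = FALSE)

  n_assign <- K^N
  logw <- numeric(n_assign)
  theta_num <- array(0, dim = c(D, K))
  thetas <- vector("list", n_assign)
  z <- integer(N)
  for (a in seq_len(n_assign)) {
    rem <- a - 1L
    for (j in seq_len(N)) {
      z[j] <- rem %% K + 1L
      rem <- rem %/% K
    }
    ndt <- matrix(0L, D, K)
    ntw <- matrix(0L, K, V)
    for (j in seq_len(N)) {
      ndt[doc_of[j], z[j]] <- ndt[doc_of[j], z[j]] + 1L
      ntw[z[j], word_of[j]] <- ntw[z[j], word_of[j]] + 1L
    }
    nt <- rowSums(ntw)
    logw[a] <- sum(lgamma(ndt + alpha)) - sum(lgamma(l_d + K * alpha)) +
      sum(lgamma(ntw + beta)) - sum(lgamma(nt + V * beta))
    thetas[[a]] <- (ndt + alpha) / (l_d + K * alpha)
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  post <- Reduce(`+`, Map(`*`, thetas, w))
  unname(post)
}
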