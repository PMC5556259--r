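#' Total variation distance between two discrete distributions
#'
#' @param p,q Numeric probability vectors of equal length.
#' @return `0.5 * sum(abs(p - q))`, in \[0, 1\].
#' @export
total_variation <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p - q))
}

#' Greedy matching of fitted topics to generating topics
#'
#' Topic indices are arbitrary across runs (label switching), so recovery is
#' evaluated after a one-to-one matching: pairs are taken greedily by
#' maximal overlap `sum(pmin(phi_hat[t, ], phi_true[s, ]))`, i.e. minimal
#' total variation, highest overlap first.
#'
#' @param phi_hat Fitted K x V topic-term matrix.
#' @param phi_true Generating K x V topic-term matrix.
#' @return List with `map` (integer vector: `map[t]` is the true topic
#'   matched to fitted topic `t`) and `tv` (per-pair total variation
#'   distances, indexed by fitted topic).
#' @export
match_topics_greedy <- function(phi_hat, phi_true) {
  K <- nrow(phi_hat)
  stopifnot(nrow(phi_true) == K, ncol(phi_true) == ncol(phi_hat))
  overlap <- matrix(0, K, K)
  for (t in seq_len(K)) {
    for (s in seq_len(K)) {
      overlap[t, s] <- sum(pmin(phi_hat[t, ], phi_true[s, ]))
    }
  }
  map <- integer(K)
  tv <- numeric(K)
  O <- overlap
  for (step in seq_len(K)) {
    ij <- arrayInd(which.max(O), dim(O))
    t <- ij[1]; s <- ij[2]
    map[t] <- s
    tv[t] <- total_variation(phi_hat[t, ], phi_true[s, ])
    O[t, ] <- -Inf
    O[, s] <- -Inf
  }
  list(map = map, tv = tv)
}

#' Parameter-recovery metrics for a fit against generator truth
#'
#' Matches fitted to generating topics (see [match_topics_greedy()]) and
#' reports the mean total variation between matched topic-term rows and the
#' fraction of documents whose fitted dominant topic maps to the generating
#' dominant topic. The generating dominant topic of a document is the topic
#' that generated the most of its positions (the mode of its true
#' assignments; ties toward the lowest topic id) — the realized quantity a
#' fit can actually recover, unlike the argmax of the latent `theta_d`,
#' which a finite document does not determine.
#'
#' @param model Fitted `lda_model`.
#' @param truth Truth list from [generate_corpus()].
#' @return List with `mean_tv`, `dominant_agreement` (proportion in
#'   \[0, 1\]), and the topic `map`.
#' @export
recovery_metrics <- function(model, truth) {
  m <- match_topics_greedy(model$phi, truth$phi)
  K <- nrow(truth$phi)
  dom_hat <- apply(model$theta, 1, which.max)
  dom_true <- vapply(truth$assignments,
                     function(z) which.max(tabulate(z, nbins = K)), integer(1))
  agree <- mean(m$map[dom_hat] == dom_true)
  list(mean_tv = mean(m$tv), dominant_agreement = agree, map = m$map)
}

#' Entropy of each document-topic distribution
#'
#' Diagnostic for the concentration scheme: larger `alpha0` flattens the
#' document-topic posteriors, which shows up as higher mean row entropy.
#'
#' @param model An `lda_model`.
#' @return Numeric vector of per-document entropies (nats).
#' @export
theta_entropy <- function(model) {
  apply(model$theta, 1, function(p) -sum(p[p > 0] * log(p[p > 0])))
}
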