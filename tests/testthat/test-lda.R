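test_that("hyperparameters enforce the alpha = alpha0/K scheme", {
  hp <- lda_hyperparameters(K = 20, alpha0 = 10, beta = 0.1)
  expect_identical(hp$alpha, 0.5)
  expect_error(lda_hyperparameters(K = 1), "K must be")
  expect_error(lda_hyperparameters(K = 5, alpha0 = -1), "positive")
  expect_error(lda_hyperparameters(K = 5, n_iterations = 10, burn_in = 10))
})

test_that("K = 1 closed form under the test override", {
  dtm <- tiny_dtm(list(c(1, 1, 2), c(3, 3)))
  hp <- lda_hyperparameters(K = 2, beta = 0.1)  # valid construction
  hp$K <- 1L
  m <- fit_lda_gibbs(dtm, hp, allow_single_topic = TRUE)
  expect_equal(m$theta, matrix(1, 2, 1))
  N <- 5; V <- 3
  expect_equal(as.numeric(m$phi),
               (c(2, 1, 2) + 0.1) / (N + V * 0.1))
  # ordinary fits reject K = 1
  expect_error(fit_lda_gibbs(dtm, hp), "K must be")
})

test_that("empty documents get the prior mean 1/K", {
  dtm <- tiny_dtm(list(c(1, 2, 3), integer(0)))
  m <- fit_lda_gibbs(dtm, lda_hyperparameters(K = 4, n_iterations = 60,
                                              burn_in = 20, seed = 1))
  expect_equal(unname(m$theta[2, ]), rep(0.25, 4))
})

test_that("fits are bitwise reproducible from the seed", {
  g <- generate_corpus(K = 3, V = 30, D = 20, mean_length = 8, seed = 10)
  hp <- lda_hyperparameters(K = 3, n_iterations = 80, burn_in = 20, seed = 123)
  m1 <- fit_lda_gibbs(g$corpus, hp)
  m2 <- fit_lda_gibbs(g$corpus, hp)
  expect_identical(m1$phi, m2$phi)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$assignments, m2$assignments)
  m3 <- fit_lda_gibbs(g$corpus, lda_hyperparameters(K = 3, n_iterations = 80,
                                                    burn_in = 20, seed = 124))
  expect_false(identical(m1$phi, m3$phi))
})

test_that("phi and theta rows are stochastic and positive; counts conserve", {
  g <- generate_corpus(K = 4, V = 40, D = 30, mean_length = 10, seed = 2)
  m <- fit_lda_gibbs(g$corpus, lda_hyperparameters(K = 4, n_iterations = 120,
                                                   burn_in = 30, seed = 5),
                     check_counts = TRUE)  # sampler aborts on any violation
  expect_equal(rowSums(m$phi), rep(1, 4), tolerance = 1e-9)
  expect_equal(rowSums(m$theta), rep(1, 30), tolerance = 1e-9)
  expect_true(all(m$phi > 0) && all(m$theta > 0))
  # final-sweep assignments conserve document lengths
  expect_equal(lengths(m$assignments), lengths(g$corpus$docs))
  expect_true(all(unlist(m$assignments) %in% 1:4))
})

test_that("degenerate corpora are rejected", {
  expect_error(fit_lda_gibbs(tiny_dtm(list(integer(0))),
                             lda_hyperparameters(K = 2)), "empty")
  expect_error(fit_lda_gibbs(qoltopics:::new_doc_term_corpus(character(), list(1L)),
                             lda_hyperparameters(K = 2)), "empty")
})

test_that("top_words ranks by probability with index tie-break", {
  m <- manual_model(phi = rbind(c(0.5, 0.3, 0.2)),
                    theta = matrix(1, 1, 1), vocab = c("t0", "t1", "t2"))
  tw <- top_words(m, 1, n = 2)
  expect_equal(tw$term, c("t0", "t1"))
  expect_equal(tw$probability, c(0.5, 0.3))

  m2 <- manual_model(phi = rbind(c(0.4, 0.4, 0.2)),
                     theta = matrix(1, 1, 1), vocab = c("t0", "t1", "t2"))
  expect_equal(top_words(m2, 1, n = 1)$term, "t0")

  # n = V: a permutation of the vocabulary, probabilities summing to 1
  set.seed(6)
  p <- rgamma(7, 1); p <- p / sum(p)
  m3 <- manual_model(phi = rbind(p), theta = matrix(1, 1, 1),
                     vocab = letters[1:7])
  tw3 <- top_words(m3, 1, n = 7)
  expect_setequal(tw3$term, letters[1:7])
  expect_equal(sum(tw3$probability), 1)
  expect_equal(tw3$probability, sort(p, decreasing = TRUE))

  expect_error(top_words(m3, 0), "topic_id")
  expect_error(top_words(m3, 2), "topic_id")
})

test_that("dominant_topic_counts tallies argmax theta with low-index ties", {
  theta <- rbind(c(0.1, 0.2, 0.6, 0.1),
                 c(0.1, 0.2, 0.7, 0.0),
                 c(0.5, 0.5, 0.0, 0.0))   # tie -> topic 1
  m <- manual_model(phi = matrix(0.25, 4, 4), theta = theta)
  d <- dominant_topic_counts(m)
  expect_equal(d$count, c(1L, 0L, 2L, 0L))
  expect_equal(d$percent, c(33.33, 0, 66.67, 0))
  expect_equal(sum(d$percent), 100, tolerance = 0.1)

  # spiked: all documents on topic 3
  m2 <- manual_model(phi = matrix(0.25, 4, 4),
                     theta = matrix(rep(c(0, 0, 1, 0), 5), 5, byrow = TRUE))
  d2 <- dominant_topic_counts(m2)
  expect_equal(d2$count, c(0L, 0L, 5L, 0L))
  expect_equal(d2$percent, c(0, 0, 100, 0))

  # random fixture vs brute-force tally
  set.seed(31)
  th <- qoltopics:::rdirichlet(50, rep(0.5, 6))
  m3 <- manual_model(phi = matrix(1 / 6, 6, 6), theta = th)
  brute <- tabulate(apply(th, 1, which.max), 6)
  expect_equal(dominant_topic_counts(m3)$count, brute)
})

test_that("perplexity matches its closed forms and an independent recomputation", {
  # uniform phi: perplexity = V regardless of theta
  V <- 9
  dtm <- tiny_dtm(list(c(1, 5, 9), c(2, 2)), vocab = letters[1:V])
  m <- manual_model(phi = matrix(1 / V, 2, V, dimnames = list(NULL, letters[1:V])),
                    theta = rbind(c(0.3, 0.7), c(0.9, 0.1)),
                    vocab = letters[1:V])
  expect_equal(perplexity(m, dtm), V)

  # independent log-sum recomputation on a random model
  set.seed(13)
  phi <- qoltopics:::rdirichlet(3, rep(0.5, V))
  theta <- qoltopics:::rdirichlet(2, rep(1, 3))
  m2 <- manual_model(phi = phi, theta = theta, vocab = letters[1:V])
  ll <- 0
  for (d in 1:2) for (w in dtm$docs[[d]]) {
    ll <- ll + log(sum(theta[d, ] * phi[, w]))
  }
  expect_equal(perplexity(m2, dtm), exp(-ll / 5), tolerance = 1e-10)
  expect_gte(perplexity(m2, dtm), 1)

  # out-of-vocabulary terms are named in the error
  dtm_oov <- tiny_dtm(list(1L), vocab = "zebra")
  m3 <- manual_model(phi = matrix(1 / V, 1, V), theta = matrix(1, 1, 1),
                     vocab = letters[1:V])
  expect_error(perplexity(m3, dtm_oov), "zebra")
})

test_that("document-topic entropy is non-decreasing in alpha0", {
  g <- generate_corpus(K = 4, V = 100, D = 150, mean_length = 30,
                       beta_gen = 0.01, alpha0 = 10, seed = 9)
  ent <- vapply(c(1, 10, 50), function(a0) {
    m <- fit_lda_gibbs(g$corpus,
                       lda_hyperparameters(K = 4, alpha0 = a0, beta = 0.1,
                                           n_iterations = 300, burn_in = 100,
                                           seed = 3))
    mean(theta_entropy(m))
  }, numeric(1))
  expect_true(all(diff(ent) >= 0))
})
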