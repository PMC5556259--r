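test_that("weighted Jaccard matches hand-computed min/max sums", {
  x <- c(a = 0.5, b = 0.3, c = 0.2)
  y <- c(a = 0.5, b = 0.5)
  # min-sum = 0.5 + 0.3 + 0 = 0.8; max-sum = 0.5 + 0.5 + 0.2 = 1.2
  expect_equal(weighted_jaccard(x, y), 0.8 / 1.2, tolerance = 1e-12)
  expect_equal(weighted_jaccard(x, x), 1)
  expect_equal(weighted_jaccard(c(a = 1), c(b = 1)), 0)
  expect_error(weighted_jaccard(c(a = 0), c(b = 1)), "nonempty")
})

test_that("weighted Jaccard axioms hold on randomized profiles", {
  set.seed(2024)
  vocab <- sprintf("w%02d", 1:30)
  rand_profile <- function() {
    n <- sample(1:10, 1)
    terms <- sample(vocab, n)
    w <- rgamma(n, 1); stats::setNames(w / sum(w), terms)
  }
  for (i in 1:200) {
    x <- rand_profile(); y <- rand_profile()
    s <- weighted_jaccard(x, y)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, weighted_jaccard(y, x))                      # symmetry
    expect_equal(weighted_jaccard(x, x), 1)                      # identity
    # uniform-weight limit: equal-size uniform supports reduce to set Jaccard
    if (length(x) == length(y)) {
      xu <- stats::setNames(rep(1 / length(x), length(x)), names(x))
      yu <- stats::setNames(rep(1 / length(y), length(y)), names(y))
      ji <- length(intersect(names(x), names(y))) /
        length(union(names(x), names(y)))
      expect_equal(weighted_jaccard(xu, yu), ji, tolerance = 1e-12)
    }
  }
})

test_that("adding a shared term never decreases similarity (monotonicity)", {
  set.seed(55)
  vocab <- sprintf("w%02d", 1:20)
  for (i in 1:100) {
    yterms <- sample(vocab, sample(3:8, 1))
    y <- stats::setNames(rep(1 / length(yterms), length(yterms)), yterms)
    xterms <- sample(setdiff(vocab, yterms), sample(2:5, 1))
    w <- rgamma(length(xterms), 1)
    x <- stats::setNames(w / sum(w), xterms)
    s0 <- weighted_jaccard(x, y)
    # add one of y's terms to x with positive weight, renormalize
    shared <- sample(yterms, 1)
    eps <- runif(1, 0.05, 0.5)
    x2 <- c(x * (1 - eps), stats::setNames(eps, shared))
    expect_gte(weighted_jaccard(x2, y), s0 - 1e-12)
  }
})

test_that("overlap variant scores shared topic mass over the union", {
  x <- c(a = 0.5, b = 0.3, c = 0.2)
  y <- c(a = 0.5, d = 0.5)
  expect_equal(weighted_jaccard(x, y, variant = "overlap"), 0.5 / 4)
})

test_that("items align to the topic sharing their words", {
  phi <- rbind(c(0.6, 0.3, 0.05, 0.05),
               c(0.05, 0.05, 0.5, 0.4))
  m <- manual_model(phi = phi, theta = matrix(0.5, 3, 2),
                    vocab = c("cancer", "douleur", "cheveu", "perruque"))
  q <- questionnaire("test", tibble::tibble(
    item_number = 1:2, scale = c("s1", "s2"),
    text = c("cancer douleur", "cheveu perruque")))
  al <- align_items(m, q, lexicons = lexicon_set(medical_terms = "cancer"))
  expect_equal(al$best_topic, c(1L, 2L))
  expect_true(all(al$score > 0))
  sm <- attr(al, "score_matrix")
  expect_equal(dim(sm), c(2, 2))
  expect_equal(al$score, sm[cbind(1:2, al$best_topic)])
})

test_that("alignment is invariant to topic relabeling", {
  set.seed(7)
  phi <- qoltopics:::rdirichlet(4, rep(0.1, 12))
  vocab <- sprintf("w%02d", 1:12)
  m <- manual_model(phi = phi, theta = matrix(0.25, 2, 4), vocab = vocab)
  q <- questionnaire("test", tibble::tibble(
    item_number = 1:3, scale = "s",
    text = vapply(1:3, function(i) paste(sample(vocab, 3), collapse = " "),
                  character(1))))
  lex <- lexicon_set(medical_terms = "cancer")
  al <- align_items(m, q, lexicons = lex)
  perm <- c(3, 1, 4, 2)
  m_perm <- manual_model(phi = phi[perm, ], theta = matrix(0.25, 2, 4),
                         vocab = vocab)
  al_perm <- align_items(m_perm, q, lexicons = lex)
  expect_equal(perm[al_perm$best_topic], al$best_topic)
  expect_equal(al_perm$score, al$score)
})

test_that("items that preprocess to nothing are flagged and skipped", {
  m <- manual_model(phi = rbind(c(0.5, 0.5)), theta = matrix(1, 1, 1),
                    vocab = c("cancer", "douleur"))
  q <- questionnaire("test", tibble::tibble(
    item_number = 1:2, scale = "s", text = c("cancer", "le la")))
  lex <- lexicon_set(medical_terms = "cancer", stopwords = c("le", "la"))
  expect_warning(al <- align_items(m, q, lexicons = lex), "skipped: 2")
  expect_equal(al$item_number, 1L)
})

test_that("precision reproduces the published validation arithmetic", {
  mk <- function(n_val, n_inv) {
    n <- n_val + n_inv
    al <- tibble::tibble(item_number = seq_len(n), best_topic = 1L)
    ann <- tibble::tibble(item_number = seq_len(n), topic_id = 1L,
                          validated = c(rep(TRUE, n_val), rep(FALSE, n_inv)))
    evaluate_precision(al, ann)
  }
  expect_equal(mk(39, 14)$precision, 74)
  expect_equal(mk(36, 17)$precision, 68)
  expect_equal(mk(0, 53)$precision, 0)
  expect_equal(mk(39, 14)$n_validated, 39)

  al <- tibble::tibble(item_number = 1:2, best_topic = c(1L, 2L))
  ann <- tibble::tibble(item_number = 1L, topic_id = 1L, validated = TRUE)
  expect_error(evaluate_precision(al, ann), "no annotation.*2")
})

test_that("emerging topics are those never validated, with document shares", {
  theta <- matrix(0.01, 100, 4)
  dom <- rep(1:4, c(50, 30, 15, 5))
  theta[cbind(1:100, dom)] <- 0.9
  m <- manual_model(phi = matrix(0.25, 4, 4), theta = theta)
  al <- tibble::tibble(item_number = 1:3, best_topic = c(1L, 2L, 3L))
  ann <- tibble::tibble(item_number = 1:3, topic_id = c(1L, 2L, 3L),
                        validated = c(TRUE, TRUE, FALSE))
  rep_ <- emerging_topics(al, ann, m)
  expect_setequal(rep_$topic, c(3L, 4L))
  expect_equal(rep_$count[rep_$topic == 4], 5)
  expect_equal(rep_$percent[rep_$topic == 4], 5)

  al2 <- tibble::tibble(item_number = 1:4, best_topic = 1:4)
  ann_all <- tibble::tibble(item_number = 1:4, topic_id = 1:4, validated = TRUE)
  expect_equal(nrow(emerging_topics(al2, ann_all, m)), 0)
})

test_that("cross-corpus matching pairs a model with itself perfectly", {
  set.seed(44)
  phi <- qoltopics:::rdirichlet(5, rep(0.05, 40))
  m <- manual_model(phi = phi, theta = matrix(0.2, 3, 5),
                    vocab = sprintf("w%02d", 1:40))
  p <- match_topics_across_corpora(m, m)
  expect_equal(nrow(p), 5)
  expect_equal(p$topic_a, p$topic_b)
  expect_equal(p$score, rep(1, 5))
})

test_that("disjoint vocabularies yield an empty pairing", {
  m1 <- manual_model(phi = rbind(c(0.6, 0.4)), theta = matrix(1, 1, 1),
                     vocab = c("a", "b"))
  m2 <- manual_model(phi = rbind(c(0.7, 0.3)), theta = matrix(1, 1, 1),
                     vocab = c("c", "d"))
  p <- match_topics_across_corpora(m1, m2)
  expect_equal(nrow(p), 0)
})

test_that("two corpora from the same topics pair up by similarity", {
  g1 <- generate_corpus(K = 5, V = 120, D = 150, mean_length = 40,
                        beta_gen = 0.01, seed = 61)
  # second corpus from the same phi, fresh theta/z
  set.seed(62)
  phi <- g1$truth$phi
  docs2 <- lapply(1:150, function(d) {
    th <- as.numeric(qoltopics:::rdirichlet(1, rep(2, 5)))
    z <- sample.int(5, 40, TRUE, th)
    vapply(z, function(t) sample.int(120, 1, prob = phi[t, ]), integer(1))
  })
  dtm2 <- qoltopics:::new_doc_term_corpus(g1$corpus$vocabulary, docs2)
  hp <- lda_hyperparameters(K = 5, n_iterations = 400, burn_in = 100, seed = 1)
  m1 <- fit_lda_gibbs(g1$corpus, hp)
  m2 <- fit_lda_gibbs(dtm2, hp)
  pairing <- match_topics_across_corpora(m1, m2)
  # verify against truth: topics of both fits mapped to generator topics
  map1 <- match_topics_greedy(m1$phi, phi)$map
  map2 <- match_topics_greedy(m2$phi, phi)$map
  correct <- sum(map1[pairing$topic_a] == map2[pairing$topic_b])
  expect_gte(correct, 4)
})
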