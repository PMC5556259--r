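test_that("topic tables list top words per topic with a label column", {
  phi <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.2, 0.7))
  m <- manual_model(phi = phi, theta = matrix(0.5, 2, 2),
                    vocab = c("cheveu", "perdre", "perruque"))
  tt <- topic_table(m, n = 10)
  expect_equal(nrow(tt), 2)
  expect_equal(tt$top_words[1], "cheveu, perdre, perruque")  # all words, V < 10
  expect_equal(tt$label, c("", ""))

  tt2 <- topic_table(m, n = 2, labels = c("hair loss", "wigs"),
                     translations = c(cheveu = "hair", perdre = "lose",
                                      perruque = "wig"))
  expect_equal(tt2$translation[1], "hair, lose")
  expect_equal(tt2$label[2], "wigs")
})

test_that("renderers are byte-stable pure functions", {
  phi <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.2, 0.7))
  m <- manual_model(phi = phi, theta = matrix(0.5, 2, 2),
                    vocab = c("a", "b", "c"))
  tt <- topic_table(m)
  expect_identical(render_tsv(tt), render_tsv(tt))
  expect_identical(render_markdown(tt), render_markdown(tt))
  expect_match(render_markdown(tt), "^\\| topic \\|")
  expect_equal(length(strsplit(render_tsv(tt), "\n")[[1]]), 3)
})

test_that("distribution cells format counts with two-decimal shares", {
  expect_equal(format_count_percent(523, 16868), "523 (3.10)")
  expect_equal(format_count_percent(3014, 70092), "3014 (4.30)")
  expect_equal(format_count_percent(0, 100), "0 (0.00)")
  d <- distribution_table(c(523, 16868 - 523))
  expect_equal(d$documents[1], "523 (3.10)")
  expect_equal(d$documents[3], "16868 (100.00)")
})

test_that("dimension coverage uses truncated integer percentages", {
  expect_equal(dimension_coverage(c(rep(TRUE, 22), FALSE))$percent, 95)
  expect_equal(dimension_coverage(c(rep(TRUE, 20), rep(FALSE, 3)))$percent, 86)
  expect_equal(dimension_coverage(rep(TRUE, 4))$percent, 100)
})

test_that("alignment map groups validated topics by scale with a trailing section", {
  m <- manual_model(phi = matrix(0.2, 5, 5), theta = matrix(0.2, 4, 5))
  q <- questionnaire("test", tibble::tibble(
    item_number = 1:4,
    scale = c("Pain", "Pain", "Fatigue", "Fatigue"),
    text = letters[1:4]))
  al <- tibble::tibble(item_number = 1:4, scale = q$items$scale,
                       best_topic = c(2L, 2L, 3L, 4L),
                       score = rep(0.5, 4))
  ann <- tibble::tibble(item_number = 1:4, topic_id = c(2L, 2L, 3L, 4L),
                        validated = c(TRUE, TRUE, TRUE, FALSE))
  tab <- alignment_map_table(al, ann, q, m)
  expect_equal(tab$topics[tab$scale == "Pain"], "2")
  expect_equal(tab$topics[tab$scale == "Fatigue"], "3")
  orphan_row <- tab[tab$section == "topics without a relationship", ]
  expect_equal(orphan_row$topics, "1, 4, 5")

  # every topic validated somewhere -> empty trailing section
  m3 <- manual_model(phi = matrix(1 / 3, 3, 3), theta = matrix(1 / 3, 2, 3))
  ann3 <- tibble::tibble(item_number = 1:4, topic_id = c(1L, 2L, 3L, 3L),
                         validated = TRUE)
  al3 <- tibble::tibble(item_number = 1:4, scale = q$items$scale,
                        best_topic = c(1L, 2L, 3L, 3L), score = 0.5)
  tab3 <- alignment_map_table(al3, ann3, q, m3)
  expect_equal(tab3$topics[tab3$section == "topics without a relationship"], "")
})

test_that("the cross-corpus report partitions both topic sets", {
  set.seed(17)
  for (i in 1:20) {
    Ka <- sample(3:8, 1); Kb <- sample(3:8, 1)
    npair <- sample(0:min(Ka, Kb), 1)
    pairing <- tibble::tibble(topic_a = sample(Ka, npair),
                              topic_b = sample(Kb, npair),
                              score = runif(npair, 0.3, 1))
    counts_a <- tibble::tibble(topic = 1:Ka, count = rpois(Ka, 50) + 1L)
    counts_b <- tibble::tibble(topic = 1:Kb, count = rpois(Kb, 50) + 1L)
    tab <- cross_corpus_table(pairing, counts_a, counts_b)
    seen_a <- tab$topic_a[tab$topic_a != "N/A"]
    seen_b <- tab$topic_b[tab$topic_b != "N/A"]
    expect_setequal(as.integer(seen_a), 1:Ka)   # no topic lost
    expect_equal(anyDuplicated(seen_a), 0)      # none duplicated
    expect_setequal(as.integer(seen_b), 1:Kb)
    expect_equal(anyDuplicated(seen_b), 0)
    expect_true(all(tab$section %in% c("both", "only one")))
  }
})

test_that("unmatched questionnaire flags render as Yes/No", {
  pairing <- tibble::tibble(topic_a = 1L, topic_b = 2L, score = 0.9)
  counts_a <- tibble::tibble(topic = 1:2, count = c(10L, 5L))
  counts_b <- tibble::tibble(topic = 1:2, count = c(7L, 8L))
  tab <- cross_corpus_table(pairing, counts_a, counts_b,
                            matched_a = c(TRUE, FALSE),
                            matched_b = c(TRUE, FALSE))
  expect_equal(tab$questionnaire_match[tab$section == "both"], "Yes")
  expect_true("No" %in% tab$questionnaire_match)
})

test_that("bundled study tables load with the documented shape", {
  st <- qlq_study_tables()
  expect_equal(nrow(st$topic_counts), 20)
  expect_equal(sum(st$topic_counts$forum_n), 16868)
  expect_equal(sum(st$topic_counts$facebook_n), 70092)
  expect_equal(nrow(st$dimension_map), 23)
  expect_equal(st$validation_counts$n_validated +
                 st$validation_counts$n_invalidated,
               st$validation_counts$n_items)
})
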