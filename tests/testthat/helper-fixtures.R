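# Shared fixtures, built in code.

test_lexicons <- function() {
  lexicon_set(
    medical_terms = c("cancer", "chimiothérapie", "oncologue", "docteur",
                      "sein", "cancer du sein", "tamoxifène", "douleur",
                      "mammographie"),
    lay_to_medical = c(crabe = "cancer", onco = "oncologue",
                       chimio = "chimiothérapie"),
    stopwords = c("le", "la", "les", "un", "une", "de", "du", "et", "je", "il"),
    slang = c("lol", "mdr", "xd", "ptdr"),
    pseudonyms = c("marie123", "jeandu34"),
    noise_terms = c("femme", "temps"),
    spelling_dictionary = c(cancr = "cancer", doctur = "docteur")
  )
}

test_lemmatizer <- function() {
  dictionary_lemmatizer(data.frame(
    surface = c("regarde", "revient", "cheveux", "perdu", "vais", "douleurs"),
    lemma = c("regarder", "revenir", "cheveu", "perdre", "aller", "douleur"),
    pos = c("V", "V", "NN", "V", "V", "NN"),
    stringsAsFactors = FALSE
  ))
}

# A tiny document-term corpus over an explicit vocabulary (1-based ids).
tiny_dtm <- function(docs, vocab = c("a", "b", "c")) {
  qoltopics:::new_doc_term_corpus(vocab, lapply(docs, as.integer))
}

# Build an lda_model directly from given phi/theta (for operations that do
# not need a fitted chain).
manual_model <- function(phi, theta, vocab = colnames(phi)) {
  if (is.null(vocab)) vocab <- sprintf("w%d", seq_len(ncol(phi)))
  colnames(phi) <- vocab
  qoltopics:::new_lda_model(phi = phi, theta = theta,
                            hyperparameters = list(K = nrow(phi), alpha0 = 10,
                                                   alpha = 10 / nrow(phi),
                                                   beta = 0.1, seed = 1L),
                            vocabulary = vocab)
}

# Random raw-text fixture drawing from every token class the normalization
# pipeline handles; returns the text only (properties recompute the pipeline).
random_noisy_fixture <- function(lex) {
  pool <- c(lex$medical_terms[!grepl(" ", lex$medical_terms)],
            "guérir", "espoir", "fatigue", "attendre", "résultat")
  n <- sample(1:8, 1)
  clean <- sample(pool, n, replace = TRUE)
  generate_noisy_text(clean, lexicons = lex,
                      noise = sample(c("user_tag", "url", "slang", "pseudonym",
                                       "lay_swap", "misspell", "case"),
                                     sample(2:6, 1)),
                      seed = sample.int(1e6, 1))
}

delete_config <- function() preprocess_config(link_mode = "delete")
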