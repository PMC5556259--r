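Package: qoltopics
Title: Topic Modeling of Patient-Authored Text Aligned to Quality-of-Life Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for mining patient concerns from noisy
    social-media text and confronting them with standardized quality-of-life
    instruments. Normalizes patient-authored messages (user tags, links,
    slang, lay medical vocabulary, pseudonyms), builds vocabulary scenarios
    restricted to medical terms optionally extended by part of speech, fits
    latent Dirichlet allocation by collapsed Gibbs sampling with the
    alpha = alpha0/K hyperparameter scheme, aligns inferred topics to
    questionnaire items (EORTC QLQ-C30 and QLQ-BR23 numbering) with a
    probability-weighted Jaccard similarity, evaluates alignment precision
    against expert annotations, and flags emerging topics absent from the
    instruments. A synthetic-data module generates corpora, questionnaires
    and noisy-text fixtures with known ground truth so every stage is
    testable without access to the original communities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    tibble,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
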