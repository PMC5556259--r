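#' Read a run configuration from YAML
#'
#' A single YAML file drives the whole chain: paths to the corpus, lexicon
#' directory, questionnaire and annotations, the preprocessing settings, the
#' sampler hyperparameters, and the alignment settings. Missing blocks fall
#' back to package defaults. The configuration round-trips through
#' [yaml::write_yaml()].
#'
#' @param path Path to a YAML file.
#' @return A named list with elements `paths`, `preprocess` (a
#'   `preprocess_config`), `hyperparameters` (an `lda_hyperparameters`),
#'   `alignment` (list `top_n`, `variant`, `threshold`), `scenario`,
#'   `output_dir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  pp <- cfg$preprocess %||% list()
  hp <- cfg$hyperparameters %||% list()
  al <- cfg$alignment %||% list()
  list(
    paths = cfg$paths %||% list(),
    scenario = cfg$scenario %||% "MED+NN+V+A",
    preprocess = preprocess_config(
      steps = pp$steps %||% 1:9,
      link_mode = pp$link_mode %||% "replace",
      emoticons = pp$emoticons %||% TRUE
    ),
    hyperparameters = lda_hyperparameters(
      K = hp$K %||% 20, alpha0 = hp$alpha0 %||% 10, beta = hp$beta %||% 0.1,
      n_iterations = hp$n_iterations %||% 1000, burn_in = hp$burn_in %||% 200,
      seed = hp$seed %||% 1L
    ),
    alignment = list(top_n = al$top_n %||% 20,
                     variant = al$variant %||% "minmax",
                     threshold = al$threshold %||% 0.3),
    output_dir = cfg$output_dir %||% "."
  )
}

#' Run the full pipeline from a configuration
#'
#' Chains normalization, vocabulary construction, Gibbs fitting, item
#' alignment, precision evaluation and reporting. Stages log their timing;
#' the model artifact and report tables are written under the configured
#' output directory when `write_outputs = TRUE`.
#'
#' @param config A list as returned by [read_run_config()], or a path to a
#'   YAML file.
#' @param lemmatizer Optional lemmatizer (see [dictionary_lemmatizer()]).
#' @param write_outputs Write model artifact and TSV reports.
#' @param verbose Log stage progress and timings.
#' @return List with `corpus`, `tokenized`, `dtm`, `model`, `alignment`, and
#'   (when annotations are configured) `precision`, `emerging`.
#' @export
run_pipeline <- function(config, lemmatizer = dictionary_lemmatizer(),
                         write_outputs = FALSE, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(label, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    say("[%s] done in %.2fs", label, as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  say("seed: %d", config$hyperparameters$seed)

  corpus <- stage("read", read_corpus(config$paths$corpus))
  lexicons <- if (!is.null(config$paths$lexicons)) {
    read_lexicons(config$paths$lexicons)
  } else {
    lexicon_set(medical_terms = "cancer")
  }
  tokenized <- stage("preprocess",
                     preprocess_corpus(corpus, config = config$preprocess,
                                       lexicons = lexicons, lemmatizer = lemmatizer))
  dtm <- stage("vocabulary",
               build_vocabulary(tokenized, scenario = config$scenario,
                                lexicons = lexicons))
  model <- stage("fit", fit_lda_gibbs(dtm, config$hyperparameters))

  out <- list(corpus = corpus, tokenized = tokenized, dtm = dtm, model = model)

  if (!is.null(config$paths$questionnaire)) {
    q <- read_questionnaire(config$paths$questionnaire)
    out$alignment <- stage("align",
                           align_items(model, q, config = config$preprocess,
                                       lexicons = lexicons,
                                       top_n = config$alignment$top_n,
                                       variant = config$alignment$variant,
                                       lemmatizer = lemmatizer))
    if (!is.null(config$paths$annotations)) {
      ann <- read_annotations(config$paths$annotations)
      out$precision <- stage("evaluate", evaluate_precision(out$alignment, ann))
      out$emerging <- emerging_topics(out$alignment, ann, model)
      say("precision: %d%% (%d validated / %d invalidated)",
          out$precision$precision, out$precision$n_validated,
          out$precision$n_invalidated)
    }
  }

  if (write_outputs) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    save_model(model, file.path(config$output_dir, "model"))
    writeLines(render_tsv(topic_table(model, n = 20)),
               file.path(config$output_dir, "topics.tsv"))
    writeLines(render_tsv(distribution_table(dominant_topic_counts(model))),
               file.path(config$output_dir, "distribution.tsv"))
    if (!is.null(out$alignment)) {
      utils::write.csv(as.data.frame(out$alignment),
                       file.path(config$output_dir, "alignment.csv"),
                       row.names = FALSE)
    }
  }
  out
}
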