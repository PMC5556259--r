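#' Read a corpus of social-media messages
#'
#' One message per document. The canonical format is JSONL (one UTF-8 JSON
#' object per line with keys `message_id`, `thread_id`, `user_id`, `date`,
#' `text`); CSV with the same column names is also accepted. Dates are kept
#' as raw strings and never interpreted.
#'
#' @param path Path to a `.jsonl` or `.csv` file.
#' @param format `"jsonl"` or `"csv"`; guessed from the file extension when
#'   omitted.
#' @return A tibble of class `qol_corpus` with one row per message, in file
#'   order, and columns `message_id`, `thread_id`, `user_id`, `date`, `text`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  required <- c("message_id", "thread_id", "user_id", "date", "text")
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    records <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) stop("malformed JSON on line ", i, ": ",
                                               conditionMessage(e), call. = FALSE))
      missing <- setdiff(required, names(rec))
      if (length(missing) > 0) {
        stop("record ", i, " (message_id=", rec$message_id %||% "<absent>",
             ") is missing field(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      lapply(rec[required], as.character)
    })
    corpus <- tibble::as_tibble(do.call(rbind.data.frame,
                                        c(records, stringsAsFactors = FALSE)))
    names(corpus) <- required
  } else {
    df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop("CSV corpus is missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    corpus <- tibble::as_tibble(df[required])
  }
  dup <- corpus$message_id[duplicated(corpus$message_id)]
  if (length(dup) > 0) {
    stop("duplicate message_id in corpus: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  class(corpus) <- c("qol_corpus", class(corpus))
  corpus
}

#' Write a corpus as JSONL
#'
#' @param corpus A `qol_corpus` tibble (see [read_corpus()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(as.list(corpus[i, c("message_id", "thread_id", "user_id",
                                         "date", "text")]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Summarize a corpus (users, threads, messages)
#'
#' Counts of distinct users, distinct threads, and messages, the three
#' figures conventionally reported for a scraped community corpus.
#'
#' @param corpus A `qol_corpus` tibble.
#' @return Named integer vector `c(n_users, n_threads, n_messages)`.
#' @export
corpus_summary <- function(corpus) {
  c(n_users = length(unique(corpus$user_id)),
    n_threads = length(unique(corpus$thread_id)),
    n_messages = nrow(corpus))
}

#' Read a questionnaire from JSON
#'
#' The JSON object carries `instrument_name` and an `items` array of
#' `{item_number, scale, text}`. Item numbering follows the combined scheme
#' used with the EORTC instruments: QLQ-C30 items 1-30, QLQ-BR23 items 31-53.
#'
#' @param path Path to a questionnaire JSON file.
#' @return A `questionnaire` object: list with `instrument_name` and an
#'   `items` tibble.
#' @export
read_questionnaire <- function(path) {
  if (!file.exists(path)) stop("questionnaire file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(obj$items)) stop("questionnaire JSON has no 'items' array", call. = FALSE)
  items <- tibble::as_tibble(obj$items)
  questionnaire(obj$instrument_name %||% "unnamed", items)
}

#' Construct a questionnaire object
#'
#' @param instrument_name Instrument label, e.g. `"EORTC QLQ-C30 + QLQ-BR23"`.
#' @param items Data frame with columns `item_number` (integer), `scale`
#'   (character), `text` (character).
#' @return A `questionnaire` object.
#' @export
questionnaire <- function(instrument_name, items) {
  items <- tibble::as_tibble(items)
  needed <- c("item_number", "scale", "text")
  missing <- setdiff(needed, names(items))
  if (length(missing) > 0) {
    stop("questionnaire items lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  items$item_number <- as.integer(items$item_number)
  if (anyDuplicated(items$item_number)) {
    stop("duplicate item_number in questionnaire: ",
         paste(unique(items$item_number[duplicated(items$item_number)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(items$item_number < 1)) stop("item_number must be >= 1", call. = FALSE)
  if (any(!nzchar(items$text))) stop("questionnaire item text must be nonempty", call. = FALSE)
  structure(list(instrument_name = instrument_name, items = items[needed]),
            class = "questionnaire")
}

#' Write a questionnaire to JSON
#'
#' @param q A `questionnaire` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_questionnaire <- function(q, path) {
  jsonlite::write_json(list(instrument_name = q$instrument_name, items = q$items),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.questionnaire <- function(x, ...) {
  cat("<questionnaire>", x$instrument_name, "-", nrow(x$items), "items\n")
  print(x$items, ...)
  invisible(x)
}

#' Construct a lexicon set
#'
#' Bundles the resources the normalization pipeline consumes: the medical
#' term list (MeSH-style, the MED set; multi-word entries allowed), the
#' lay-to-medical substitution table, stopwords, slang, pseudonyms, noise
#' terms always excluded from vocabularies, and a spelling dictionary.
#'
#' @param medical_terms Character vector of medical terms.
#' @param lay_to_medical Named character vector: `names()` are lay variants,
#'   values the canonical terms. No entry may map to itself.
#' @param stopwords,slang,pseudonyms,noise_terms Character vectors.
#' @param spelling_dictionary Named character vector: misspelling -> correction.
#' @return A `lexicon_set` object.
#' @export
lexicon_set <- function(medical_terms = character(),
                        lay_to_medical = character(),
                        stopwords = character(),
                        slang = character(),
                        pseudonyms = character(),
                        noise_terms = c("femme", "temps"),
                        spelling_dictionary = character()) {
  check_map <- function(map, what) {
    if (length(map) > 0) {
      if (is.null(names(map)) || any(!nzchar(names(map)))) {
        stop(what, " must be a named character vector", call. = FALSE)
      }
      self <- names(map) == unname(map)
      if (any(self)) {
        stop(what, " maps term(s) to themselves: ",
             paste(names(map)[self], collapse = ", "), call. = FALSE)
      }
    }
    map
  }
  structure(list(
    medical_terms = as.character(medical_terms),
    lay_to_medical = check_map(lay_to_medical, "lay_to_medical"),
    stopwords = as.character(stopwords),
    slang = as.character(slang),
    pseudonyms = as.character(pseudonyms),
    noise_terms = as.character(noise_terms),
    spelling_dictionary = check_map(spelling_dictionary, "spelling_dictionary")
  ), class = "lexicon_set")
}

#' Read a lexicon set from a directory
#'
#' Expects one-term-per-line text files `medical_terms.txt`, `stopwords.txt`,
#' `slang.txt`, `pseudonyms.txt`, `noise_terms.txt` and two-column TSVs
#' `lay_to_medical.tsv`, `spelling_dictionary.tsv` (variant TAB canonical,
#' no header). Absent files yield empty components.
#'
#' @param dir Directory containing the lexicon files.
#' @return A `lexicon_set` object.
#' @export
read_lexicons <- function(dir) {
  if (!dir.exists(dir)) stop("lexicon directory not found: ", dir, call. = FALSE)
  read_list <- function(name) {
    f <- file.path(dir, name)
    if (!file.exists(f)) return(character())
    x <- readLines(f, encoding = "UTF-8", warn = FALSE)
    x[nzchar(trimws(x))]
  }
  read_map <- function(name) {
    f <- file.path(dir, name)
    if (!file.exists(f)) return(character())
    df <- utils::read.delim(f, header = FALSE, colClasses = "character",
                            encoding = "UTF-8")
    if (ncol(df) < 2) stop(name, " must have two tab-separated columns", call. = FALSE)
    stats::setNames(df[[2]], df[[1]])
  }
  lexicon_set(
    medical_terms = read_list("medical_terms.txt"),
    lay_to_medical = read_map("lay_to_medical.tsv"),
    stopwords = read_list("stopwords.txt"),
    slang = read_list("slang.txt"),
    pseudonyms = read_list("pseudonyms.txt"),
    noise_terms = read_list("noise_terms.txt"),
    spelling_dictionary = read_map("spelling_dictionary.tsv")
  )
}

#' Write a lexicon set to a directory
#'
#' Inverse of [read_lexicons()]; empty components are not written.
#'
#' @param lex A `lexicon_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lexicons <- function(lex, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_list <- function(x, name) {
    if (length(x) > 0) writeLines(x, file.path(dir, name), useBytes = TRUE)
  }
  write_map <- function(map, name) {
    if (length(map) > 0) {
      utils::write.table(data.frame(names(map), unname(map)),
                         file.path(dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
    }
  }
  write_list(lex$medical_terms, "medical_terms.txt")
  write_list(lex$stopwords, "stopwords.txt")
  write_list(lex$slang, "slang.txt")
  write_list(lex$pseudonyms, "pseudonyms.txt")
  write_list(lex$noise_terms, "noise_terms.txt")
  write_map(lex$lay_to_medical, "lay_to_medical.tsv")
  write_map(lex$spelling_dictionary, "spelling_dictionary.tsv")
  invisible(dir)
}

#' Read an expert annotation table
#'
#' CSV with columns `item_number`, `topic_id`, `validated` (0/1). Each
#' (item, topic) pair records whether the medical expert validated the
#' proposed relationship.
#'
#' @param path Path to the CSV file.
#' @return Tibble with integer `item_number`, `topic_id` and logical
#'   `validated`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, encoding = "UTF-8")
  missing <- setdiff(c("item_number", "topic_id", "validated"), names(df))
  if (length(missing) > 0) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ann <- tibble::tibble(item_number = as.integer(df$item_number),
                        topic_id = as.integer(df$topic_id),
                        validated = as.logical(as.integer(df$validated)))
  key <- paste(ann$item_number, ann$topic_id)
  if (anyDuplicated(key)) {
    stop("duplicate (item_number, topic_id) pair(s) in annotations: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  ann
}

#' Write an annotation table as CSV
#'
#' @param annotations Tibble as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  out <- data.frame(item_number = annotations$item_number,
                    topic_id = annotations$topic_id,
                    validated = as.integer(annotations$validated))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a fitted topic model to a directory
#'
#' The artifact is human-inspectable and language-neutral: `model.json`
#' holds the hyperparameters, seed, iteration counts and vocabulary;
#' `phi.tsv` and `theta.tsv` hold the topic-word and document-topic
#' matrices at full double precision.
#'
#' @param model An `lda_model` (see [fit_lda_gibbs()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(model$hyperparameters, list(vocabulary = model$vocabulary))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  write_matrix <- function(m, name) {
    con <- file(file.path(dir, name), open = "wb")
    on.exit(close(con))
    writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t")),
               con, useBytes = TRUE)
  }
  write_matrix(model$phi, "phi.tsv")
  write_matrix(model$theta, "theta.tsv")
  invisible(dir)
}

#' Load a fitted topic model saved by [save_model()]
#'
#' @param dir Directory written by [save_model()].
#' @return An `lda_model`.
#' @export
load_model <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path)) stop("no model.json under ", dir, call. = FALSE)
  meta <- jsonlite::fromJSON(meta_path)
  read_matrix <- function(name) {
    lines <- readLines(file.path(dir, name), encoding = "UTF-8", warn = FALSE)
    do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
  }
  vocab <- as.character(meta$vocabulary)
  hp <- meta[setdiff(names(meta), "vocabulary")]
  phi <- read_matrix("phi.tsv")
  theta <- read_matrix("theta.tsv")
  colnames(phi) <- vocab
  new_lda_model(phi = phi, theta = theta, hyperparameters = hp, vocabulary = vocab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
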