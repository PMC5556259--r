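#' Preprocessing configuration
#'
#' The normalization pipeline applies up to nine steps, always in this
#' canonical order:
#'
#' 1. user-tag removal (`@name`),
#' 2. hyperlink/email replacement (tokens `"link"` / `"mail"`) and emoticon
#'    coding (`":)"` to `":smile:"`, `":("` to `":sad:"`),
#' 3. slang removal (lol, mdr, xD, ...; matched case-insensitively),
#' 4. lemmatization (pluggable; dictionary lookup by default),
#' 5. lowercasing,
#' 6. stopword removal,
#' 7. lay-term substitution (e.g. crabe -> cancer),
#' 8. spelling correction (pluggable; dictionary lookup by default),
#' 9. pseudonym removal.
#'
#' `steps` selects a subsequence of that order; steps are never reordered.
#'
#' @param steps Integer vector, subsequence of `1:9`.
#' @param link_mode `"replace"` (hyperlinks become the token `"link"`,
#'   emails `"mail"`) or `"delete"` (removed outright).
#' @param emoticons `TRUE` to code emoticons as `:smile:` / `:sad:` tokens.
#' @param link_token,mail_token Replacement tokens used in `"replace"` mode.
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(steps = 1:9, link_mode = c("replace", "delete"),
                              emoticons = TRUE,
                              link_token = "link", mail_token = "mail") {
  steps <- as.integer(steps)
  if (any(is.na(steps)) || any(steps < 1L | steps > 9L) || is.unsorted(steps, strictly = TRUE)) {
    stop("steps must be a strictly increasing subsequence of 1:9", call. = FALSE)
  }
  structure(list(steps = steps, link_mode = match.arg(link_mode),
                 emoticons = isTRUE(emoticons),
                 link_token = link_token, mail_token = mail_token),
            class = "preprocess_config")
}

# Fixed emoticon coding table.
EMOTICON_CODES <- c(
  ":)" = ":smile:", ":-)" = ":smile:", "=)" = ":smile:",
  ":(" = ":sad:", ":-(" = ":sad:", "=(" = ":sad:"
)

#' Dictionary lemmatizer
#'
#' Returns a lemmatizer function mapping a character vector of surface forms
#' to a data frame with columns `lemma` and `pos` (`NN`, `V`, `A`, `OTHER`).
#' Lookup is case-insensitive on the surface form; forms absent from the
#' dictionary keep their surface as lemma with pos `OTHER` (identity
#' fallback), so the pipeline needs no external morphological analyzer.
#'
#' @param table Data frame with columns `surface`, `lemma`, `pos`, or `NULL`
#'   for the pure identity lemmatizer.
#' @return A function `f(surfaces)` returning `data.frame(lemma, pos)`.
#' @export
dictionary_lemmatizer <- function(table = NULL) {
  if (is.null(table) || nrow(table) == 0) {
    return(function(surfaces) {
      data.frame(lemma = surfaces, pos = rep("OTHER", length(surfaces)),
                 stringsAsFactors = FALSE)
    })
  }
  key <- tolower(table$surface)
  lemma_map <- stats::setNames(as.character(table$lemma), key)
  pos_map <- stats::setNames(as.character(table$pos), key)
  function(surfaces) {
    k <- tolower(surfaces)
    lemma <- unname(lemma_map[k])
    pos <- unname(pos_map[k])
    miss <- is.na(lemma)
    lemma[miss] <- surfaces[miss]
    pos[miss] <- "OTHER"
    data.frame(lemma = lemma, pos = pos, stringsAsFactors = FALSE)
  }
}

#' Dictionary spelling corrector
#'
#' Returns a corrector mapping tokens through a misspelling-to-correction
#' table; tokens absent from the table pass through unchanged.
#'
#' @param dictionary Named character vector (misspelling -> correction) or
#'   `NULL` for the identity corrector.
#' @return A function `f(tokens)` returning corrected tokens.
#' @export
dictionary_speller <- function(dictionary = NULL) {
  if (is.null(dictionary) || length(dictionary) == 0) {
    return(function(tokens) tokens)
  }
  function(tokens) {
    hit <- tokens %in% names(dictionary)
    tokens[hit] <- unname(dictionary[tokens[hit]])
    tokens
  }
}

# Tokenize normalized text. Unicode word characters, keeping :smile:-style
# coded emoticons intact; French elision clitics (l', d', j', qu', ...) are
# split off before extraction.
tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  text <- gsub("\\b([[:alpha:]]{1,2})['’]", "\\1 ", text, perl = TRUE)
  m <- gregexpr(":[a-z_]+:|[\\p{L}\\p{N}][\\p{L}\\p{N}_'’-]*", text, perl = TRUE)
  tokens <- regmatches(text, m)[[1]]
  tokens[nzchar(tokens)]
}

#' Normalize one message into tokens
#'
#' Applies the enabled normalization steps (see [preprocess_config()]) to a
#' raw message and returns the retained tokens with lemma and part of
#' speech. Deterministic, and idempotent on its own output: re-running the
#' pipeline on `paste(tokens$lemma, collapse = " ")` changes nothing
#' (provided the lemma/spelling dictionaries are fixed points on their own
#' outputs, which [lexicon_set()] invariants guarantee for the substitution
#' tables).
#'
#' @param text Raw message text (length-1 character; `NA` treated as empty).
#' @param config A `preprocess_config`.
#' @param lexicons A `lexicon_set`.
#' @param lemmatizer Function as returned by [dictionary_lemmatizer()].
#' @param speller Function as returned by [dictionary_speller()]; defaults
#'   to a dictionary corrector built from `lexicons$spelling_dictionary`.
#' @return A data frame with columns `surface`, `lemma`, `pos`; zero rows
#'   for empty input.
#' @export
preprocess_document <- function(text, config = preprocess_config(),
                                lexicons = lexicon_set(),
                                lemmatizer = dictionary_lemmatizer(),
                                speller = dictionary_speller(lexicons$spelling_dictionary)) {
  stopifnot(inherits(config, "preprocess_config"), inherits(lexicons, "lexicon_set"))
  if (length(text) != 1) stop("preprocess_document expects a single string", call. = FALSE)
  if (is.na(text)) text <- ""
  on <- function(k) k %in% config$steps

  # -- raw-text steps ------------------------------------------------------
  if (on(1L)) {
    text <- gsub("(?<=^|[^\\w])@[\\w._-]+", " ", text, perl = TRUE)
  }
  if (on(2L)) {
    link_rep <- if (config$link_mode == "replace") paste0(" ", config$link_token, " ") else " "
    mail_rep <- if (config$link_mode == "replace") paste0(" ", config$mail_token, " ") else " "
    text <- gsub("(https?://|www\\.)[^\\s]+", link_rep, text, perl = TRUE)
    text <- gsub("[\\w.+-]+@[\\w-]+\\.[\\w.]+", mail_rep, text, perl = TRUE)
    if (config$emoticons) {
      for (emo in names(EMOTICON_CODES)) {
        text <- gsub(emo, paste0(" ", EMOTICON_CODES[[emo]], " "), text, fixed = TRUE)
      }
    }
  }

  surfaces <- tokenize_text(text)
  if (length(surfaces) == 0) {
    return(data.frame(surface = character(), lemma = character(),
                      pos = character(), stringsAsFactors = FALSE))
  }

  # -- token steps ---------------------------------------------------------
  if (on(3L) && length(lexicons$slang) > 0) {
    keep <- !(tolower(surfaces) %in% tolower(lexicons$slang))
    surfaces <- surfaces[keep]
  }
  if (length(surfaces) == 0) {
    return(data.frame(surface = character(), lemma = character(),
                      pos = character(), stringsAsFactors = FALSE))
  }

  if (on(4L)) {
    lem <- lemmatizer(surfaces)
  } else {
    lem <- data.frame(lemma = surfaces, pos = rep("OTHER", length(surfaces)),
                      stringsAsFactors = FALSE)
  }
  tok <- data.frame(surface = surfaces, lemma = lem$lemma, pos = lem$pos,
                    stringsAsFactors = FALSE)

  if (on(5L)) tok$lemma <- tolower(tok$lemma)
  if (on(6L) && length(lexicons$stopwords) > 0) {
    tok <- tok[!(tok$lemma %in% lexicons$stopwords), , drop = FALSE]
  }
  if (on(7L) && length(lexicons$lay_to_medical) > 0) {
    hit <- tok$lemma %in% names(lexicons$lay_to_medical)
    tok$lemma[hit] <- unname(lexicons$lay_to_medical[tok$lemma[hit]])
  }
  if (on(8L)) tok$lemma <- speller(tok$lemma)
  if (on(9L) && length(lexicons$pseudonyms) > 0) {
    tok <- tok[!(tok$lemma %in% tolower(lexicons$pseudonyms)), , drop = FALSE]
  }
  rownames(tok) <- NULL
  tok
}

#' Normalize every message of a corpus
#'
#' @param corpus A `qol_corpus` tibble or any data frame with a `text` column.
#' @param ... Passed on to [preprocess_document()].
#' @return A list of token data frames, one per message, in corpus order.
#' @export
preprocess_corpus <- function(corpus, ...) {
  lapply(corpus$text, preprocess_document, ...)
}
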