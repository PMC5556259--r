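#' Merge multi-word medical terms in a lemma stream
#'
#' Medical vocabularies define terms as sequences of words, most often a
#' single word. Multi-word entries ("cancer du sein") are matched on the
#' lemma stream left to right, longest match first, without overlap; a
#' matched span is emitted as one space-joined term.
#'
#' @param lemmas Character vector, the lemma stream of one document.
#' @param terms Character vector of medical terms (entries may contain
#'   spaces).
#' @return List with `term` (character vector after merging) and `merged`
#'   (logical, `TRUE` where the element came from a multi-word match).
#' @export
multiword_match <- function(lemmas, terms) {
  multi <- terms[grepl(" ", terms, fixed = TRUE)]
  if (length(multi) == 0 || length(lemmas) == 0) {
    return(list(term = lemmas, merged = rep(FALSE, length(lemmas))))
  }
  max_len <- max(lengths(strsplit(multi, " ", fixed = TRUE)))
  out <- character(0)
  merged <- logical(0)
  i <- 1L
  n <- length(lemmas)
  while (i <= n) {
    hit <- 0L
    top <- min(max_len, n - i + 1L)
    if (top >= 2L) {
      for (L in seq(top, 2L)) {
        cand <- paste(lemmas[i:(i + L - 1L)], collapse = " ")
        if (cand %in% multi) { hit <- L; break }
      }
    }
    if (hit > 0L) {
      out <- c(out, paste(lemmas[i:(i + hit - 1L)], collapse = " "))
      merged <- c(merged, TRUE)
      i <- i + hit
    } else {
      out <- c(out, lemmas[i])
      merged <- c(merged, FALSE)
      i <- i + 1L
    }
  }
  list(term = out, merged = merged)
}

#' Build a vocabulary and document-term corpus under a scenario
#'
#' Filters normalized documents down to the terms a scenario retains and
#' encodes each document as a sequence of term ids. Scenario `MED` keeps
#' only terms found in the medical list (after multi-word merging);
#' `MED+NN`, `MED+NN+V` and `MED+NN+V+A` additionally keep tokens tagged as
#' nouns, verbs and adjectives. Noise terms (by default *femme*, *temps* —
#' strongly represented words that drown topics) are always excluded, as are
#' stopwords, slang and pseudonyms (closure; normally already removed
#' upstream).
#'
#' @param tokenized List of token data frames from [preprocess_corpus()].
#' @param scenario One of `"MED"`, `"MED+NN"`, `"MED+NN+V"`, `"MED+NN+V+A"`.
#' @param lexicons A `lexicon_set`; `medical_terms` must be nonempty.
#' @param extra_medical Optional extra terms treated as medical (e.g. drug
#'   and nonconventional-treatment lists supplied by the user).
#' @return A `doc_term_corpus`: list with `vocabulary` (character vector,
#'   index = term id), `docs` (list of integer id vectors, one per document)
#'   and `scenario`.
#' @export
build_vocabulary <- function(tokenized,
                             scenario = c("MED", "MED+NN", "MED+NN+V", "MED+NN+V+A"),
                             lexicons, extra_medical = character()) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(lexicons, "lexicon_set"))
  med <- unique(c(lexicons$medical_terms, extra_medical))
  if (length(med) == 0) stop("medical term list is empty", call. = FALSE)
  pos_keep <- switch(scenario,
                     "MED" = character(),
                     "MED+NN" = "NN",
                     "MED+NN+V" = c("NN", "V"),
                     "MED+NN+V+A" = c("NN", "V", "A"))
  excluded <- unique(c(lexicons$noise_terms, lexicons$stopwords,
                       tolower(lexicons$slang), tolower(lexicons$pseudonyms)))

  doc_terms <- lapply(tokenized, function(tok) {
    if (is.null(tok) || nrow(tok) == 0) return(character())
    mm <- multiword_match(tok$lemma, med)
    # map POS back onto merged stream: merged spans count as medical
    pos <- character(length(mm$term))
    j <- 1L
    for (k in seq_along(mm$term)) {
      if (mm$merged[k]) {
        pos[k] <- "MED"
        j <- j + length(strsplit(mm$term[k], " ", fixed = TRUE)[[1]])
      } else {
        pos[k] <- tok$pos[j]
        j <- j + 1L
      }
    }
    keep <- (mm$term %in% med) | (pos %in% pos_keep) | pos == "MED"
    keep <- keep & !(mm$term %in% excluded)
    mm$term[keep]
  })

  vocab <- unique(unlist(doc_terms, use.names = FALSE))
  if (length(vocab) == 0) {
    warning("all documents are empty after vocabulary filtering", call. = FALSE)
    return(new_doc_term_corpus(character(), rep(list(integer()), length(tokenized)),
                               scenario))
  }
  docs <- lapply(doc_terms, function(tt) match(tt, vocab))
  new_doc_term_corpus(vocab, docs, scenario)
}

new_doc_term_corpus <- function(vocabulary, docs, scenario = NA_character_) {
  structure(list(vocabulary = vocabulary, docs = docs, scenario = scenario),
            class = "doc_term_corpus")
}

#' @export
print.doc_term_corpus <- function(x, ...) {
  cat("<doc_term_corpus>", length(x$docs), "documents,",
      length(x$vocabulary), "terms",
      if (!is.na(x$scenario)) paste0("(scenario ", x$scenario, ")"), "\n")
  cat("  total positions:", sum(lengths(x$docs)), "\n")
  invisible(x)
}

#' Document lengths of a document-term corpus
#'
#' @param corpus A `doc_term_corpus`.
#' @return Integer vector of per-document term counts.
#' @export
doc_lengths <- function(corpus) {
  vapply(corpus$docs, length, integer(1))
}
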